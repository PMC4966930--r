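---
title: "Pairwise kinship by the index of chromosome sharing: models and methods"
author: "icskin package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise kinship by the index of chromosome sharing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Forensic casework — disaster-victim and missing-person identification in
particular — often has to decide whether two DNA samples come from
relatives when the only available reference is a *distant* relative: an
uncle, a cousin, a great-grandparent. Standard STR panels resolve
first-degree relationships only. Genome-wide SNP genotypes carry enough
information to separate relationships out to the fifth degree, but
likelihood methods built on allele or haplotype frequencies are distorted
by linkage disequilibrium (LD) between dense markers.

`icskin` implements an approach that sidesteps frequencies altogether.
The observable is the **index of chromosome sharing (ICS)**: order the
autosomal SNPs along a genetic map, score identity by state (IBS = 0, 1
or 2) at every locus called in both individuals, take maximal runs of
IBS ≥ 1 as *shared segments* (runs of a single locus are discarded as
coincidental), measure each segment by the centi-Morgan distance between
its first and last SNP, and sum the lengths of all segments strictly
longer than a threshold *Th*:

$$ics(Th) = \sum_{\text{segments } s:\; \ell_s > Th} \ell_s .$$

The ICS of a pair is `ics(Th)` at a calibrated threshold — *C-Th* for
collateral relationships (sibling C-1, uncle–nephew C-2, first cousin
C-3, first cousin once removed C-4, second cousin C-5) and *L-Th* for
lineal ones (parent–child L-1, grandparent–grandchild L-2,
great-grandparent–great-grandchild L-3). Close relatives share long IBD
segments and accumulate a large ICS; unrelated pairs (UN) share only
short chance runs that the threshold removes. Because ICS is compared
against *simulated reference distributions* rather than against
frequency-based likelihoods, LD enters through the simulation instead of
invalidating the model.

## Calibration by simulation

Everything downstream needs the distribution of ICS per relationship.
These are obtained by gene-dropping simulation:

1. **Founder panel.** `makeHaplotypePanel()` generates a phased
   haplotype pool standing in for a phased population cohort. It is a
   Li–Stephens-style copying mosaic over `nAncestors` (default 100)
   hidden ancestral haplotypes; a haplotype switches ancestors between
   adjacent loci with probability $1 - e^{-d/\lambda}$ for a cM gap $d$.
   The ancestral pool itself is generated as per-ancestor Markov chains
   that keep the previous allele with probability $e^{-d/\lambda}$, so
   population-level $r^2$ decays as $e^{-d/\lambda}$ by construction.
   The decay scale $\lambda$ (`ldScale`) defaults to 0.25 cM, placing
   most $r^2$ decay within a quarter of a centi-Morgan as is typical of
   common array SNPs; ancestral allele frequencies are drawn from
   0.2–0.5 (folded), reflecting the common-variant ascertainment of
   genotyping arrays, and a panel MAF floor of 0.01 is enforced by
   resampling. A real phased panel can be supplied instead via
   `readPanelVCF()`; phasing itself is out of scope.
2. **Genetic map.** `makeSyntheticMap()` builds 22 autosome-like
   chromosomes with human-proportioned lengths rescaled to total exactly
   3662.5 cM, the shortest chromosome pinned at 63 cM. The default
   density is 1500 SNPs per chromosome (33,000 loci). Density matters:
   chance IBS runs between unrelated individuals must be short in cM
   relative to genuine IBD segments, which is exactly why the method is
   designed for high-density arrays. At substantially sparser synthetic
   maps the chance-sharing floor rises and the calibrated thresholds
   drift upward. bp coordinates are carried for interchange but never
   used in computation; cM is the sole metric.
3. **Gene dropping.** `simulateCohort()` drops founder haplotypes
   through a fixed 12-member, 4-generation pedigree whose member pairs
   realize C-1…C-5 and L-1…L-3; unrelated pairs are founders of
   different families. Each family consumes six donors drawn without
   replacement (1494 donors → 249 families). Meiosis is
   interference-free: each adjacent-locus interval recombines
   independently with probability min(cM gap / 100, 0.5), chromosomes
   segregate independently, and the transmitted strand starts on either
   parental haplotype with probability 1/2. Simulation is error-free by
   default (so parent–child pairs pin ICS at exactly the 3662.5 cM map
   total); `injectGenotypeErrors()` adds array-style miscalls and
   missingness for sensitivity studies.

## Threshold selection

`icsSweep()` evaluates `ics(Th)` for every labelled pair over a 1 cM
grid from 0 to 63 cM (the shortest chromosome), detecting segments once
per pair and re-thresholding. `selectThreshold()` scores each *Th* by
the mean Mann–Whitney AUC of the adjacent-relationship comparisons
(C-1 vs C-2, …, C-5 vs UN; L-1 vs L-2, L-2 vs L-3, L-3 vs UN) and picks
the *Th* with the maximum mean AUC, smallest on ties.

Under synthetic conditions the lineal mean-AUC curve is nearly flat
(all three comparisons are close to perfectly separable), so its argmax
can drift to large thresholds at which almost every UN pair has ICS
exactly 0 — and a zero-inflated class cannot be fitted by the
log-normal family below. `feasibleThreshold()` therefore adjusts the
selected threshold down to the largest grid value at which every fitted
class keeps at least 95% positive ICS values. `calibrateKinship()`
wires the whole pipeline together.

## Distribution fitting and model choice

For each relationship the ICS sample is fitted by maximum likelihood
under three two-parameter families: normal, normal truncated to
[0, total map length], and log-normal (`fitDistribution()`). Normal and
log-normal MLEs are closed-form; the truncated normal is maximized
numerically (BFGS on $(\mu, \log\sigma)$, initialized at the
untruncated MLE). Families are compared by
$AIC = 2k - 2\log(ML)$ with $k = 2$, summed over the relationships of a
group because every relationship keeps its own $\mu, \sigma$; the
family with the smallest group AIC wins (`selectModel()`). Numerical
ties — the truncated normal collapses onto the normal whenever the data
sit far from both bounds — are resolved in the order log-normal,
truncated normal, normal. Which family wins is data-dependent: on the
synthetic cohorts generated here the truncated normal and log-normal
are close competitors, and the pipeline simply propagates the AIC
winner. ICS values of exactly 0 are excluded from log-normal fitting
with a message; a class that is more than 5% zeros aborts, which is
what motivates the feasibility guard above. A one-sample z test with
known $\sigma$ on the fit's natural scale (log scale for the
log-normal) is provided (`zTestICS()`) to compare held-out ICS values
against a fitted distribution.

L-1 is deliberately *not* fitted: error-free parent–child pairs share
an allele at every locus, so their ICS is a point mass at the map
total, completely separated from every other relationship.
`l1Precheck()` decides L-1 deterministically — true when more than
$1 - 10^{-3}$ of called loci have IBS ≥ 1, a tolerance that absorbs
realistic array typing-error rates.

## Probabilistic evaluation

With fitted densities $f(ICS \mid H)$ in hand:

- **Likelihood ratio** (`likelihoodRatio()`):
  $LR = f(ICS \mid H_1) / f(ICS \mid H_2)$, computed in log space
  (ratios against UN routinely exceed $10^{50}$) and reported both
  linear and as log10.
- **Posterior probabilities** (`posteriorProbs()`): Bayes' theorem over
  the competing set — C-1…C-5 + UN for collateral analysis, L-2, L-3 +
  UN for lineal (L-1 pre-checked) — with flat priors by default and
  arbitrary priors accepted. Log-space max-subtraction keeps the
  normalization exact to $10^{-12}$.
- **Hummel predicates** (`hummelPredicate()`): posterior bands
  ≥ 0.998 "practically proven", [0.99, 0.998) "highly likely",
  [0.95, 0.99) "very likely", [0.90, 0.95) "likely", < 0.90
  "undetermined".
- **Predicate geometry**: `predicateRanges()` scans ICS over
  [0, 3662.5] at 0.1 cM and reports the ICS intervals of each band for
  a target relationship; `predicateMass()` integrates the target's own
  density over the region where its posterior clears a threshold
  (grid scan, root-refined interval endpoints, adaptive quadrature at
  `rel.tol` 1e-8). Interval stability was checked by halving the scan
  step.

## Numerical and design choices

- "Longer than *Th*" is strict (`>`), and isolated sharing is any
  single-locus run regardless of flanking distance; both follow the
  method's published definition of the worked ten-SNP example.
- Uncalled loci are deleted *before* run detection, so a segment may
  bridge a missing locus; endpoints are always called loci.
- Chromosome boundaries always break runs; zero-length multi-SNP
  segments (coincident cM) are retained but contribute nothing.
- Crossover probabilities are capped at 0.5 (free recombination); no
  crossover interference, no sex-specific maps.
- Per-family seeds are derived from the master seed by a fixed affine
  map modulo $2^{31} - 19$, so any family can be regenerated
  independently.
- AUC uses the midrank (tie-aware) Mann–Whitney estimator.

## Problem sizes and what the tests show

The packaged experiments run at the simulation's published design
(1494 donors, 249 six-founder families, flat priors) on the reduced
33,000-locus map; the test suite uses a 200-family calibration with 50
fresh test pairs per relationship, plus smaller worlds for unit
properties. On these conditions the calibrated C-Th lands around
8–11 cM rather than the low single digits reported for a 174,254-SNP
array — the chance-sharing floor scales with marker density, and the
threshold adapts accordingly. Qualitative structure is robust: mean ICS
decreases strictly from C-1 to UN and from L-1 to UN, parent–child
pairs sit exactly at the map total, posterior-mass rows are monotone
across the Hummel bands, and the distant relationships C-4/C-5 are far
harder to call than C-1…C-3. Which of C-4 and C-5 is hardest depends on
how close the UN distribution sits to C-5: with a sixth-degree
relationship absent from the hypothesis set, C-5's neighbourhood is
bounded by UN, and the synthetic UN lies closer to C-5 than a
dense-array cohort's would.

The synthetic generator emulates LD decay, array-like allele
frequencies and pedigree recombination; it does not emulate genotyping
error (off by default), population structure, ascertainment against
specific variant classes, or the long-range LD of real populations.
Passing tests therefore demonstrate the *method* — segment detection,
calibration, fitting and inference — under controlled conditions; they
do not certify population-specific thresholds or distributions, which
must be recalibrated from a phased cohort of the relevant population
(> 1000 individuals) before casework use.

## Known limitations

- Pairwise only: no trio or multi-reference joint inference.
- Calibration is population-specific; shipped defaults are synthetic.
- The L-group threshold is weakly identified (flat AUC curve); the
  fit-feasibility guard makes the choice deterministic but other values
  in the flat region would perform equally.
- A pair whose best posterior is "undetermined" may still have a
  competing relationship clearing a band; the full posterior vector is
  reported so the caller can apply their own reporting policy.
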