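#' @import methods
NULL

#' GeneticMap: ordered SNP loci with genetic (cM) and physical (bp) coordinates
#'
#' An ordered collection of biallelic SNP loci grouped by chromosome.
#' Genetic positions (centi-Morgan) are the sole coordinate used for segment
#' lengths and ICS values; base-pair positions are carried for interchange
#' with PLINK `.map`/VCF but never enter any computation.
#'
#' @slot chrom character, chromosome label per locus.
#' @slot snp character, unique SNP identifier per locus.
#' @slot cM numeric, genetic position in centi-Morgan (non-negative,
#'   non-decreasing within each chromosome).
#' @slot bp integer, physical position in base pairs (may be `NA`).
#' @slot chromOrder character, chromosome labels in map order.
#'
#' @seealso [readGeneticMap()], [makeSyntheticMap()], [totalMapLength()]
#' @export
setClass("GeneticMap",
  representation(chrom = "character", snp = "character", cM = "numeric",
                 bp = "integer", chromOrder = "character"),
  validity = function(object) {
    n <- length(object@snp)
    if (n == 0L)
      return("map must contain at least one locus")
    if (length(object@chrom) != n || length(object@cM) != n ||
        length(object@bp) != n)
      return("chrom, snp, cM and bp must have equal length")
    if (anyDuplicated(object@snp))
      return(sprintf("duplicate snp_id: %s",
                     object@snp[anyDuplicated(object@snp)]))
    if (anyNA(object@cM) || any(object@cM < 0))
      return("all genetic positions must be non-negative cM values")
    if (!identical(object@chromOrder, unique(object@chrom)))
      return("chromOrder must equal unique(chrom) in order of appearance")
    for (ch in object@chromOrder) {
      pos <- object@cM[object@chrom == ch]
      if (is.unsorted(pos))
        return(sprintf("cM positions are not non-decreasing on chromosome %s",
                       ch))
    }
    # loci of one chromosome must be contiguous in map order
    if (any(rle(object@chrom)$values |> duplicated()))
      return("loci of a chromosome must be contiguous in map order")
    TRUE
  })

#' DiploidGenotypes: unphased biallelic genotype calls aligned to a GeneticMap
#'
#' Genotypes are stored as allele-1 dosage per locus per sample:
#' 0 = ref/ref, 1 = het, 2 = alt/alt, `NA` = missing. Because alleles are
#' biallelic and pairs unordered, dosage is a lossless encoding. Row order is
#' map order and never changes independently of the map.
#'
#' @slot map a [GeneticMap-class].
#' @slot dosage integer matrix, loci x samples, values in `0:2` or `NA`;
#'   rownames are SNP ids, colnames sample ids.
#'
#' @seealso [readGenotypes()], [callRate()], [ibsStates()]
#' @export
setClass("DiploidGenotypes",
  representation(map = "GeneticMap", dosage = "matrix"),
  validity = function(object) {
    d <- object@dosage
    if (!is.integer(d[1]) && !all(is.na(d)))
      return("dosage must be an integer matrix")
    if (nrow(d) != length(object@map@snp))
      return("dosage must have one row per map locus")
    if (!identical(rownames(d), object@map@snp))
      return("dosage rownames must equal map snp ids in map order")
    if (is.null(colnames(d)) || anyDuplicated(colnames(d)))
      return("dosage must have unique sample ids as colnames")
    v <- d[!is.na(d)]
    if (length(v) && (any(v < 0L) || any(v > 2L)))
      return("dosage values must be 0, 1, 2 or NA")
    TRUE
  })

#' HaplotypePanel: phased founder haplotypes over a GeneticMap
#'
#' A pool of phased haplotypes (alleles coded 0/1, no missing data) paired
#' into donor individuals; used as the founder pool for pedigree simulation.
#'
#' @slot map a [GeneticMap-class].
#' @slot haplotypes integer matrix, loci x haplotypes, values 0/1.
#' @slot donors character, donor id of each haplotype column; every donor
#'   owns exactly two haplotypes.
#'
#' @seealso [makeHaplotypePanel()], [simulateCohort()]
#' @export
setClass("HaplotypePanel",
  representation(map = "GeneticMap", haplotypes = "matrix",
                 donors = "character"),
  validity = function(object) {
    h <- object@haplotypes
    if (nrow(h) != length(object@map@snp))
      return("haplotypes must have one row per map locus")
    if (length(object@donors) != ncol(h))
      return("donors must label every haplotype column")
    if (ncol(h) %% 2L != 0L)
      return("number of haplotypes must be even")
    if (!all(table(object@donors) == 2L))
      return("every donor must own exactly two haplotypes")
    if (anyNA(h) || !all(h == 0L | h == 1L))
      return("haplotype alleles must be 0/1 with no missing values")
    TRUE
  })

#' IbsTrack: per-locus IBS states between two individuals
#'
#' Loci where either individual is uncalled are absent from the track;
#' `locusIndex` maps each retained state back to the map row.
#'
#' @slot state integer, IBS state 0/1/2 per retained locus.
#' @slot locusIndex integer, map row index of each retained locus.
#' @slot chrom character, chromosome label of each retained locus.
#' @slot samples character(2), the two sample ids compared.
#'
#' @seealso [ibsStates()], [detectSharedSegments()]
#' @export
setClass("IbsTrack",
  representation(state = "integer", locusIndex = "integer",
                 chrom = "character", samples = "character"),
  validity = function(object) {
    n <- length(object@state)
    if (length(object@locusIndex) != n || length(object@chrom) != n)
      return("state, locusIndex and chrom must have equal length")
    if (n && is.unsorted(object@locusIndex, strictly = TRUE))
      return("locusIndex must be strictly increasing (map order)")
    if (n && (any(object@state < 0L) || any(object@state > 2L)))
      return("IBS states must be 0, 1 or 2")
    TRUE
  })

#' IcsValue: an index-of-chromosome-sharing value
#'
#' @slot value numeric, summed cM length of shared segments longer than the
#'   threshold.
#' @slot threshold numeric, segment-length threshold Th in cM.
#' @slot group character, `"C"` (collateral), `"L"` (lineal) or `""`.
#' @export
setClass("IcsValue",
  representation(value = "numeric", threshold = "numeric",
                 group = "character"),
  validity = function(object) {
    if (length(object@value) != 1L || is.na(object@value) || object@value < 0)
      return("value must be a single non-negative number")
    if (length(object@threshold) != 1L || object@threshold < 0)
      return("threshold must be a single non-negative number")
    if (!object@group %in% c("C", "L", ""))
      return('group must be "C", "L" or ""')
    TRUE
  })

#' Pedigree: a fixed pedigree given by parent pointers
#'
#' @slot members character, member labels.
#' @slot father named character, father of each non-founder (`NA` for
#'   founders).
#' @slot mother named character, mother of each non-founder.
#' @seealso [defaultPedigree()], [geneDrop()]
#' @export
setClass("Pedigree",
  representation(members = "character", father = "character",
                 mother = "character"),
  validity = function(object) {
    m <- object@members
    if (anyDuplicated(m)) return("member labels must be unique")
    if (!identical(names(object@father), m) ||
        !identical(names(object@mother), m))
      return("father and mother must be named by all members")
    fo <- is.na(object@father); mo <- is.na(object@mother)
    if (!identical(fo, mo))
      return("members must have either both parents or neither")
    pp <- c(object@father[!fo], object@mother[!mo])
    if (!all(pp %in% m))
      return("all parents must be pedigree members")
    # acyclicity via generation numbering
    gen <- stats::setNames(rep(NA_real_, length(m)), m)
    gen[fo] <- 0
    for (i in seq_len(length(m) + 1L)) {
      todo <- is.na(gen)
      if (!any(todo)) break
      for (x in m[todo]) {
        gf <- gen[object@father[x]]; gm <- gen[object@mother[x]]
        if (!is.na(gf) && !is.na(gm)) gen[x] <- max(gf, gm) + 1
      }
      if (i > length(m)) return("pedigree contains a cycle")
    }
    TRUE
  })

#' MeiosisModel: interference-free recombination model
#'
#' Crossover probability between adjacent loci is `min(d_cM / 100, capRate)`
#' where `d_cM` is the genetic gap; intervals are independent (no
#' interference) and chromosomes segregate independently.
#'
#' @slot capRate numeric, upper bound on the per-interval crossover
#'   probability (free recombination, default 0.5).
#' @seealso [meiosis()], [recombinationFraction()]
#' @export
setClass("MeiosisModel",
  representation(capRate = "numeric"),
  validity = function(object) {
    if (length(object@capRate) != 1L || object@capRate <= 0 ||
        object@capRate > 0.5)
      return("capRate must be a single value in (0, 0.5]")
    TRUE
  })

#' FamilyRealization: one gene-dropped family
#'
#' @slot haplotypes named list; per member an loci x 2 integer matrix of
#'   alleles.
#' @slot origins named list; per member an loci x 2 integer matrix tracing
#'   each allele to a founder haplotype (1..2*n_founders), or an empty list
#'   when tracing was disabled.
#' @slot familyIndex integer.
#' @slot founderDonors named character, panel donor assigned to each founder.
#' @export
setClass("FamilyRealization",
  representation(haplotypes = "list", origins = "list",
                 familyIndex = "integer", founderDonors = "character"))

#' KinCohort: simulated families plus pair bookkeeping
#'
#' @slot genotypes a [DiploidGenotypes-class] holding every simulated member
#'   (samples named `fam<i>_<member>`).
#' @slot pairs data.frame with columns `relationship`, `sampleA`, `sampleB`,
#'   `family` (NA for cross-family UN pairs).
#' @slot pedigree the [Pedigree-class] used.
#' @slot seed integer master seed.
#' @seealso [simulateCohort()], [relationshipPairs()]
#' @export
setClass("KinCohort",
  representation(genotypes = "DiploidGenotypes", pairs = "data.frame",
                 pedigree = "Pedigree", seed = "integer"))

#' IcsSweep: ics(Th) matrices over a threshold grid
#'
#' @slot thGrid numeric, ascending thresholds in cM.
#' @slot values named list; per relationship a pairs x thresholds matrix of
#'   ics(Th) values.
#' @seealso [icsSweep()], [selectThreshold()]
#' @export
setClass("IcsSweep",
  representation(thGrid = "numeric", values = "list"),
  validity = function(object) {
    if (is.unsorted(object@thGrid, strictly = TRUE))
      return("thGrid must be strictly increasing")
    for (v in object@values) {
      if (!is.matrix(v) || ncol(v) != length(object@thGrid))
        return("each value matrix must have one column per threshold")
    }
    TRUE
  })

#' ThresholdResult: AUC-based selection of the segment-length threshold
#'
#' @slot group character, `"C"` or `"L"`.
#' @slot thGrid numeric.
#' @slot componentAuc matrix, adjacent-relationship comparisons x thresholds.
#' @slot meanAuc numeric, column means of `componentAuc`.
#' @slot selectedTh numeric, threshold attaining the maximum mean AUC
#'   (smallest on ties).
#' @export
setClass("ThresholdResult",
  representation(group = "character", thGrid = "numeric",
                 componentAuc = "matrix", meanAuc = "numeric",
                 selectedTh = "numeric"))

#' FittedDistribution: a fitted ICS distribution for one relationship
#'
#' Families: `"normal"`, `"truncnorm"` (normal truncated to
#' `[lower, upper]`), `"lognormal"`. Each has a location `mu` and scale
#' `sigma` (log scale for the log-normal).
#'
#' @slot relationship character label (e.g. `"C-3"`, `"UN"`).
#' @slot family character, one of the three model families.
#' @slot mu,sigma numeric parameters (`sigma > 0`).
#' @slot lower,upper numeric truncation bounds (used by `truncnorm` only).
#' @slot n integer, number of ICS values fitted.
#' @slot logLik numeric, maximized log-likelihood.
#' @seealso [fitDistribution()], [densityICS()], [selectModel()]
#' @export
setClass("FittedDistribution",
  representation(relationship = "character", family = "character",
                 mu = "numeric", sigma = "numeric", lower = "numeric",
                 upper = "numeric", n = "integer", logLik = "numeric"),
  validity = function(object) {
    if (!object@family %in% c("normal", "truncnorm", "lognormal"))
      return("family must be normal, truncnorm or lognormal")
    if (object@sigma <= 0) return("sigma must be positive")
    if (object@family == "truncnorm" &&
        !(is.finite(object@lower) && is.finite(object@upper) &&
          object@lower < object@upper))
      return("truncnorm requires finite lower < upper")
    TRUE
  })

#' ModelSelection: AIC comparison of the three candidate families
#'
#' @slot group character, `"C"` or `"L"`.
#' @slot aic named numeric, group AIC per family (sum of per-relationship
#'   AICs, each relationship fitted with its own mu and sigma).
#' @slot chosen character, family with the minimal group AIC.
#' @slot fits named list; per family a named list of
#'   [FittedDistribution-class] per relationship.
#' @export
setClass("ModelSelection",
  representation(group = "character", aic = "numeric", chosen = "character",
                 fits = "list"))

#' HypothesisSet: competing relationship hypotheses with priors
#'
#' @slot group character, `"C"` or `"L"` (or `""` for ad-hoc sets).
#' @slot fits named list of [FittedDistribution-class], one per hypothesis.
#' @slot priors named numeric, prior probabilities (sum to 1, all positive).
#' @seealso [hypothesisSet()], [posteriorProbs()]
#' @export
setClass("HypothesisSet",
  representation(group = "character", fits = "list", priors = "numeric"),
  validity = function(object) {
    if (length(object@fits) < 1L)
      return("at least one hypothesis is required")
    if (!identical(names(object@fits), names(object@priors)))
      return("fits and priors must share names")
    if (any(object@priors <= 0))
      return("all priors must be positive")
    if (abs(sum(object@priors) - 1) > 1e-9)
      return("priors must sum to 1")
    if (!all(vapply(object@fits, is, logical(1), "FittedDistribution")))
      return("all hypotheses must carry a FittedDistribution")
    TRUE
  })

#' KinshipResult: probabilistic evaluation of one pair
#'
#' @slot ics a [IcsValue-class].
#' @slot logDensities named numeric, log f(ICS | H_j) per hypothesis.
#' @slot posteriors named numeric, flat- or user-prior posteriors (sum to 1).
#' @slot log10LrVsUN named numeric, log10 LR of each related hypothesis
#'   against UN (empty when UN is not among the hypotheses).
#' @slot bestHypothesis character.
#' @slot predicate character, Hummel predicate of the best posterior.
#' @export
setClass("KinshipResult",
  representation(ics = "IcsValue", logDensities = "numeric",
                 posteriors = "numeric", log10LrVsUN = "numeric",
                 bestHypothesis = "character", predicate = "character"),
  validity = function(object) {
    p <- object@posteriors
    if (length(p) && abs(sum(p) - 1) > 1e-9)
      return("posteriors must sum to 1")
    if (length(p) && (any(p < 0) || any(p > 1)))
      return("posteriors must lie in [0, 1]")
    TRUE
  })
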