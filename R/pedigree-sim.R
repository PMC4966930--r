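# Gene-dropping simulation: founder haplotypes are transmitted through a
# 12-member, 4-generation pedigree with interference-free recombination
# (crossover probability per adjacent-locus interval = min(cM gap / 100,
# 0.5)), yielding genotype pairs for five collateral (C-1..C-5), three
# lineal (L-1..L-3) relationships and cross-family unrelated (UN) pairs.

#' Construct a Pedigree
#'
#' @param members character member labels.
#' @param father,mother named character parent pointers (`NA` for
#'   founders); names must cover all members.
#' @return a [Pedigree-class].
#' @export
Pedigree <- function(members, father, mother) {
  new("Pedigree", members = members,
      father = father[members], mother = mother[members])
}

#' The default 12-member pedigree
#'
#' Four generations, members A--L: founders A, B, C, F, G, J;
#' A x B -> D, E; C x D -> H; E x F -> I; G x H -> K; I x J -> L.
#' Relationship pairs read off this structure:
#' C-1 sibling (D, E); C-2 uncle-nephew (D, I); C-3 first cousin (H, I);
#' C-4 first cousin once removed (H, L); C-5 second cousin (K, L);
#' L-1 parent-child (A, E); L-2 grandparent-grandchild (A, I);
#' L-3 great-grandparent-great-grandchild (A, L).
#'
#' @return a [Pedigree-class].
#' @export
defaultPedigree <- function() {
  members <- LETTERS[1:12]
  father <- stats::setNames(rep(NA_character_, 12L), members)
  mother <- father
  father[c("D", "E")] <- "A"; mother[c("D", "E")] <- "B"
  father["H"] <- "C"; mother["H"] <- "D"
  father["I"] <- "E"; mother["I"] <- "F"
  father["K"] <- "G"; mother["K"] <- "H"
  father["L"] <- "I"; mother["L"] <- "J"
  Pedigree(members, father, mother)
}

#' Founders of a pedigree
#' @param pedigree a [Pedigree-class].
#' @return character vector of founder labels.
#' @export
pedigreeFounders <- function(pedigree) {
  pedigree@members[is.na(pedigree@father)]
}

#' Relationship labels and member pairs of the default pedigree
#' @return named list of character(2) member pairs.
#' @export
relationshipMap <- function() {
  list("C-1" = c("D", "E"), "C-2" = c("D", "I"), "C-3" = c("H", "I"),
       "C-4" = c("H", "L"), "C-5" = c("K", "L"),
       "L-1" = c("A", "E"), "L-2" = c("A", "I"), "L-3" = c("A", "L"))
}

setMethod("show", "Pedigree", function(object) {
  nf <- sum(is.na(object@father))
  cat(sprintf("Pedigree: %d members (%d founders)\n",
              length(object@members), nf))
})

#' Construct a MeiosisModel
#' @param capRate cap on per-interval crossover probability (default 0.5,
#'   free recombination).
#' @return a [MeiosisModel-class].
#' @export
MeiosisModel <- function(capRate = 0.5) new("MeiosisModel", capRate = capRate)

#' Crossover probability for an adjacent-locus interval
#'
#' The recombination fraction is taken as 1/100 of the cM gap (a 1 cM
#' interval recombines with probability 0.01), capped at the model's
#' `capRate` so that wide gaps approach free recombination.
#'
#' @param model a [MeiosisModel-class].
#' @param dCM cM gap(s) between adjacent loci.
#' @return numeric crossover probabilities.
#' @export
recombinationFraction <- function(model, dCM) pmin(dCM / 100, model@capRate)

#' Simulate one meiosis (gamete haplotype)
#'
#' Per chromosome the transmitted source starts on either parental
#' haplotype with probability 1/2 and switches between them independently
#' per interval with probability [recombinationFraction()]. Draws from the
#' current RNG state; callers control reproducibility via `set.seed()`.
#'
#' @param parentHaps loci x 2 integer matrix (the parent's two phased
#'   haplotypes).
#' @param map the [GeneticMap-class] the haplotypes are aligned to.
#' @param model a [MeiosisModel-class].
#' @param origins optional loci x 2 matrix of origin labels carried with
#'   the alleles (for transmission bookkeeping).
#' @return integer gamete vector, or `list(gamete, origin)` when `origins`
#'   is supplied.
#' @export
meiosis <- function(parentHaps, map, model = MeiosisModel(),
                    origins = NULL) {
  stopifnot(nrow(parentHaps) == nLoci(map), ncol(parentHaps) == 2L)
  src <- integer(nrow(parentHaps))
  for (idx in .chromIndices(map)) {
    L <- length(idx)
    r <- recombinationFraction(model, diff(map@cM[idx]))
    flips <- if (L > 1L) stats::rbinom(L - 1L, 1L, r) else integer(0)
    start <- stats::rbinom(1L, 1L, 0.5)
    src[idx] <- (start + cumsum(c(0L, flips))) %% 2L + 1L
  }
  gamete <- parentHaps[cbind(seq_len(nrow(parentHaps)), src)]
  if (is.null(origins)) return(gamete)
  list(gamete = gamete,
       origin = origins[cbind(seq_len(nrow(origins)), src)])
}

.chromIndices <- function(map) {
  split(seq_len(nLoci(map)), factor(map@chrom, levels = map@chromOrder))
}

#' Gene-drop founder haplotypes through a pedigree
#'
#' Founders receive their assigned haplotypes unchanged; every non-founder
#' receives one [meiosis()] gamete from each parent, descending in
#' topological order. With `trace = TRUE` every allele is labelled with the
#' founder haplotype (1..2*n_founders) it descends from.
#'
#' @param pedigree a [Pedigree-class].
#' @param founderHaps named list (one per founder) of loci x 2 integer
#'   haplotype matrices.
#' @param map a [GeneticMap-class].
#' @param model a [MeiosisModel-class].
#' @param trace keep founder-origin matrices for every member.
#' @param familyIndex integer annotation.
#' @param founderDonors optional named character annotation.
#' @return a [FamilyRealization-class].
#' @export
geneDrop <- function(pedigree, founderHaps, map, model = MeiosisModel(),
                     trace = FALSE, familyIndex = 1L,
                     founderDonors = character()) {
  founders <- pedigreeFounders(pedigree)
  if (!all(founders %in% names(founderHaps)))
    stop("founderHaps must be named with every founder label")
  haps <- list(); orig <- list()
  for (i in seq_along(founders)) {
    f <- founders[i]
    haps[[f]] <- founderHaps[[f]]
    if (trace)
      orig[[f]] <- matrix(rep(c(2L * i - 1L, 2L * i), each = nLoci(map)),
                          ncol = 2L)
  }
  todo <- setdiff(pedigree@members, founders)
  guard <- 0L
  while (length(todo)) {
    guard <- guard + 1L
    if (guard > length(pedigree@members) + 1L)
      stop("pedigree is not acyclic")
    for (m in todo) {
      fa <- pedigree@father[[m]]; mo <- pedigree@mother[[m]]
      if (!is.null(haps[[fa]]) && !is.null(haps[[mo]])) {
        if (trace) {
          g1 <- meiosis(haps[[fa]], map, model, origins = orig[[fa]])
          g2 <- meiosis(haps[[mo]], map, model, origins = orig[[mo]])
          haps[[m]] <- cbind(g1$gamete, g2$gamete)
          orig[[m]] <- cbind(g1$origin, g2$origin)
        } else {
          haps[[m]] <- cbind(meiosis(haps[[fa]], map, model),
                             meiosis(haps[[mo]], map, model))
        }
        todo <- setdiff(todo, m)
      }
    }
  }
  new("FamilyRealization", haplotypes = haps, origins = orig,
      familyIndex = as.integer(familyIndex),
      founderDonors = founderDonors)
}

#' Maximum feasible number of families from a founder panel
#'
#' Each simulated family consumes six distinct donors, drawn without
#' replacement across families (e.g. 1494 donors support 249 families).
#'
#' @param panel a [HaplotypePanel-class].
#' @param foundersPerFamily founders consumed per family (6 for the default
#'   pedigree).
#' @return integer.
#' @export
maxFamilies <- function(panel, foundersPerFamily = 6L) {
  floor(length(panelDonors(panel)) / foundersPerFamily)
}

#' Simulate a cohort of gene-dropped families
#'
#' Founder donors are drawn from the panel without replacement across
#' families (disjoint sextets); each family is gene-dropped under a
#' per-family seed derived from `seed`, so the cohort is reproducible and
#' individual families can be regenerated independently.
#'
#' @param panel a [HaplotypePanel-class].
#' @param nFamilies number of families; capped by [maxFamilies()].
#' @param pedigree a [Pedigree-class] (default [defaultPedigree()]).
#' @param model a [MeiosisModel-class].
#' @param seed master integer seed.
#' @param errorRate optional genotype-error rate: each resulting genotype
#'   call is independently replaced by a uniformly random other dosage with
#'   this probability (default 0, matching error-free simulation).
#' @param missingRate optional per-call missingness rate (default 0).
#' @return a [KinCohort-class] with samples named `fam<i>_<member>` and a
#'   pair table covering C-1..C-5, L-1..L-3 and one cross-family UN pair
#'   per family.
#' @export
simulateCohort <- function(panel, nFamilies, pedigree = defaultPedigree(),
                           model = MeiosisModel(), seed = 1L,
                           errorRate = 0, missingRate = 0) {
  nmax <- maxFamilies(panel, length(pedigreeFounders(pedigree)))
  if (nFamilies > nmax)
    stop("insufficient donors: at most ", nmax, " families are feasible")
  if (nFamilies < 1L) stop("nFamilies must be >= 1")
  map <- panel@map
  founders <- pedigreeFounders(pedigree)
  members <- pedigree@members
  nf <- length(founders)
  withSeed(seed, {
    donorPick <- sample(panelDonors(panel), nf * nFamilies)
    dosage <- matrix(NA_integer_, nrow = nLoci(map),
                     ncol = nFamilies * length(members))
    cn <- character(ncol(dosage))
    for (i in seq_len(nFamilies)) {
      fam <- withSeed(deriveSeed(seed, i), {
        dn <- donorPick[((i - 1L) * nf + 1L):(i * nf)]
        fh <- lapply(seq_len(nf), function(j) {
          cols <- which(panel@donors == dn[j])
          panel@haplotypes[, cols, drop = FALSE]
        })
        names(fh) <- founders
        geneDrop(pedigree, fh, map, model, familyIndex = i,
                 founderDonors = stats::setNames(dn, founders))
      })
      off <- (i - 1L) * length(members)
      for (k in seq_along(members)) {
        h <- fam@haplotypes[[members[k]]]
        dosage[, off + k] <- h[, 1L] + h[, 2L]
        cn[off + k] <- sprintf("fam%d_%s", i, members[k])
      }
    }
    colnames(dosage) <- cn
    rownames(dosage) <- map@snp
    if (errorRate > 0 || missingRate > 0)
      dosage <- injectGenotypeErrors(dosage, errorRate = errorRate,
                                     missingRate = missingRate)
    pairs <- .cohortPairs(nFamilies, founders)
    new("KinCohort", genotypes = DiploidGenotypes(map, dosage),
        pairs = pairs, pedigree = pedigree, seed = as.integer(seed))
  })
}

# Pair table: labelled within-family pairs plus one UN pair per family
# (founders of different families). Uses the current RNG stream.
.cohortPairs <- function(nFamilies, founders) {
  rel <- relationshipMap()
  out <- do.call(rbind, lapply(seq_len(nFamilies), function(i) {
    data.frame(relationship = names(rel),
               sampleA = sprintf("fam%d_%s", i,
                                 vapply(rel, `[`, "", 1L)),
               sampleB = sprintf("fam%d_%s", i,
                                 vapply(rel, `[`, "", 2L)),
               family = i)
  }))
  if (nFamilies >= 2L) {
    other <- seq_len(nFamilies) %% nFamilies + 1L  # partner family, never self
    un <- data.frame(
      relationship = "UN",
      sampleA = sprintf("fam%d_%s", seq_len(nFamilies),
                        sample(founders, nFamilies, replace = TRUE)),
      sampleB = sprintf("fam%d_%s", other,
                        sample(founders, nFamilies, replace = TRUE)),
      family = NA_integer_)
    out <- rbind(out, un)
  }
  rownames(out) <- NULL
  out
}

#' Inject genotyping errors into a dosage matrix or DiploidGenotypes
#'
#' Each called genotype is independently replaced by one of the two other
#' dosage values with probability `errorRate`, and set missing with
#' probability `missingRate` (applied after miscalls). Used to study the
#' sensitivity of ICS and of the parent-child pre-check to array typing
#' error; the default simulation pipeline is error-free.
#'
#' @param x integer dosage matrix/vector or [DiploidGenotypes-class].
#' @param errorRate per-call miscall probability.
#' @param missingRate per-call missingness probability.
#' @param seed optional integer seed.
#' @return object of the same shape as `x`.
#' @export
injectGenotypeErrors <- function(x, errorRate = 0, missingRate = 0,
                                 seed = NULL) {
  if (is(x, "DiploidGenotypes"))
    return(DiploidGenotypes(
      x@map, injectGenotypeErrors(dosageMatrix(x), errorRate, missingRate,
                                  seed)))
  withSeed(seed, {
    d <- x
    called <- which(!is.na(d))
    if (errorRate > 0 && length(called)) {
      hit <- called[stats::runif(length(called)) < errorRate]
      if (length(hit)) {
        shift <- sample(1:2, length(hit), replace = TRUE)
        d[hit] <- (d[hit] + shift) %% 3L
      }
    }
    if (missingRate > 0 && length(called)) {
      d[called[stats::runif(length(called)) < missingRate]] <- NA_integer_
    }
    d
  })
}

#' Pair table of a cohort
#' @param cohort a [KinCohort-class].
#' @param relationship optional label filter (e.g. `"C-3"`).
#' @return data.frame with `relationship`, `sampleA`, `sampleB`, `family`.
#' @export
relationshipPairs <- function(cohort, relationship = NULL) {
  p <- cohort@pairs
  if (!is.null(relationship)) p <- p[p$relationship %in% relationship, ]
  p
}

#' Genotypes of a cohort
#' @param cohort a [KinCohort-class].
#' @return a [DiploidGenotypes-class].
#' @export
cohortGenotypes <- function(cohort) cohort@genotypes

setMethod("show", "KinCohort", function(object) {
  nFam <- max(object@pairs$family, na.rm = TRUE)
  cat(sprintf("KinCohort: %d families, %d samples, %d labelled pairs\n",
              nFam, ncol(object@genotypes@dosage), nrow(object@pairs)))
})

#' @rdname geneticMap
setMethod("geneticMap", "KinCohort", function(x) x@genotypes@map)
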