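# Shared fixtures, built in code and cached for the duration of the run.
# Small scales are used here; full study-scale runs live in
# scripts/acceptance.R.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# A tiny hand-made map: 2 chromosomes, equally spaced loci.
tinyMap <- function(nPerChrom = 10L, spacing = 1) {
  k <- nPerChrom
  GeneticMap(chrom = rep(c("1", "2"), each = k),
             snp = sprintf("s%02d", seq_len(2L * k)),
             cM = rep(spacing * (seq_len(k) - 1L), 2L),
             bp = seq_len(2L * k) * 1000L)
}

# Genotypes from explicit dosage rows (loci x samples).
tinyGenotypes <- function(map, ...) {
  cols <- list(...)
  d <- do.call(cbind, cols)
  colnames(d) <- names(cols)
  DiploidGenotypes(map, d)
}

# Moderate synthetic world shared by several test files.
smallMap <- function() fixture("smallMap", function()
  makeSyntheticMap(nChromosomes = 6L, snpsPerChromosome = 400L,
                   chromosomeLengths = c(160, 140, 120, 100, 80, 63),
                   seed = 421L))

smallPanel <- function() fixture("smallPanel", function()
  makeHaplotypePanel(smallMap(), nIndividuals = 80L, seed = 422L))

smallCohort <- function() fixture("smallCohort", function()
  simulateCohort(smallPanel(), nFamilies = 12L, seed = 423L))

# Genome-scale (all 22 chromosomes) but thinned cohort for ordering tests.
orderingCohort <- function() fixture("orderingCohort", function() {
  map <- makeSyntheticMap(seed = 431L)  # default study density
  panel <- makeHaplotypePanel(map, nIndividuals = 620L, seed = 432L)
  simulateCohort(panel, nFamilies = 100L, seed = 433L)
})

# Brute-force maximal-run shared-segment enumerator: the independent oracle
# for detectSharedSegments. Operates on a vector of IBS states, the map
# indices they sit at, and the map; enumerates runs by explicit scanning.
bruteForceSegments <- function(states, locusIndex, map) {
  out <- NULL
  n <- length(states)
  i <- 1L
  while (i <= n) {
    if (states[i] >= 1L) {
      j <- i
      while (j < n && states[j + 1L] >= 1L &&
             map@chrom[locusIndex[j + 1L]] == map@chrom[locusIndex[i]])
        j <- j + 1L
      if (j > i) {
        fi <- locusIndex[i]; li <- locusIndex[j]
        out <- rbind(out, data.frame(
          chrom = map@chrom[fi], firstIndex = fi, lastIndex = li,
          nSnps = j - i + 1L, lengthCM = map@cM[li] - map@cM[fi]))
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  if (is.null(out))
    data.frame(chrom = character(), firstIndex = integer(),
               lastIndex = integer(), nSnps = integer(),
               lengthCM = numeric())
  else out
}

# Exhaustive allele-matching IBS oracle: genotypes as unordered allele
# pairs; IBS = size of the maximum bipartite matching, found by trying
# both pairings.
matchingIbsOracle <- function(pairA, pairB) {
  direct <- (pairA[1] == pairB[1]) + (pairA[2] == pairB[2])
  crossed <- (pairA[1] == pairB[2]) + (pairA[2] == pairB[1])
  max(direct, crossed)
}

dosageToPair <- function(d) switch(d + 1L, c(0L, 0L), c(0L, 1L), c(1L, 1L))
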