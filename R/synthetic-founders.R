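# Synthetic genetic maps and LD-structured founder haplotype panels.
#
# The panel generator is a Li-Stephens-style copying mosaic: within each
# chromosome every haplotype copies from one of K ancestral haplotypes,
# switching ancestors between adjacent loci with probability
# 1 - exp(-d / ldScale) for a cM gap d. This produces linkage
# disequilibrium that decays with genetic distance -- the feature of real
# panels that naive allele-frequency simulators miss and that segment-based
# sharing statistics are sensitive to.

#' Default autosome genetic lengths (cM)
#'
#' Human-autosome-like relative lengths rescaled so that chromosome 21 is
#' exactly 63 cM (the shortest autosome) and the total is exactly
#' 3662.5 cM, the scale on which the maximum ICS value lives.
#'
#' @param total total map length in cM.
#' @param shortest length of the shortest chromosome (pinned, not
#'   rescaled).
#' @return named numeric of 22 lengths summing to `total`.
#' @export
defaultChromosomeLengths <- function(total = 3662.5, shortest = 63) {
  base <- c(286.3, 268.6, 223.2, 214.5, 204.1, 192.0, 187.2, 168.0, 166.4,
            181.1, 158.2, 174.7, 125.9, 120.3, 141.9, 134.0, 128.5, 117.5,
            107.9, 108.2, 62.8, 74.1)
  names(base) <- as.character(1:22)
  i <- which.min(base)
  out <- base * (total - shortest) / sum(base[-i])
  out[i] <- shortest
  out
}

#' Generate a synthetic genetic map
#'
#' Per chromosome, locus cM positions are sorted uniform draws spanning
#' `[0, length]` with the first locus pinned at 0 and the last at `length`,
#' so [totalMapLength()] equals `sum(chromosomeLengths)` exactly. The
#' default preset is 22 autosome-like chromosomes totalling 3662.5 cM with
#' the shortest chromosome at 63 cM.
#'
#' @param nChromosomes number of chromosomes.
#' @param snpsPerChromosome loci per chromosome (>= 2); scalar or vector.
#' @param chromosomeLengths cM length per chromosome.
#' @param seed optional integer seed.
#' @return a [GeneticMap-class].
#' @examples
#' m <- makeSyntheticMap(seed = 7)
#' totalMapLength(m)  # 3662.5
#' @export
makeSyntheticMap <- function(nChromosomes = 22L, snpsPerChromosome = 1500L,
                             chromosomeLengths = defaultChromosomeLengths(),
                             seed = NULL) {
  if (nChromosomes < 1L)
    stop("nChromosomes must be >= 1")
  if (length(chromosomeLengths) != nChromosomes)
    chromosomeLengths <- rep_len(chromosomeLengths, nChromosomes)
  nsnp <- rep_len(as.integer(snpsPerChromosome), nChromosomes)
  if (any(nsnp < 2L)) stop("snpsPerChromosome must be >= 2")
  if (any(chromosomeLengths <= 0)) stop("chromosome lengths must be > 0")
  withSeed(seed, {
    chrom <- character(0); snp <- character(0); cM <- numeric(0)
    labs <- if (!is.null(names(chromosomeLengths)))
      names(chromosomeLengths) else as.character(seq_len(nChromosomes))
    for (c_i in seq_len(nChromosomes)) {
      L <- chromosomeLengths[c_i]; k <- nsnp[c_i]
      pos <- c(0, sort(stats::runif(k - 2L)) * L, L)[seq_len(max(k, 2L))]
      if (k == 2L) pos <- c(0, L)
      chrom <- c(chrom, rep(labs[c_i], k))
      snp <- c(snp, sprintf("chr%s_snp%d", labs[c_i], seq_len(k)))
      cM <- c(cM, pos)
    }
    GeneticMap(chrom = chrom, snp = snp, cM = cM,
               bp = as.integer(round(cM * 1e6)) + 1L)
  })
}

#' Generate an LD-structured phased haplotype panel
#'
#' Copying-mosaic generative model (fixed, documented): per chromosome,
#' `nAncestors` ancestral haplotypes are drawn i.i.d. Bernoulli(p_l), with
#' p_l sampled from `mafRange` and folded to either allele with equal
#' probability. Each panel haplotype then copies allele-by-allele from a
#' hidden ancestor, switching to a uniformly chosen ancestor between
#' adjacent loci with probability `1 - exp(-d / ldScale)` (cM gap `d`).
#' Loci whose panel minor-allele frequency falls at or below `minMaf` are
#' resampled (bounded attempts).
#'
#' @param map a [GeneticMap-class].
#' @param nIndividuals number of diploid donors (>= 2); the panel holds
#'   `2 * nIndividuals` haplotypes.
#' @param ldScale LD decay scale in cM (> 0); smaller values give
#'   shorter-range LD. The default 0.25 cM puts most r-squared decay within
#'   a quarter of a centi-Morgan, the scale typical of array SNP panels.
#' @param mafRange ancestral allele-frequency range (folded).
#' @param nAncestors hidden ancestors per chromosome.
#' @param minMaf panel MAF floor (loci with MAF <= `minMaf` are resampled).
#' @param seed optional integer seed.
#' @return a [HaplotypePanel-class].
#' @export
makeHaplotypePanel <- function(map, nIndividuals, ldScale = 0.25,
                               mafRange = c(0.2, 0.5), nAncestors = 100L,
                               minMaf = 0.01, seed = NULL) {
  stopifnot(is(map, "GeneticMap"))
  if (nIndividuals < 2L) stop("nIndividuals must be >= 2")
  if (ldScale <= 0) stop("ldScale must be > 0")
  nHap <- 2L * as.integer(nIndividuals)
  K <- as.integer(nAncestors)
  withSeed(seed, {
    chromIdx <- split(seq_len(nLoci(map)),
                      factor(map@chrom, levels = map@chromOrder))
    hap <- matrix(0L, nrow = nLoci(map), ncol = nHap)
    for (idx in chromIdx) {
      L <- length(idx)
      pSwitch <- 1 - exp(-diff(map@cM[idx]) / ldScale)
      # hidden source paths: segment ids per haplotype, then random
      # ancestor per segment
      W <- matrix(stats::rbinom((L - 1L) * nHap, 1L, pSwitch),
                  nrow = L - 1L, ncol = nHap)
      S <- apply(rbind(1L, W), 2L, cumsum)
      maxS <- max(S)
      choice <- matrix(sample.int(K, maxS * nHap, replace = TRUE),
                       nrow = maxS, ncol = nHap)
      src <- matrix(choice[cbind(as.vector(S),
                                 rep(seq_len(nHap), each = L))],
                    nrow = L, ncol = nHap)
      # ancestral pool with built-in LD: per ancestor a Markov chain that
      # keeps its previous allele with probability exp(-d/ldScale) and
      # otherwise redraws at the local frequency, so population r^2 decays
      # as exp(-d/ldScale) regardless of K
      p <- .foldedFreq(L, mafRange)
      keepProb <- exp(-diff(map@cM[idx]) / ldScale)
      anc <- matrix(0L, nrow = K, ncol = L)
      anc[, 1L] <- stats::rbinom(K, 1L, p[1L])
      for (l in seq_len(L - 1L) + 1L) {
        keep <- stats::runif(K) < keepProb[l - 1L]
        anc[, l] <- ifelse(keep, anc[, l - 1L],
                           stats::rbinom(K, 1L, p[l]))
      }
      block <- anc[cbind(as.vector(src), rep(seq_len(L), nHap))]
      block <- matrix(block, nrow = L, ncol = nHap)
      for (attempt in seq_len(50L)) {
        f <- rowMeans(block)
        bad <- which(pmin(f, 1 - f) <= minMaf)
        if (!length(bad)) break
        if (attempt == 50L)
          stop(length(bad), " locus/loci could not reach MAF > ", minMaf,
               " after bounded resampling")
        pB <- .foldedFreq(length(bad), mafRange)
        anc[, bad] <- matrix(stats::rbinom(K * length(bad), 1L,
                                           rep(pB, each = K)),
                             nrow = K)
        block[bad, ] <- matrix(
          anc[cbind(as.vector(src[bad, , drop = FALSE]),
                    rep(bad, nHap))],
          nrow = length(bad), ncol = nHap)
      }
      hap[idx, ] <- block
    }
    donors <- rep(sprintf("D%04d", seq_len(nIndividuals)), each = 2L)
    colnames(hap) <- sprintf("%s_h%d", donors, rep(1:2, nIndividuals))
    rownames(hap) <- map@snp
    new("HaplotypePanel", map = map, haplotypes = hap, donors = donors)
  })
}

.foldedFreq <- function(n, mafRange) {
  f <- stats::runif(n, mafRange[1L], mafRange[2L])
  flip <- stats::runif(n) < 0.5
  ifelse(flip, 1 - f, f)
}

#' @rdname sampleIds
setMethod("sampleIds", "HaplotypePanel", function(x) unique(x@donors))

#' @rdname nLoci
setMethod("nLoci", "HaplotypePanel", function(x) nrow(x@haplotypes))

#' Haplotype matrix of a panel (loci x haplotypes, alleles 0/1)
#' @param panel a [HaplotypePanel-class].
#' @return integer matrix.
#' @export
haplotypeMatrix <- function(panel) panel@haplotypes

#' Donor ids of a panel
#' @param panel a [HaplotypePanel-class].
#' @return character vector (one entry per donor).
#' @export
panelDonors <- function(panel) unique(panel@donors)

setMethod("show", "HaplotypePanel", function(object) {
  cat(sprintf("HaplotypePanel: %d haplotypes (%d donors) x %d loci\n",
              ncol(object@haplotypes), length(unique(object@donors)),
              nrow(object@haplotypes)))
})

#' Collapse panel haplotypes into diploid genotypes
#'
#' @param panel a [HaplotypePanel-class].
#' @param donors donor ids to include (default all).
#' @return a [DiploidGenotypes-class] with one sample per donor.
#' @export
panelGenotypes <- function(panel, donors = panelDonors(panel)) {
  h <- panel@haplotypes
  d <- vapply(donors, function(dn) {
    cols <- which(panel@donors == dn)
    if (length(cols) != 2L) stop("unknown donor: ", dn)
    h[, cols[1L]] + h[, cols[2L]]
  }, integer(nrow(h)))
  DiploidGenotypes(panel@map, d)
}

#' Write a panel as a phased plain-text VCF
#'
#' @param panel a [HaplotypePanel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePanelVCF <- function(panel, path) {
  map <- panel@map
  h <- panel@haplotypes
  donors <- panelDonors(panel)
  pos <- ifelse(is.na(map@bp), as.integer(round(map@cM * 1e6)) + 1L, map@bp)
  gt <- vapply(donors, function(dn) {
    cols <- which(panel@donors == dn)
    paste0(h[, cols[1L]], "|", h[, cols[2L]])
  }, character(nrow(h)))
  lines <- c("##fileformat=VCFv4.2",
             paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                    paste(donors, collapse = "\t")),
             paste(map@chrom, pos, map@snp, "A", "G", ".", ".", ".", "GT",
                   apply(gt, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Load a phased haplotype panel from VCF
#'
#' Accepts a VCF with phased GT (`|` separator) at biallelic sites aligned
#' to `map` by SNP id; all map loci must be present and fully called.
#'
#' @param path phased VCF path.
#' @param map a [GeneticMap-class].
#' @return a [HaplotypePanel-class].
#' @export
readPanelVCF <- function(path, map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (!all(map@snp %in% rownames(gt)))
    stop("phased VCF must cover every map locus")
  gt <- gt[map@snp, , drop = FALSE]
  if (any(!grepl("^[01]\\|[01]$", gt)))
    stop("panel VCF must be fully phased ('|') and fully called")
  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt))
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt))
  donors <- colnames(gt)
  hap <- matrix(0L, nrow = nrow(gt), ncol = 2L * ncol(gt))
  hap[, seq(1L, ncol(hap), 2L)] <- a1
  hap[, seq(2L, ncol(hap), 2L)] <- a2
  colnames(hap) <- sprintf("%s_h%d", rep(donors, each = 2L), rep(1:2,
                                                                 ncol(gt)))
  rownames(hap) <- map@snp
  new("HaplotypePanel", map = map, haplotypes = hap,
      donors = rep(donors, each = 2L))
}
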