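# Genetic-map and genotype input/output.
#
# Coordinate conventions used throughout the package: loci are kept in map
# order, lengths are computed purely in cM, and genotypes are unordered
# biallelic allele pairs stored as allele-1 dosage (0/1/2, NA = uncalled).

#' Construct a GeneticMap
#'
#' @param chrom character, chromosome label per locus.
#' @param snp character, unique SNP ids.
#' @param cM numeric genetic positions (non-decreasing within chromosome).
#' @param bp optional integer physical positions (carried, never used in
#'   length computations).
#' @return a [GeneticMap-class].
#' @export
GeneticMap <- function(chrom, snp, cM, bp = NA_integer_) {
  chrom <- rep_len(as.character(chrom), length(snp))
  bp <- rep_len(suppressWarnings(as.integer(bp)), length(snp))
  new("GeneticMap", chrom = chrom, snp = as.character(snp),
      cM = as.numeric(cM), bp = bp, chromOrder = unique(chrom))
}

#' Read a PLINK-style genetic map
#'
#' Expected dialect: whitespace-separated columns
#' `chrom  snp_id  cM  bp`, no header. Rows violating within-chromosome
#' cM monotonicity, duplicate SNP ids or malformed fields are rejected.
#'
#' @param path path to a `.map` file.
#' @return a [GeneticMap-class].
#' @export
readGeneticMap <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty map file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop("malformed map row at line ", which(nf < 4L)[1L],
         ": expected 4 whitespace-separated columns")
  m <- do.call(rbind, fields)[, 1:4, drop = FALSE]
  cM <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(cM))
    stop("malformed cM value at line ", which(is.na(cM))[1L])
  bp <- suppressWarnings(as.integer(m[, 4L]))
  if (anyDuplicated(m[, 2L]))
    stop("duplicate snp_id in map: ", m[duplicated(m[, 2L]), 2L][1L])
  GeneticMap(chrom = m[, 1L], snp = m[, 2L], cM = cM, bp = bp)
}

#' Write a genetic map in PLINK .map dialect
#'
#' @param map a [GeneticMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneticMap <- function(map, path) {
  stopifnot(is(map, "GeneticMap"))
  bp <- ifelse(is.na(map@bp), 0L, map@bp)
  utils::write.table(
    data.frame(map@chrom, map@snp, format(map@cM, digits = 15L,
                                          scientific = FALSE, trim = TRUE),
               bp),
    path, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname totalMapLength
setMethod("totalMapLength", "GeneticMap", function(map) {
  sum(chromosomeLengths(map))
})

#' @rdname chromosomeLengths
setMethod("chromosomeLengths", "GeneticMap", function(map) {
  vapply(split(map@cM, factor(map@chrom, levels = map@chromOrder)),
         function(p) p[length(p)] - p[1L], numeric(1))
})

#' @rdname nLoci
setMethod("nLoci", "GeneticMap", function(x) length(x@snp))

#' @rdname geneticMap
setMethod("geneticMap", "DiploidGenotypes", function(x) x@map)

#' @rdname geneticMap
setMethod("geneticMap", "HaplotypePanel", function(x) x@map)

setMethod("show", "GeneticMap", function(object) {
  cat(sprintf("GeneticMap: %d loci on %d chromosome(s), %.3f cM total\n",
              nLoci(object), length(object@chromOrder),
              totalMapLength(object)))
})

#' Construct DiploidGenotypes from a dosage matrix
#'
#' @param map a [GeneticMap-class].
#' @param dosage integer matrix loci x samples (0/1/2/NA); rownames must be
#'   the map's SNP ids (set from the map when absent).
#' @return a [DiploidGenotypes-class].
#' @export
DiploidGenotypes <- function(map, dosage) {
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage))) rownames(dosage) <- map@snp
  new("DiploidGenotypes", map = map, dosage = dosage)
}

#' @rdname sampleIds
setMethod("sampleIds", "DiploidGenotypes", function(x) colnames(x@dosage))

#' @rdname dosageMatrix
setMethod("dosageMatrix", "DiploidGenotypes", function(x) x@dosage)

#' @rdname nLoci
setMethod("nLoci", "DiploidGenotypes", function(x) nrow(x@dosage))

setMethod("show", "DiploidGenotypes", function(object) {
  cat(sprintf("DiploidGenotypes: %d loci x %d sample(s); %.4f called\n",
              nrow(object@dosage), ncol(object@dosage),
              mean(!is.na(object@dosage))))
})

.gtToDosage <- function(gt) {
  # "0/1", "1|0", "./." (and partial calls) -> dosage
  out <- rep(NA_integer_, length(gt))
  gt <- sub(":.*$", "", gt)
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  out[ok] <- as.integer(a1[ok]) + as.integer(a2[ok])
  out
}

.dosageToGt <- function(d, sep = "/") {
  out <- rep(paste0(".", sep, "."), length(d))
  out[!is.na(d) & d == 0L] <- paste0("0", sep, "0")
  out[!is.na(d) & d == 1L] <- paste0("0", sep, "1")
  out[!is.na(d) & d == 2L] <- paste0("1", sep, "1")
  out
}

#' Read diploid genotypes aligned to a genetic map
#'
#' Two formats are supported. `"tsv"`: a header row of SNP ids (first column
#' `sample`), one row per sample, cells in `0/0`, `0/1`, `1/1`, `./.`.
#' `"vcf"`: a VCF 4.x file with GT fields; multi-allelic sites are skipped
#' with a warning. Loci are aligned to the map by SNP id: map loci absent
#' from the file become missing; file loci absent from the map are dropped
#' (count reported via `message`).
#'
#' @param path input file.
#' @param map a [GeneticMap-class].
#' @param format `"tsv"`, `"vcf"` or `"auto"` (by file extension).
#' @return a [DiploidGenotypes-class].
#' @export
readGenotypes <- function(path, map, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character")
    samples <- tab[[1L]]
    snps <- colnames(tab)[-1L]
    cells <- as.matrix(tab[, -1L, drop = FALSE])
    dmat <- matrix(.gtToDosage(cells), nrow = nrow(cells),
                   dimnames = list(samples, snps))
    dmat <- t(dmat)                       # loci x samples
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    bi <- vcfR::is.biallelic(v)
    if (any(!bi)) {
      warning(sum(!bi), " multi-allelic site(s) skipped")
      v <- v[bi, ]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    dmat <- matrix(.gtToDosage(gt), nrow = nrow(gt), dimnames = dimnames(gt))
  }
  hit <- intersect(rownames(dmat), map@snp)
  if (!length(hit))
    stop("no SNP ids shared between ", path, " and the map")
  dropped <- nrow(dmat) - length(hit)
  if (dropped > 0L)
    message(dropped, " locus/loci absent from the map dropped")
  full <- matrix(NA_integer_, nrow = nLoci(map), ncol = ncol(dmat),
                 dimnames = list(map@snp, colnames(dmat)))
  full[hit, ] <- dmat[hit, ]
  DiploidGenotypes(map, full)
}

#' Write genotypes as the package's TSV dialect
#'
#' @param g a [DiploidGenotypes-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypesTSV <- function(g, path) {
  d <- dosageMatrix(g)
  cells <- matrix(.dosageToGt(d), nrow = nrow(d), dimnames = dimnames(d))
  tab <- cbind(sample = colnames(d), as.data.frame(t(cells)))
  utils::write.table(tab, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal plain-text VCF 4.2
#'
#' Alleles are written as REF=A, ALT=G placeholders (allele identity is
#' coded 0/1 throughout the package); positions come from the map's bp
#' column, falling back to round(cM * 1e6) + 1 when absent.
#'
#' @param g a [DiploidGenotypes-class].
#' @param path output path (plain text).
#' @param phased unused for unphased genotypes; kept for symmetry with
#'   [writePanelVCF()].
#' @return `path`, invisibly.
#' @export
writeGenotypesVCF <- function(g, path, phased = FALSE) {
  map <- geneticMap(g)
  d <- dosageMatrix(g)
  pos <- ifelse(is.na(map@bp), as.integer(round(map@cM * 1e6)) + 1L, map@bp)
  body <- matrix(.dosageToGt(d, sep = if (phased) "|" else "/"),
                 nrow = nrow(d))
  lines <- c("##fileformat=VCFv4.2",
             paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                    paste(colnames(d), collapse = "\t")),
             paste(map@chrom, pos, map@snp, "A", "G", ".", ".", ".", "GT",
                   apply(body, 1L, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Genotype call rate of a sample
#'
#' Fraction of map loci with a non-missing call; samples below a quality
#' threshold (0.99 by convention for array data) should be excluded by the
#' caller before kinship analysis.
#'
#' @param g a [DiploidGenotypes-class].
#' @param sample sample id.
#' @return fraction in \[0, 1\].
#' @export
callRate <- function(g, sample) {
  if (!sample %in% sampleIds(g))
    stop("unknown sample: ", sample)
  mean(!is.na(dosageMatrix(g)[, sample]))
}
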