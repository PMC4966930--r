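# IBS state tracks, shared-segment detection and ICS computation.
#
# The index of chromosome sharing (ICS) between two individuals is the sum
# of the genetic lengths (cM) of their shared IBS segments longer than a
# threshold Th. A shared segment is a maximal run of >= 2 consecutive called
# loci with IBS state 1 or 2 on one chromosome; its length is the cM
# distance between its first and last locus. Runs of a single locus
# ("isolated sharing") are never segments. Loci uncalled in either
# individual are removed before run detection, so a run may bridge them.

# IBS state from dosages: size of the maximum matching between two
# unordered allele pairs. For biallelic dosage a, b this is 2 - |a - b|.
.ibsFromDosage <- function(a, b) 2L - abs(a - b)

#' Per-locus IBS states between two individuals
#'
#' The IBS state at a locus is 0, 1 or 2: the number of alleles that can be
#' matched between the two unordered genotypes (e.g. AA vs AA -> 2,
#' AA vs AB -> 1, AA vs BB -> 0, AB vs AB -> 2). Loci uncalled in either
#' sample are excluded from the track and ignored in all downstream
#' analysis.
#'
#' @param x a [DiploidGenotypes-class] holding `sampleA` (and `sampleB`
#'   when `y` is not given).
#' @param sampleA,sampleB sample ids.
#' @param y optional second [DiploidGenotypes-class] holding `sampleB`;
#'   must carry a map identical to `x`'s.
#' @return an [IbsTrack-class].
#' @examples
#' m <- makeSyntheticMap(2, 20, c(50, 40), seed = 1)
#' p <- makeHaplotypePanel(m, 4, seed = 2)
#' g <- panelGenotypes(p)
#' ibsStates(g, sampleIds(g)[1], sampleIds(g)[2])
#' @export
ibsStates <- function(x, sampleA, sampleB, y = x) {
  mapX <- geneticMap(x); mapY <- geneticMap(y)
  if (!identical(mapX@snp, mapY@snp) || !identical(mapX@cM, mapY@cM))
    stop("samples are aligned to different maps")
  if (!sampleA %in% sampleIds(x)) stop("unknown sample: ", sampleA)
  if (!sampleB %in% sampleIds(y)) stop("unknown sample: ", sampleB)
  a <- dosageMatrix(x)[, sampleA]
  b <- dosageMatrix(y)[, sampleB]
  keep <- unname(which(!is.na(a) & !is.na(b)))
  new("IbsTrack",
      state = unname(.ibsFromDosage(a[keep], b[keep])),
      locusIndex = keep,
      chrom = mapX@chrom[keep],
      samples = c(sampleA, sampleB))
}

setMethod("show", "IbsTrack", function(object) {
  cat(sprintf("IbsTrack %s vs %s: %d called loci (IBS2 %.3f, IBS1 %.3f, IBS0 %.3f)\n",
              object@samples[1L], object@samples[2L], length(object@state),
              mean(object@state == 2L), mean(object@state == 1L),
              mean(object@state == 0L)))
})

#' Detect shared IBS segments
#'
#' Maximal runs of consecutive retained loci with IBS state >= 1, within a
#' chromosome; single-locus runs (isolated sharing) are discarded. Segment
#' length is the cM difference between its first and last SNP.
#'
#' @param track an [IbsTrack-class].
#' @param map the [GeneticMap-class] the track was computed on.
#' @return data.frame with columns `chrom`, `firstSnp`, `lastSnp`,
#'   `firstIndex`, `lastIndex`, `nSnps`, `lengthCM`, in map order.
#' @export
detectSharedSegments <- function(track, map) {
  stopifnot(is(track, "IbsTrack"), is(map, "GeneticMap"))
  n <- length(track@state)
  empty <- data.frame(chrom = character(), firstSnp = character(),
                      lastSnp = character(), firstIndex = integer(),
                      lastIndex = integer(), nSnps = integer(),
                      lengthCM = numeric())
  if (n == 0L) return(empty)
  shared <- track@state >= 1L
  # run ids: break on sharing change OR chromosome change
  newRun <- c(TRUE, shared[-1L] != shared[-n] |
                    track@chrom[-1L] != track@chrom[-n])
  runId <- cumsum(newRun)
  starts <- which(newRun)
  ends <- c(starts[-1L] - 1L, n)
  keep <- shared[starts] & (ends - starts >= 1L)
  if (!any(keep)) return(empty)
  s <- starts[keep]; e <- ends[keep]
  fi <- track@locusIndex[s]; li <- track@locusIndex[e]
  data.frame(chrom = track@chrom[s],
             firstSnp = map@snp[fi], lastSnp = map@snp[li],
             firstIndex = fi, lastIndex = li,
             nSnps = e - s + 1L,
             lengthCM = map@cM[li] - map@cM[fi])
}

#' Sum segment lengths above a threshold: ics(Th)
#'
#' @param segments data.frame from [detectSharedSegments()].
#' @param th threshold in cM; only segments strictly longer than `th`
#'   contribute.
#' @return summed cM length.
#' @export
icsFromSegments <- function(segments, th) {
  if (length(th) != 1L || is.na(th) || th < 0)
    stop("threshold must be a single non-negative cM value")
  sum(segments$lengthCM[segments$lengthCM > th])
}

#' ICS between two samples
#'
#' Composition of [ibsStates()], [detectSharedSegments()] and
#' [icsFromSegments()].
#'
#' @inheritParams ibsStates
#' @param th segment-length threshold in cM (C-Th or L-Th after
#'   calibration).
#' @param group `"C"`, `"L"` or `""` (annotation only).
#' @return an [IcsValue-class].
#' @export
icsPair <- function(x, sampleA, sampleB, th, group = "", y = x) {
  track <- ibsStates(x, sampleA, sampleB, y)
  segs <- detectSharedSegments(track, geneticMap(x))
  new("IcsValue", value = icsFromSegments(segs, th),
      threshold = as.numeric(th), group = group)
}

setMethod("show", "IcsValue", function(object) {
  g <- if (nzchar(object@group)) paste0("_", object@group) else ""
  cat(sprintf("ICS%s = %.3f cM (Th = %g cM)\n", g, object@value,
              object@threshold))
})

#' Numeric value of an IcsValue
#' @param x an [IcsValue-class].
#' @return plain numeric.
#' @export
icsValue <- function(x) x@value

#' Export shared segments as BED-like TSV
#'
#' @param segments data.frame from [detectSharedSegments()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSegmentsTSV <- function(segments, path) {
  utils::write.table(
    segments[, c("chrom", "firstSnp", "lastSnp", "nSnps", "lengthCM")],
    path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}
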