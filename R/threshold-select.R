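# Threshold calibration: sweep ics(Th) over a grid, compute ROC AUCs
# between adjacent relationship classes and pick the Th maximizing the
# mean AUC (C-Th for collateral, L-Th for lineal relatives).

#' Mann-Whitney AUC
#'
#' Probability that a score drawn from `closer` exceeds one drawn from
#' `farther`, counting ties as 1/2 (midrank estimator). Higher ICS is
#' expected for closer relationships.
#'
#' @param closer,farther numeric score vectors (both nonempty).
#' @return AUC in \[0, 1\].
#' @export
aucMannWhitney <- function(closer, farther) {
  nx <- length(closer); ny <- length(farther)
  if (nx == 0L || ny == 0L) stop("both score vectors must be nonempty")
  r <- rank(c(closer, farther))
  (sum(r[seq_len(nx)]) - nx * (nx + 1) / 2) / (nx * ny)
}

#' Compute ics(Th) over a threshold grid for labelled pairs
#'
#' Shared segments are detected once per pair and re-thresholded across the
#' grid. The default grid is 0..63 cM in 1 cM steps, spanning from no
#' filtering up to the genetic length of the shortest chromosome; a grid
#' exceeding the shortest chromosome triggers a warning.
#'
#' @param cohort a [KinCohort-class], or a [DiploidGenotypes-class] when
#'   `pairs` is supplied.
#' @param thGrid ascending cM thresholds.
#' @param pairs optional pair table (`relationship`, `sampleA`, `sampleB`);
#'   defaults to the cohort's own.
#' @return an [IcsSweep-class].
#' @export
icsSweep <- function(cohort, thGrid = 0:63, pairs = NULL) {
  if (is(cohort, "KinCohort")) {
    g <- cohortGenotypes(cohort)
    pairs <- pairs %||% relationshipPairs(cohort)
  } else {
    g <- cohort
    if (is.null(pairs)) stop("pairs table required with raw genotypes")
  }
  map <- geneticMap(g)
  thGrid <- sort(unique(as.numeric(thGrid)))
  if (max(thGrid) > min(chromosomeLengths(map)))
    warning("threshold grid exceeds the shortest chromosome (",
            round(min(chromosomeLengths(map)), 2), " cM)")
  rels <- unique(pairs$relationship)
  values <- lapply(rels, function(rel) {
    sub <- pairs[pairs$relationship == rel, , drop = FALSE]
    m <- matrix(vapply(seq_len(nrow(sub)), function(i) {
      segs <- detectSharedSegments(
        ibsStates(g, sub$sampleA[i], sub$sampleB[i]), map)
      vapply(thGrid, function(th) icsFromSegments(segs, th), numeric(1))
    }, numeric(length(thGrid))), ncol = length(thGrid), byrow = TRUE)
    colnames(m) <- as.character(thGrid)
    m
  })
  names(values) <- rels
  new("IcsSweep", thGrid = thGrid, values = values)
}

#' ics(Th) matrices of a sweep
#' @param sweep an [IcsSweep-class].
#' @param relationship optional label.
#' @return named list of matrices, or one matrix.
#' @export
sweepValues <- function(sweep, relationship = NULL) {
  if (is.null(relationship)) sweep@values else sweep@values[[relationship]]
}

setMethod("show", "IcsSweep", function(object) {
  cat(sprintf("IcsSweep: %d relationships x %d thresholds (%g..%g cM)\n",
              length(object@values), length(object@thGrid),
              min(object@thGrid), max(object@thGrid)))
})

.comparisonChain <- function(group) {
  switch(group,
         C = c("C-1", "C-2", "C-3", "C-4", "C-5", "UN"),
         L = c("L-1", "L-2", "L-3", "UN"),
         stop('group must be "C" or "L"'))
}

#' Select the segment-length threshold by mean AUC
#'
#' For the collateral group the mean of five adjacent-comparison AUCs
#' (C-1 vs C-2, ..., C-5 vs UN) is computed per threshold; for the lineal
#' group the mean of three (L-1 vs L-2, L-2 vs L-3, L-3 vs UN). The
#' threshold attaining the maximum mean AUC is selected, ties broken to
#' the smallest threshold.
#'
#' @param sweep an [IcsSweep-class] containing every class of the group.
#' @param group `"C"` or `"L"`.
#' @return a [ThresholdResult-class].
#' @export
selectThreshold <- function(sweep, group = c("C", "L")) {
  group <- match.arg(group)
  chain <- .comparisonChain(group)
  missing <- setdiff(chain, names(sweep@values))
  if (length(missing))
    stop("sweep is missing relationship class(es): ",
         paste(missing, collapse = ", "))
  nTh <- length(sweep@thGrid)
  comps <- paste(chain[-length(chain)], chain[-1L], sep = " vs ")
  auc <- matrix(NA_real_, nrow = length(comps), ncol = nTh,
                dimnames = list(comps, as.character(sweep@thGrid)))
  for (k in seq_along(comps)) {
    a <- sweep@values[[chain[k]]]
    b <- sweep@values[[chain[k + 1L]]]
    auc[k, ] <- vapply(seq_len(nTh), function(j)
      aucMannWhitney(a[, j], b[, j]), numeric(1))
  }
  meanAuc <- colMeans(auc)
  sel <- sweep@thGrid[which.max(meanAuc)]  # first max = smallest Th on ties
  new("ThresholdResult", group = group, thGrid = sweep@thGrid,
      componentAuc = auc, meanAuc = unname(meanAuc), selectedTh = sel)
}

#' Selected threshold of a ThresholdResult
#' @param x a [ThresholdResult-class].
#' @return cM threshold.
#' @export
selectedTh <- function(x) x@selectedTh

setMethod("show", "ThresholdResult", function(object) {
  i <- which(object@thGrid == object@selectedTh)
  cat(sprintf("%s-Th = %g cM (mean AUC %.4f over %d comparisons)\n",
              object@group, object@selectedTh, object@meanAuc[i],
              nrow(object@componentAuc)))
})
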