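# Probabilistic evaluation of a pair's relationship from its ICS value:
# likelihood ratios against the unrelated hypothesis, Bayesian posteriors
# over the competing relationships (flat priors by default), Hummel
# verbal predicates, and the ICS ranges / probability masses of each
# predicate band. All density arithmetic is done in log space: likelihood
# ratios against UN routinely reach 10^50 and beyond.

#' Construct a HypothesisSet
#'
#' Competing relationship hypotheses with priors. The standard sets are
#' C-1..C-5 + UN for collateral analysis and L-2, L-3 + UN for lineal
#' analysis (parent-child, L-1, is decided by [l1Precheck()] before any
#' density is evaluated); arbitrary sets of >= 2 hypotheses are accepted.
#'
#' @param fits named list of [FittedDistribution-class] (names are the
#'   hypothesis labels).
#' @param priors optional named prior probabilities; default flat `1/n`.
#' @param group `"C"`, `"L"` or `""`.
#' @return a [HypothesisSet-class].
#' @export
hypothesisSet <- function(fits, priors = NULL, group = "") {
  if (length(fits) < 2L) stop("at least 2 hypotheses are required")
  if (is.null(priors))
    priors <- stats::setNames(rep(1 / length(fits), length(fits)),
                              names(fits))
  new("HypothesisSet", group = group, fits = fits,
      priors = priors[names(fits)])
}

setMethod("show", "HypothesisSet", function(object) {
  cat(sprintf("HypothesisSet (%s): %s\n",
              if (nzchar(object@group)) object@group else "ad hoc",
              paste(names(object@fits), collapse = ", ")))
})

#' Likelihood ratio between two relationship hypotheses
#'
#' `LR = f(ICS | H1) / f(ICS | H2)`, computed from log densities. If the
#' denominator underflows to zero density while the numerator is positive
#' the LR is `+Inf` (flagged); if both densities are zero the LR is
#' undefined and an error is raised.
#'
#' @param ics ICS value (numeric or [IcsValue-class]).
#' @param h1,h2 [FittedDistribution-class] for the two hypotheses.
#' @return list with `lr`, `log10Lr`, `infinite` flag.
#' @export
likelihoodRatio <- function(ics, h1, h2) {
  x <- if (is(ics, "IcsValue")) icsValue(ics) else as.numeric(ics)
  l1 <- densityICS(h1, x, log = TRUE)
  l2 <- densityICS(h2, x, log = TRUE)
  if (!is.finite(l1) && !is.finite(l2))
    stop("both densities are zero at ICS = ", x, ": LR undefined")
  d <- l1 - l2
  lr <- exp(d)
  list(lr = lr, log10Lr = d / log(10), infinite = is.infinite(lr))
}

#' Hummel predicate for a posterior probability
#'
#' Verbal scale: "practically proven" (>= 0.998), "highly likely"
#' (\[0.99, 0.998)), "very likely" (\[0.95, 0.99)), "likely"
#' (\[0.90, 0.95)), "undetermined" (< 0.90). The bands partition \[0, 1\].
#'
#' @param p posterior probability (vectorized).
#' @return character predicates.
#' @export
hummelPredicate <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  out <- character(length(p))
  out[p < 0.90] <- "undetermined"
  out[p >= 0.90 & p < 0.95] <- "likely"
  out[p >= 0.95 & p < 0.99] <- "very likely"
  out[p >= 0.99 & p < 0.998] <- "highly likely"
  out[p >= 0.998] <- "practically proven"
  out
}

# log-density matrix (length(x) x n hypotheses)
.logDensMatrix <- function(hs, x) {
  matrix(vapply(hs@fits, function(f) densityICS(f, x, log = TRUE),
                numeric(length(x))),
         nrow = length(x), ncol = length(hs@fits),
         dimnames = list(NULL, names(hs@fits)))
}

# posterior matrix with max-subtraction; rows with all -Inf become NA
.posteriorMatrix <- function(hs, x) {
  ld <- .logDensMatrix(hs, x) +
    matrix(log(hs@priors), nrow = length(x), ncol = length(hs@priors),
           byrow = TRUE)
  colnames(ld) <- names(hs@fits)
  mx <- apply(ld, 1L, max)
  w <- exp(ld - mx)
  w[!is.finite(mx), ] <- NA_real_
  w / rowSums(w)
}

#' Posterior probabilities over competing relationships
#'
#' Bayes' theorem over the hypothesis set:
#' `Pr(Hi | ICS) = f(ICS | Hi) Pr(Hi) / sum_j f(ICS | Hj) Pr(Hj)`,
#' reducing to a pure density ratio under flat priors. Computation is in
#' log space with max-subtraction. The verdict is the highest-posterior
#' hypothesis together with its Hummel predicate; when UN is among the
#' hypotheses, log10 LRs of each related hypothesis against UN are also
#' reported.
#'
#' @param ics ICS value (numeric or [IcsValue-class]).
#' @param hs a [HypothesisSet-class].
#' @return a [KinshipResult-class].
#' @export
posteriorProbs <- function(ics, hs) {
  iv <- if (is(ics, "IcsValue")) ics
        else new("IcsValue", value = as.numeric(ics), threshold = 0,
                 group = hs@group %||% "")
  x <- icsValue(iv)
  ld <- .logDensMatrix(hs, x)[1L, ]
  if (all(!is.finite(ld)))
    stop("all hypothesis densities are zero at ICS = ", x,
         "; check the parent-child pre-check (l1Precheck) or the ICS range")
  post <- .posteriorMatrix(hs, x)[1L, ]
  names(post) <- names(hs@fits)
  lr10 <- numeric(0)
  if ("UN" %in% names(hs@fits)) {
    others <- setdiff(names(hs@fits), "UN")
    lr10 <- vapply(others, function(h)
      (ld[h] - ld["UN"]) / log(10), numeric(1))
  }
  best <- names(post)[which.max(post)]
  new("KinshipResult", ics = iv, logDensities = ld, posteriors = post,
      log10LrVsUN = lr10, bestHypothesis = best,
      predicate = hummelPredicate(max(post)))
}

setMethod("show", "KinshipResult", function(object) {
  cat(sprintf("KinshipResult: ICS = %.3f cM\n", icsValue(object@ics)))
  for (h in names(object@posteriors))
    cat(sprintf("  Pr(%s | ICS) = %.6f%s\n", h, object@posteriors[h],
                if (h %in% names(object@log10LrVsUN))
                  sprintf("  [log10 LR vs UN = %.2f]",
                          object@log10LrVsUN[h]) else ""))
  cat(sprintf("  verdict: %s (%s)\n", object@bestHypothesis,
              object@predicate))
})

#' Posterior probabilities of a KinshipResult
#' @param x a [KinshipResult-class].
#' @return named numeric.
#' @export
posteriors <- function(x) x@posteriors

#' Parent-child pre-check
#'
#' Parent-child pairs share at least one allele at every locus, so their
#' ICS is pinned at the total map length and completely separated from all
#' other relationships; they are decided deterministically rather than
#' through a fitted density. Returns `TRUE` when the fraction of retained
#' loci with IBS state >= 1 exceeds `1 - tolerance`; the default tolerance
#' of 1e-3 absorbs occasional array typing errors in real data.
#'
#' @param track an [IbsTrack-class].
#' @param tolerance allowed fraction of IBS-0 loci.
#' @return logical.
#' @export
l1Precheck <- function(track, tolerance = 1e-3) {
  if (length(track@state) == 0L) stop("empty IBS track")
  mean(track@state >= 1L) > 1 - tolerance
}

#' ICS ranges of each Hummel predicate for a target relationship
#'
#' Scans ICS over `[0, icsMax]` at `gridStep`, computes the posterior of
#' `target` at every grid point and merges consecutive points falling in
#' the same predicate band into intervals (band edges at midpoints between
#' adjacent grid points).
#'
#' @param hs a [HypothesisSet-class].
#' @param target hypothesis label.
#' @param icsMax upper end of the scan, typically [totalMapLength()].
#' @param gridStep scan step in cM (default 0.1).
#' @return data.frame with `predicate`, `lower`, `upper` (cM intervals in
#'   ascending order).
#' @export
predicateRanges <- function(hs, target, icsMax, gridStep = 0.1) {
  if (gridStep <= 0) stop("gridStep must be > 0")
  if (!target %in% names(hs@fits)) stop("unknown hypothesis: ", target)
  x <- seq(gridStep, icsMax, by = gridStep)
  post <- .posteriorMatrix(hs, x)[, target]
  band <- rep(NA_character_, length(x))
  ok <- !is.na(post)
  band[ok] <- hummelPredicate(post[ok])
  r <- rle(band)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  lower <- c(0, (x[ends[-length(ends)]] + x[starts[-1L]]) / 2)
  upper <- c(lower[-1L], icsMax)
  out <- data.frame(predicate = r$values, lower = lower, upper = upper)
  out[!is.na(out$predicate), , drop = FALSE]
}

#' Probability mass of a target's distribution within a posterior band
#'
#' The fraction of the target relationship's own fitted distribution lying
#' where its posterior probability meets `threshold`:
#' integral of `f(x | target) * 1[Pr(target | x) >= threshold] dx` over
#' `[0, icsMax]`. Qualifying intervals are located by a grid scan with
#' endpoints refined by root finding, then integrated by adaptive
#' quadrature.
#'
#' @param hs a [HypothesisSet-class].
#' @param target hypothesis label.
#' @param threshold posterior threshold in (0, 1\].
#' @param icsMax upper end of the ICS domain.
#' @param gridStep scan step in cM.
#' @return probability mass in \[0, 1\].
#' @export
predicateMass <- function(hs, target, threshold, icsMax, gridStep = 0.1) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (!target %in% names(hs@fits)) stop("unknown hypothesis: ", target)
  x <- seq(gridStep, icsMax, by = gridStep)
  post <- .posteriorMatrix(hs, x)[, target]
  post[is.na(post)] <- 0
  qual <- post >= threshold
  if (!any(qual)) return(0)
  postAt <- function(z) .posteriorMatrix(hs, z)[, target]
  g <- function(z) postAt(z) - threshold
  runs <- rle(qual)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  fit <- hs@fits[[target]]
  mass <- 0
  for (k in which(runs$values)) {
    loIdx <- starts[k]; hiIdx <- ends[k]
    lo <- if (loIdx == 1L) 0 else
      stats::uniroot(g, c(x[loIdx - 1L], x[loIdx]), tol = 1e-10)$root
    hi <- if (hiIdx == length(x)) icsMax else
      stats::uniroot(g, c(x[hiIdx], x[hiIdx + 1L]), tol = 1e-10)$root
    if (hi > lo)
      mass <- mass + stats::integrate(function(z) densityICS(fit, z),
                                      lo, hi, rel.tol = 1e-8,
                                      subdivisions = 500L)$value
  }
  mass
}

#' End-to-end classification of one pair
#'
#' Computes the IBS track, applies the parent-child pre-check for the
#' lineal group, computes the ICS at the supplied threshold and evaluates
#' posteriors over the hypothesis set. A pair passing the pre-check is
#' returned with posterior 1 on `L-1` (deterministic verdict, no density
#' involved).
#'
#' @inheritParams ibsStates
#' @param hs a [HypothesisSet-class].
#' @param th segment-length threshold in cM (the calibrated C-Th or L-Th).
#' @param group `"C"` or `"L"`.
#' @param l1Tolerance tolerance for [l1Precheck()] (lineal group only).
#' @return a [KinshipResult-class].
#' @export
classifyPair <- function(x, sampleA, sampleB, hs, th, group = c("C", "L"),
                         y = x, l1Tolerance = 1e-3) {
  group <- match.arg(group)
  track <- ibsStates(x, sampleA, sampleB, y)
  map <- geneticMap(x)
  segs <- detectSharedSegments(track, map)
  iv <- new("IcsValue", value = icsFromSegments(segs, th),
            threshold = as.numeric(th), group = group)
  if (group == "L" && l1Precheck(track, l1Tolerance)) {
    post <- stats::setNames(c(1, rep(0, length(hs@fits))),
                            c("L-1", names(hs@fits)))
    return(new("KinshipResult", ics = iv,
               logDensities = stats::setNames(numeric(0), character(0)),
               posteriors = post, log10LrVsUN = numeric(0),
               bestHypothesis = "L-1", predicate = "practically proven"))
  }
  posteriorProbs(iv, hs)
}
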