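# One-call calibration: sweep -> threshold selection (with a
# fit-feasibility guard) -> per-relationship log-normal/AIC fitting ->
# hypothesis sets ready for classification.

#' Largest fit-feasible threshold not exceeding the AUC-optimal one
#'
#' Distribution fitting requires (nearly) all ICS values of every fitted
#' class to be positive: log-normal support excludes 0, and more than 5%
#' of exact zeros in a class aborts the fit. At reduced SNP density the
#' mean-AUC curve of a group can be almost flat, letting the argmax drift
#' to large thresholds where unrelated pairs lose every segment. This
#' guard walks the grid down from the selected threshold to the largest
#' value at which every class of the group's fitting set keeps its
#' zero-ICS fraction at or below `maxZeroFrac` (falling back to the
#' smallest grid value).
#'
#' @param sweep an [IcsSweep-class].
#' @param result a [ThresholdResult-class] for the group.
#' @param maxZeroFrac maximum tolerated fraction of zero ICS values.
#' @return a cM threshold from the sweep grid.
#' @export
feasibleThreshold <- function(sweep, result, maxZeroFrac = 0.05) {
  classes <- switch(result@group,
                    C = c("C-1", "C-2", "C-3", "C-4", "C-5", "UN"),
                    L = c("L-2", "L-3", "UN"))
  ok <- function(th) {
    col <- match(th, sweep@thGrid)
    all(vapply(classes, function(r)
      mean(sweep@values[[r]][, col] == 0) <= maxZeroFrac, logical(1)))
  }
  for (th in rev(sweep@thGrid[sweep@thGrid <= result@selectedTh]))
    if (ok(th)) return(th)
  sweep@thGrid[1L]
}

#' Calibrate thresholds and ICS distributions from a simulated cohort
#'
#' Runs the full calibration pipeline on a gene-dropped cohort: an
#' ics(Th) sweep over `thGrid`, AUC-based selection of C-Th and L-Th
#' (each adjusted by [feasibleThreshold()]), maximum-likelihood fitting
#' of the three candidate families per relationship with AIC selection
#' per group, and assembly of flat-prior hypothesis sets.
#'
#' @param cohort a [KinCohort-class].
#' @param thGrid threshold grid in cM (default 0..63, 1 cM steps).
#' @param maxZeroFrac passed to [feasibleThreshold()].
#' @return list with elements `sweep`, `thC`, `thL`, `thresholdC`,
#'   `thresholdL` ([ThresholdResult-class]), `selectionC`, `selectionL`
#'   ([ModelSelection-class]), `hsC`, `hsL` ([HypothesisSet-class]) and
#'   `icsMax` (total map length).
#' @examples
#' \donttest{
#' map <- makeSyntheticMap(seed = 1)
#' panel <- makeHaplotypePanel(map, 120, seed = 2)
#' cohort <- simulateCohort(panel, 20, seed = 3)
#' cal <- calibrateKinship(cohort)
#' cal$thC
#' }
#' @export
calibrateKinship <- function(cohort, thGrid = 0:63, maxZeroFrac = 0.05) {
  sw <- icsSweep(cohort, thGrid = thGrid)
  resC <- selectThreshold(sw, "C")
  resL <- selectThreshold(sw, "L")
  thC <- feasibleThreshold(sw, resC, maxZeroFrac)
  thL <- feasibleThreshold(sw, resL, maxZeroFrac)
  icsMax <- totalMapLength(geneticMap(cohort))
  valsAt <- function(th, classes) {
    out <- lapply(classes, function(r) sw@values[[r]][, as.character(th)])
    names(out) <- classes
    out
  }
  selC <- selectModel(valsAt(thC, c("C-1", "C-2", "C-3", "C-4", "C-5",
                                    "UN")),
                      "C", upper = icsMax)
  selL <- selectModel(valsAt(thL, c("L-2", "L-3", "UN")), "L",
                      upper = icsMax)
  list(sweep = sw, thC = thC, thL = thL,
       thresholdC = resC, thresholdL = resL,
       selectionC = selC, selectionL = selL,
       hsC = hypothesisSet(chosenFits(selC), group = "C"),
       hsL = hypothesisSet(chosenFits(selL), group = "L"),
       icsMax = icsMax)
}
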