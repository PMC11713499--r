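.maskedDose <- function(dose, mask) {
  .stopIfIncompatible(dose, mask, "dose and structure mask")
  sel <- values(mask)
  if (!any(sel))
    stop("structure absent: mask '", maskName(mask), "' is empty")
  values(dose)[sel]
}

#' Cumulative dose-volume histogram for one structure
#'
#' Bins the voxel doses inside the mask and returns the cumulative curve:
#' the fraction of the structure volume receiving at least each dose edge.
#' Structure membership is by voxel center (no partial-volume weighting);
#' voxel volume is the product of the grid spacings.
#'
#' @param dose dose [ScalarVolume-class] in Gy.
#' @param mask structure [BinaryMask-class], grid-compatible and nonempty.
#' @param binWidth histogram bin width in Gy.
#' @return A [DVHCurve-class]. The curve is 1 at dose 0 and 0 beyond the
#'   maximum voxel dose.
#' @examples
#' d <- ScalarVolume(array(c(2, 4), c(2, 1, 1)), unit = "Gy")
#' m <- BinaryMask("PTV", array(TRUE, c(2, 1, 1)))
#' computeDVH(d, m, binWidth = 1)
#' @export
computeDVH <- function(dose, mask, binWidth = 0.01) {
  stopifnot(binWidth > 0)
  dv <- .maskedDose(dose, mask)
  edges <- seq(0, max(dv) + binWidth, by = binWidth)
  # fraction of voxels with dose >= edge
  frac <- vapply(edges, function(e) mean(dv >= e), numeric(1))
  new("DVHCurve", structure = maskName(mask), doseEdges = edges,
      cumulativeVolumeFraction = frac,
      totalVolume = length(dv) * prod(spacing(mask)) / 1000)
}

#' Summary dose metrics for one structure
#'
#' D-mean is the mean voxel dose in the structure; D-max the single maximum
#' point dose; `V` at isodose fraction `f` is the percent of structure
#' volume receiving at least `f * prescription`.
#'
#' @inheritParams computeDVH
#' @param prescription prescribed dose, Gy (> 0).
#' @param isodoseFractions numeric vector of isodose fractions (of the
#'   prescription) at which to evaluate V; defaults to the 93%, 100% and
#'   110% levels used for target-coverage reporting.
#' @return A [DoseMetrics-class].
#' @export
doseMetrics <- function(dose, mask, prescription,
                        isodoseFractions = c(0.93, 1, 1.1)) {
  stopifnot(prescription > 0)
  dv <- .maskedDose(dose, mask)
  vAt <- vapply(isodoseFractions,
                function(f) 100 * mean(dv >= f * prescription), numeric(1))
  names(vAt) <- as.character(isodoseFractions)
  new("DoseMetrics", structure = maskName(mask), dMean = mean(dv),
      dMax = max(dv), vAt = vAt, prescription = prescription)
}

#' Difference reference vs evaluated dose metrics
#'
#' For each metric (D-mean, D-max and every V level), reports the absolute
#' difference (evaluated minus reference) and the normalized difference
#' `100 * (evaluated - reference) / reference` in percent. Where the
#' reference value is below `eps` the normalized difference is undefined
#' and flagged `NA` rather than fabricated (this happens routinely for
#' V110% when neither plan has hot spots).
#'
#' @param reference,evaluated [DoseMetrics-class] for the same structure
#'   and isodose fractions (reference = planning CT, evaluated = synthetic
#'   CT).
#' @param eps reference magnitude below which the normalized difference is
#'   undefined.
#' @return A data.frame with columns `metric`, `reference`, `evaluated`,
#'   `difference`, `normalizedDifferencePct` (NA when undefined).
#' @export
diffMetrics <- function(reference, evaluated, eps = 1e-9) {
  if (!identical(names(reference@vAt), names(evaluated@vAt)) ||
      reference@structure != evaluated@structure)
    stop("metrics must cover the same structure and isodose fractions")
  metric <- c("dMean", "dMax", paste0("V", names(reference@vAt)))
  ref <- c(reference@dMean, reference@dMax, unname(reference@vAt))
  ev <- c(evaluated@dMean, evaluated@dMax, unname(evaluated@vAt))
  dif <- ev - ref
  nd <- ifelse(abs(ref) > eps, 100 * dif / ref, NA_real_)
  data.frame(metric = metric, reference = ref, evaluated = ev,
             difference = dif, normalizedDifferencePct = nd,
             row.names = NULL)
}
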