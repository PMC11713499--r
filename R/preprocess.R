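#' Zero out voxels outside the body contour
#'
#' Removes couch and immobilization accessories from a planning CT by
#' assigning a constant HU to every voxel outside the BODY mask. The
#' default outside value is 0 HU (water-equivalent), reproducing the common
#' accessory-removal convention; pass `outsideValue = -1000` for an
#' air-equivalent alternative (see the methods vignette for the trade-off).
#'
#' @param ct a CT [ScalarVolume-class].
#' @param body the BODY [BinaryMask-class], grid-compatible with `ct`.
#' @param outsideValue HU assigned outside the body (default 0).
#' @return A [ScalarVolume-class]; voxels inside BODY are unchanged.
#' @export
zeroOutsideBody <- function(ct, body, outsideValue = 0) {
  .stopIfIncompatible(ct, body, "ct and body mask")
  if (!any(values(body)))
    stop("degenerate body contour: BODY mask is empty")
  vals <- values(ct)
  vals[!values(body)] <- outsideValue
  ScalarVolume(vals, spacing = spacing(ct), origin = origin(ct),
               unit = ct@unit)
}

#' Align a synthetic CT onto the planning-CT grid
#'
#' The planning CT is returned unchanged; the synthetic CT is resampled
#' onto the planning grid through [resampleToReference()] (optionally via a
#' displacement field correcting positioning/organ-motion error), with the
#' HU floor clamped to -1000 so resampled air matches the planning CT.
#'
#' @param planning planning-CT [ScalarVolume-class] (defines the grid).
#' @param synthetic synthetic-CT [ScalarVolume-class] to resample.
#' @param dvf optional [VectorField-class] on the planning grid.
#' @param huFloor lower HU clamp and out-of-extent fill.
#' @return `list(planning =, synthetic =)`, both on the planning grid.
#' @export
alignPair <- function(planning, synthetic, dvf = NULL, huFloor = -1000) {
  list(planning = planning,
       synthetic = resampleToReference(synthetic, planning, dvf = dvf,
                                       floorValue = huFloor))
}
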