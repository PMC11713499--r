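#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(x) standardGeneric("voxelVolume"))
#' @rdname accessors
#' @export
setGeneric("voxelCount", function(x) standardGeneric("voxelCount"))
#' @rdname accessors
#' @export
setGeneric("maskName", function(x) standardGeneric("maskName"))
#' @rdname accessors
#' @export
setGeneric("passRate", function(x) standardGeneric("passRate"))
#' @rdname accessors
#' @export
setGeneric("gammaField", function(x) standardGeneric("gammaField"))
#' @rdname accessors
#' @export
setGeneric("analyzedVoxels", function(x) standardGeneric("analyzedVoxels"))

#' Accessors for sctQA data objects
#'
#' `values` returns the raw 3D array (numeric for [ScalarVolume-class],
#' logical for [BinaryMask-class]); `spacing` and `origin` the grid geometry
#' in mm; `voxelVolume` the volume of one voxel in mm^3; `voxelCount` the
#' number of `TRUE` voxels of a mask; `maskName` the structure label;
#' `passRate`, `gammaField` and `analyzedVoxels` the components of a
#' [GammaResult-class].
#'
#' @param x the object.
#' @return See details above.
#' @name accessors
#' @aliases values spacing origin voxelVolume voxelCount maskName passRate
#'   gammaField analyzedVoxels
NULL

#' @rdname accessors
setMethod("values", "ScalarVolume", function(x) x@values)
#' @rdname accessors
setMethod("values", "BinaryMask", function(x) x@values)
#' @rdname accessors
setMethod("spacing", "ScalarVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "BinaryMask", function(x) x@spacing)
#' @rdname accessors
setMethod("spacing", "VectorField", function(x) x@spacing)
#' @rdname accessors
setMethod("origin", "ScalarVolume", function(x) x@origin)
#' @rdname accessors
setMethod("origin", "BinaryMask", function(x) x@origin)
#' @rdname accessors
setMethod("origin", "VectorField", function(x) x@origin)
#' @rdname accessors
setMethod("voxelVolume", "ScalarVolume", function(x) prod(x@spacing))
#' @rdname accessors
setMethod("voxelVolume", "BinaryMask", function(x) prod(x@spacing))
#' @rdname accessors
setMethod("voxelCount", "BinaryMask", function(x) sum(x@values))
#' @rdname accessors
setMethod("maskName", "BinaryMask", function(x) x@name)
#' @rdname accessors
setMethod("passRate", "GammaResult", function(x) x@passRate)
#' @rdname accessors
setMethod("gammaField", "GammaResult", function(x) x@gammaField)
#' @rdname accessors
setMethod("analyzedVoxels", "GammaResult", function(x) x@analyzedVoxels)

setMethod("show", "ScalarVolume", function(object) {
  d <- dim(object@values)
  cat(sprintf("ScalarVolume [%s]: %d x %d x %d voxels, spacing %s mm\n",
              if (nzchar(object@unit)) object@unit else "unitless",
              d[1], d[2], d[3],
              paste(format(object@spacing, digits = 4), collapse = " x ")))
  cat(sprintf("  origin (%s) mm; range [%.6g, %.6g]\n",
              paste(format(object@origin, digits = 4), collapse = ", "),
              min(object@values), max(object@values)))
})

setMethod("show", "BinaryMask", function(object) {
  d <- dim(object@values)
  cat(sprintf("BinaryMask '%s': %d x %d x %d, %d voxels (%.2f cm^3)\n",
              object@name, d[1], d[2], d[3], sum(object@values),
              sum(object@values) * prod(object@spacing) / 1000))
})

setMethod("show", "CaseBundle", function(object) {
  d <- dim(object@planningCT@values)
  cat(sprintf("CaseBundle: %d x %d x %d grid, %d structures (%s)\n",
              d[1], d[2], d[3], length(object@structures),
              paste(names(object@structures), collapse = ", ")))
  cat(sprintf("  prescription %.4g Gy at the %.0f%% isodose level\n",
              object@prescriptionDose,
              100 * object@prescriptionIsodoseFraction))
})

setMethod("show", "GammaResult", function(object) {
  cr <- object@criteria
  cat(sprintf(
    "GammaResult %g%%/%g mm (%s): pass rate %.2f%% over %d voxels\n",
    cr@doseDiffPct, cr@dtaMm, cr@normalization, object@passRate,
    object@analyzedVoxels))
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf(
    "QualityReport (%d ROI voxels)\n  ME %.3f HU | MAE %.3f HU | RMSE %.3f HU | PSNR %s dB | SSIM %.4f\n",
    object@roiVoxels, object@me, object@mae, object@rmse,
    if (is.infinite(object@psnr)) "Inf" else sprintf("%.2f", object@psnr),
    object@ssim))
})

setMethod("show", "DVHCurve", function(object) {
  cat(sprintf(
    "DVHCurve '%s': %d edges up to %.3g Gy, volume %.3f cm^3\n",
    object@structure, length(object@doseEdges), max(object@doseEdges),
    object@totalVolume))
})

setMethod("show", "DoseMetrics", function(object) {
  cat(sprintf("DoseMetrics '%s': D-mean %.3f Gy, D-max %.3f Gy\n",
              object@structure, object@dMean, object@dMax))
  if (length(object@vAt))
    cat(sprintf("  V%%: %s\n",
                paste(sprintf("V%s=%.2f%%", names(object@vAt), object@vAt),
                      collapse = ", ")))
})

setMethod("show", "TestResult", function(object) {
  if (!object@applicable) {
    cat(sprintf("TestResult '%s': not applicable\n", object@testName))
  } else {
    cat(sprintf("TestResult '%s': statistic %.4g, p = %.4g (adj %.4g), n = %d\n",
                object@testName, object@statistic, object@pValue,
                object@pAdjusted, object@n))
  }
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("Spearman rS(%s, %s) = %.3f, p = %.4g\n",
              object@pair[1], object@pair[2], object@coefficient,
              object@pValue))
})
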