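#' @import methods
#' @importFrom stats sd cor rnorm runif setNames quantile
#' @useDynLib sctQA, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.EPS_GRID <- 1e-6  # mm tolerance for grid-compatibility checks

#' ScalarVolume: a 3D scalar grid with physical geometry
#'
#' The universal carrier for CT images (Hounsfield units) and dose grids (Gy).
#' Voxel indices are 0-based; the world position of the center of voxel
#' (0,0,0) is `origin`, and world = origin + index * spacing on the
#' axis-aligned grids this package supports.
#'
#' @slot values numeric 3D array, all finite.
#' @slot spacing numeric(3), per-axis physical step in mm, strictly positive.
#' @slot origin numeric(3), world position (mm) of the center of voxel (0,0,0).
#' @slot unit character scalar, `"HU"` or `"Gy"` (or `""` for dimensionless
#'   fields such as a gamma map).
#' @exportClass ScalarVolume
setClass("ScalarVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric",
                 unit = "character"),
  prototype(values = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0), unit = ""))

setValidity("ScalarVolume", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "'values' must be a 3D array")
  if (length(object@values) == 0L)
    msg <- c(msg, "'values' must be non-empty")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "'values' must be finite throughout")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 strictly positive finite numbers")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    msg <- c(msg, "'origin' must be 3 finite numbers")
  if (length(object@unit) != 1L)
    msg <- c(msg, "'unit' must be a single string")
  if (length(msg)) msg else TRUE
})

#' VectorField: a displacement vector field on a reference grid
#'
#' Displacements in mm, stored as a 4D array whose first three dimensions
#' match the companion reference grid and whose fourth dimension (length 3)
#' holds the x/y/z components. Semantics are pull/backward warping: the
#' displacement is added to a reference-grid world point to find the sampling
#' location in the moving volume.
#'
#' @slot displacements numeric 4D array `dim = c(nx, ny, nz, 3)`, finite.
#' @slot spacing,origin grid geometry, as for [ScalarVolume-class].
#' @exportClass VectorField
setClass("VectorField",
  representation(displacements = "array", spacing = "numeric",
                 origin = "numeric"),
  prototype(displacements = array(0, c(1, 1, 1, 3)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("VectorField", function(object) {
  d <- dim(object@displacements)
  msg <- character()
  if (length(d) != 4L || d[4] != 3L)
    msg <- c(msg, "'displacements' must be a 4D array with 3 components")
  if (!all(is.finite(object@displacements)))
    msg <- c(msg, "'displacements' must be finite")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive numbers")
  if (length(msg)) msg else TRUE
})

#' BinaryMask: a named boolean structure volume
#'
#' A boolean 3D volume on the same grid as a companion [ScalarVolume-class],
#' naming one structure (BODY, PTV, an organ at risk, ...).
#'
#' @slot name character structure label.
#' @slot values logical 3D array.
#' @slot spacing,origin grid geometry, as for [ScalarVolume-class].
#' @exportClass BinaryMask
setClass("BinaryMask",
  representation(name = "character", values = "array", spacing = "numeric",
                 origin = "numeric"),
  prototype(name = "mask", values = array(FALSE, c(1, 1, 1)),
            spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L || !is.logical(object@values))
    msg <- c(msg, "'values' must be a logical 3D array")
  if (length(object@name) != 1L || is.na(object@name))
    msg <- c(msg, "'name' must be a single string")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "'spacing' must be 3 positive numbers")
  if (length(msg)) msg else TRUE
})

#' CaseBundle: one patient-like validation case
#'
#' Aggregates a planning CT, a synthetic CT resampled onto the same grid, the
#' dose computed on each CT, the structure set, and prescription metadata.
#'
#' @slot planningCT,syntheticCT [ScalarVolume-class] HU volumes on one grid.
#' @slot doseReference,doseEvaluated [ScalarVolume-class] dose (Gy) computed
#'   on the planning and synthetic CT respectively.
#' @slot structures named list of [BinaryMask-class] (must include `BODY`
#'   and `PTV`).
#' @slot prescriptionDose numeric, prescribed dose in Gy (> 0).
#' @slot prescriptionIsodoseFraction numeric in (0, 1], the isodose fraction
#'   at which the prescription is specified.
#' @exportClass CaseBundle
setClass("CaseBundle",
  representation(planningCT = "ScalarVolume", syntheticCT = "ScalarVolume",
                 doseReference = "ScalarVolume", doseEvaluated = "ScalarVolume",
                 structures = "list", prescriptionDose = "numeric",
                 prescriptionIsodoseFraction = "numeric"))

setValidity("CaseBundle", function(object) {
  msg <- character()
  if (!all(vapply(object@structures, is, TRUE, "BinaryMask")))
    msg <- c(msg, "'structures' must be a list of BinaryMask objects")
  vols <- list(object@syntheticCT, object@doseReference, object@doseEvaluated)
  for (v in vols)
    if (!gridCompatible(object@planningCT, v))
      msg <- c(msg, "all member volumes must share the planning-CT grid")
  if (length(object@prescriptionDose) != 1L || object@prescriptionDose <= 0)
    msg <- c(msg, "'prescriptionDose' must be a single positive number")
  f <- object@prescriptionIsodoseFraction
  if (length(f) != 1L || f <= 0 || f > 1)
    msg <- c(msg, "'prescriptionIsodoseFraction' must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' GammaCriteria: acceptance criteria for 3D gamma analysis
#'
#' @slot doseDiffPct dose-difference tolerance, percent of the normalization
#'   dose (global mode) or of the local reference dose (local mode).
#' @slot dtaMm distance-to-agreement tolerance in mm.
#' @slot lowDoseThreshold fraction of the normalization dose below which
#'   reference voxels are excluded from analysis.
#' @slot normalization `"global"` or `"local"`.
#' @slot searchRadiusFactor spatial search bound, multiples of `dtaMm`.
#' @slot interpStepFraction sub-sampling step for the evaluated dose, as a
#'   fraction of `dtaMm`.
#' @exportClass GammaCriteria
setClass("GammaCriteria",
  representation(doseDiffPct = "numeric", dtaMm = "numeric",
                 lowDoseThreshold = "numeric", normalization = "character",
                 searchRadiusFactor = "numeric", interpStepFraction = "numeric"),
  prototype(doseDiffPct = 3, dtaMm = 3, lowDoseThreshold = 0.1,
            normalization = "global", searchRadiusFactor = 3,
            interpStepFraction = 0.1))

setValidity("GammaCriteria", function(object) {
  msg <- character()
  if (object@doseDiffPct <= 0) msg <- c(msg, "'doseDiffPct' must be > 0")
  if (object@dtaMm <= 0) msg <- c(msg, "'dtaMm' must be > 0")
  if (object@lowDoseThreshold < 0 || object@lowDoseThreshold >= 1)
    msg <- c(msg, "'lowDoseThreshold' must be in [0, 1)")
  if (!object@normalization %in% c("global", "local"))
    msg <- c(msg, "'normalization' must be \"global\" or \"local\"")
  if (object@searchRadiusFactor <= 0 || object@interpStepFraction <= 0 ||
      object@interpStepFraction > 1)
    msg <- c(msg, "search/interpolation factors out of range")
  if (length(msg)) msg else TRUE
})

#' GammaResult: per-voxel gamma field and global pass rate
#'
#' @slot gammaField [ScalarVolume-class] of dimensionless gamma values on the
#'   reference grid; sentinel `-1` at voxels excluded by the low-dose
#'   threshold.
#' @slot passRate percent of analyzed voxels with gamma <= 1.
#' @slot analyzedVoxels number of reference voxels entering the pass rate.
#' @slot criteria the [GammaCriteria-class] used.
#' @exportClass GammaResult
setClass("GammaResult",
  representation(gammaField = "ScalarVolume", passRate = "numeric",
                 analyzedVoxels = "integer", criteria = "GammaCriteria"))

setValidity("GammaResult", function(object) {
  msg <- character()
  g <- object@gammaField@values
  if (any(g < 0 & g != -1)) msg <- c(msg, "gamma values must be >= 0 (or the -1 sentinel)")
  if (object@passRate < 0 || object@passRate > 100)
    msg <- c(msg, "'passRate' must lie in [0, 100]")
  if (object@analyzedVoxels < 0L)
    msg <- c(msg, "'analyzedVoxels' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' DVHCurve: cumulative dose-volume histogram for one structure
#'
#' @slot structure structure label.
#' @slot doseEdges ascending dose edges in Gy, starting at 0.
#' @slot cumulativeVolumeFraction fraction of the structure volume receiving
#'   at least each dose edge; monotone non-increasing, 1 at dose 0.
#' @slot totalVolume structure volume in cm^3.
#' @exportClass DVHCurve
setClass("DVHCurve",
  representation(structure = "character", doseEdges = "numeric",
                 cumulativeVolumeFraction = "numeric", totalVolume = "numeric"))

setValidity("DVHCurve", function(object) {
  msg <- character()
  if (length(object@doseEdges) != length(object@cumulativeVolumeFraction))
    msg <- c(msg, "edges and fractions must have equal length")
  if (is.unsorted(object@doseEdges))
    msg <- c(msg, "'doseEdges' must be ascending")
  cf <- object@cumulativeVolumeFraction
  if (any(diff(cf) > 1e-12))
    msg <- c(msg, "'cumulativeVolumeFraction' must be non-increasing")
  if (any(cf < -1e-12 | cf > 1 + 1e-12))
    msg <- c(msg, "'cumulativeVolumeFraction' must lie in [0, 1]")
  if (object@totalVolume <= 0) msg <- c(msg, "'totalVolume' must be > 0")
  if (length(msg)) msg else TRUE
})

#' DoseMetrics: summary dose metrics for one structure
#'
#' @slot structure structure label.
#' @slot dMean mean voxel dose in the structure, Gy.
#' @slot dMax maximum point dose in the structure, Gy.
#' @slot vAt named numeric: percent of structure volume receiving at least
#'   each isodose fraction of the prescription (names are the fractions).
#' @slot prescription prescription dose, Gy.
#' @exportClass DoseMetrics
setClass("DoseMetrics",
  representation(structure = "character", dMean = "numeric", dMax = "numeric",
                 vAt = "numeric", prescription = "numeric"))

setValidity("DoseMetrics", function(object) {
  msg <- character()
  if (object@dMean < 0 || object@dMax < object@dMean - 1e-9)
    msg <- c(msg, "must satisfy 0 <= dMean <= dMax")
  if (any(object@vAt < -1e-9 | object@vAt > 100 + 1e-9))
    msg <- c(msg, "'vAt' values must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' QualityReport: the five HU image-quality metrics for a CT pair
#'
#' @slot me mean error (synthetic minus planning), HU.
#' @slot mae mean absolute error, HU.
#' @slot rmse root mean squared error, HU.
#' @slot psnr peak signal-to-noise ratio, dB (`Inf` for identical inputs).
#' @slot ssim structural similarity index in [-1, 1].
#' @slot roiVoxels number of voxels in the comparison ROI.
#' @exportClass QualityReport
setClass("QualityReport",
  representation(me = "numeric", mae = "numeric", rmse = "numeric",
                 psnr = "numeric", ssim = "numeric", roiVoxels = "integer"))

setValidity("QualityReport", function(object) {
  msg <- character()
  if (object@mae < abs(object@me) - 1e-9)
    msg <- c(msg, "MAE must be >= |ME|")
  if (object@rmse < object@mae - 1e-9)
    msg <- c(msg, "RMSE must be >= MAE")
  if (object@roiVoxels <= 0L) msg <- c(msg, "'roiVoxels' must be > 0")
  if (length(msg)) msg else TRUE
})

#' TestResult: a hypothesis-test outcome
#'
#' @slot testName label of the test performed.
#' @slot statistic test statistic.
#' @slot pValue two-sided p-value in [0, 1] (`NA` when not applicable).
#' @slot pAdjusted multiplicity-adjusted p-value (>= pValue).
#' @slot n sample size used.
#' @slot significant logical, significance at the configured alpha after
#'   adjustment (`NA` when not applicable).
#' @slot applicable logical; `FALSE` when the test could not be run (e.g. all
#'   paired differences zero) and the result is a flag, not a number.
#' @exportClass TestResult
setClass("TestResult",
  representation(testName = "character", statistic = "numeric",
                 pValue = "numeric", pAdjusted = "numeric", n = "integer",
                 significant = "logical", applicable = "logical"),
  prototype(pAdjusted = NA_real_, significant = NA, applicable = TRUE))

setValidity("TestResult", function(object) {
  msg <- character()
  p <- object@pValue; pa <- object@pAdjusted
  if (!is.na(p) && (p < 0 || p > 1)) msg <- c(msg, "'pValue' must be in [0,1]")
  if (!is.na(pa) && (pa < 0 || pa > 1))
    msg <- c(msg, "'pAdjusted' must be in [0,1]")
  if (!is.na(p) && !is.na(pa) && pa < p - 1e-12)
    msg <- c(msg, "'pAdjusted' must be >= 'pValue'")
  if (length(msg)) msg else TRUE
})

#' CorrelationResult: a rank-correlation outcome
#'
#' @slot coefficient Spearman rank correlation in [-1, 1].
#' @slot pValue two-sided p-value.
#' @slot pair character(2): the two variable labels correlated.
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  representation(coefficient = "numeric", pValue = "numeric",
                 pair = "character"))

setValidity("CorrelationResult", function(object) {
  if (abs(object@coefficient) > 1 + 1e-12)
    "|coefficient| must be <= 1" else TRUE
})

#' PhantomSpec: geometry and tissue parameters of the digital head phantom
#'
#' @slot gridShape integer(3) voxel counts.
#' @slot spacing numeric(3) mm.
#' @slot headRadii numeric(3) semi-axes (mm) of the outer soft-tissue
#'   ellipsoid.
#' @slot skullThickness skull shell thickness in mm.
#' @slot airCavityRadii numeric vector of sinus-like air-sphere radii, mm
#'   (may be empty).
#' @slot huSoft,huBone,huAir tissue HU values (air <= -900, bone > soft > air).
#' @slot seed integer RNG seed controlling any stochastic anatomy detail.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(gridShape = "integer", spacing = "numeric",
                 headRadii = "numeric", skullThickness = "numeric",
                 airCavityRadii = "numeric", huSoft = "numeric",
                 huBone = "numeric", huAir = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@huAir > -900) msg <- c(msg, "'huAir' must be <= -900")
  if (!(object@huBone > object@huSoft && object@huSoft > object@huAir))
    msg <- c(msg, "need huBone > huSoft > huAir")
  if (object@skullThickness >= min(object@headRadii))
    msg <- c(msg, "'skullThickness' must be smaller than min(headRadii)")
  if (any(object@gridShape < 4L)) msg <- c(msg, "grid too small")
  if (length(msg)) msg else TRUE
})

#' ErrorModel: the parametric synthetic-CT conversion-error model
#'
#' Parameterizes the error sources a synthetic-CT algorithm exhibits against
#' the planning CT: a global HU bias, voxel noise, bone-interface
#' misclassification (dilation/erosion of the bone compartment), facial
#' contour distortion, and an optional metal-artifact signal void.
#'
#' @slot globalBias HU added uniformly inside BODY.
#' @slot noiseSigma standard deviation (HU) of zero-mean Gaussian voxel noise
#'   inside BODY; >= 0.
#' @slot boneDilation signed mm; positive dilates the bone compartment
#'   (misclassifying adjacent soft tissue as bone), negative erodes it.
#' @slot contourShift mm of body-surface displacement along `contourAxis`.
#' @slot contourAxis axis index 1..3 for the contour shift.
#' @slot metalArtifact numeric(5) `c(cx, cy, cz, radius, huVoid)` in world mm
#'   describing a spherical signal void, or numeric(0) for none.
#' @exportClass ErrorModel
setClass("ErrorModel",
  representation(globalBias = "numeric", noiseSigma = "numeric",
                 boneDilation = "numeric", contourShift = "numeric",
                 contourAxis = "integer", metalArtifact = "numeric"),
  prototype(globalBias = 0, noiseSigma = 0, boneDilation = 0,
            contourShift = 0, contourAxis = 1L, metalArtifact = numeric(0)))

setValidity("ErrorModel", function(object) {
  msg <- character()
  if (object@noiseSigma < 0) msg <- c(msg, "'noiseSigma' must be >= 0")
  if (!object@contourAxis %in% 1:3)
    msg <- c(msg, "'contourAxis' must be 1, 2 or 3")
  if (!length(object@metalArtifact) %in% c(0L, 5L))
    msg <- c(msg, "'metalArtifact' must be numeric(0) or numeric(5)")
  if (length(msg)) msg else TRUE
})

#' BeamSpec: the parallel-beam toy dose engine configuration
#'
#' @slot direction one of `"x+", "x-", "y+", "y-", "z+", "z-"`; the axis and
#'   sense along which rays travel.
#' @slot entranceDose dose (Gy) at the body surface on each ray.
#' @slot attenuationScale effective attenuation per mm at water density.
#' @slot targetCenter world mm of the PTV sphere center.
#' @slot targetRadius PTV sphere radius, mm.
#' @exportClass BeamSpec
setClass("BeamSpec",
  representation(direction = "character", entranceDose = "numeric",
                 attenuationScale = "numeric", targetCenter = "numeric",
                 targetRadius = "numeric"),
  prototype(direction = "x+", entranceDose = 60, attenuationScale = 0.004,
            targetCenter = c(0, 0, 0), targetRadius = 15))

setValidity("BeamSpec", function(object) {
  msg <- character()
  if (!object@direction %in% c("x+", "x-", "y+", "y-", "z+", "z-"))
    msg <- c(msg, "'direction' must be one of x+/x-/y+/y-/z+/z-")
  if (object@entranceDose <= 0) msg <- c(msg, "'entranceDose' must be > 0")
  if (object@attenuationScale <= 0)
    msg <- c(msg, "'attenuationScale' must be > 0")
  if (object@targetRadius <= 0) msg <- c(msg, "'targetRadius' must be > 0")
  if (length(msg)) msg else TRUE
})
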