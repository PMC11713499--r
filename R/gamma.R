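#' Construct gamma-analysis criteria
#'
#' @param doseDiffPct dose-difference tolerance, percent.
#' @param dtaMm distance-to-agreement tolerance, mm.
#' @param lowDoseThreshold fraction of the normalization dose below which
#'   reference voxels are excluded (default 0.10).
#' @param normalization `"global"` (percent of the maximum reference dose)
#'   or `"local"` (percent of the local reference dose).
#' @param searchRadiusFactor spatial search bound in multiples of `dtaMm`.
#' @param interpStepFraction evaluated-dose sampling step as a fraction of
#'   `dtaMm`.
#' @return A [GammaCriteria-class].
#' @export
gammaCriteria <- function(doseDiffPct = 3, dtaMm = 3, lowDoseThreshold = 0.1,
                          normalization = "global", searchRadiusFactor = 3,
                          interpStepFraction = 0.1) {
  new("GammaCriteria", doseDiffPct = doseDiffPct, dtaMm = dtaMm,
      lowDoseThreshold = lowDoseThreshold, normalization = normalization,
      searchRadiusFactor = searchRadiusFactor,
      interpStepFraction = interpStepFraction)
}

.extent <- function(v) {
  d <- .gridDim(v)
  rbind(origin(v), origin(v) + (d - 1) * spacing(v))
}

.gammaSetup <- function(reference, evaluated, criteria) {
  er <- .extent(reference); ee <- .extent(evaluated)
  if (any(er[1, ] > ee[2, ]) || any(er[2, ] < ee[1, ]))
    stop("reference and evaluated grids have non-overlapping extents")
  refVals <- values(reference)
  normDose <- max(refVals)
  analyzed <- refVals >= criteria@lowDoseThreshold * normDose
  if (!any(analyzed)) stop("no analyzable dose: all voxels below threshold")
  tol <- if (criteria@normalization == "global") {
    array(criteria@doseDiffPct / 100 * normDose, dim(refVals))
  } else {
    criteria@doseDiffPct / 100 * refVals
  }
  list(refVals = refVals, analyzed = analyzed, tol = tol,
       normDose = normDose)
}

.gammaResult <- function(gvec, reference, analyzed, criteria) {
  valid <- analyzed & !is.na(gvec)
  pass <- 100 * sum(gvec[valid] <= 1) / sum(valid)
  gvec[!valid] <- -1  # sentinel: voxel not analyzed
  field <- ScalarVolume(array(gvec, dim(values(reference))),
                        spacing = spacing(reference),
                        origin = origin(reference), unit = "")
  new("GammaResult", gammaField = field, passRate = pass,
      analyzedVoxels = as.integer(sum(valid)), criteria = criteria)
}

#' 3D gamma analysis of two dose distributions
#'
#' For every reference voxel at or above the low-dose threshold, the gamma
#' index is the minimum over nearby evaluated-dose sample points of
#' `sqrt(|dr|^2/dtaMm^2 + dD^2/tolerance^2)`; a voxel passes when
#' gamma <= 1, and the global pass rate is the percent of analyzed voxels
#' passing. The evaluated dose is sampled by trilinear interpolation on a
#' sub-voxel lattice (step `interpStepFraction * dtaMm`) out to
#' `searchRadiusFactor * dtaMm`, visiting candidates in order of distance
#' with early termination. The reference should be the planning-CT dose and
#' the evaluated the synthetic-CT dose; the comparison is not symmetric.
#'
#' @param reference,evaluated dose [ScalarVolume-class] objects (Gy) on
#'   overlapping extents.
#' @param criteria a [GammaCriteria-class].
#' @return A [GammaResult-class]. The gamma field holds `-1` at voxels
#'   excluded by the low-dose threshold.
#' @export
gammaIndex <- function(reference, evaluated, criteria = gammaCriteria()) {
  s <- .gammaSetup(reference, evaluated, criteria)
  g <- .gammaFastCpp(
    as.numeric(s$refVals), dim(s$refVals), spacing(reference),
    origin(reference), as.numeric(values(evaluated)),
    dim(values(evaluated)), spacing(evaluated), origin(evaluated),
    as.logical(s$analyzed), as.numeric(s$tol), criteria@dtaMm,
    criteria@searchRadiusFactor * criteria@dtaMm,
    criteria@interpStepFraction * criteria@dtaMm)
  .gammaResult(g, reference, s$analyzed, criteria)
}

#' Brute-force gamma oracle
#'
#' Independent verification of [gammaIndex()]: evaluates the gamma
#' minimization exhaustively over a dense lattice (step `dtaMm/20`)
#' covering the whole evaluated extent, with no search-radius truncation
#' (samples are skipped only when an exact envelope bound proves they
#' cannot alter the minimum). Guarded to small instances
#' (<= 25^3 analyzed voxels); intended for validation, not production.
#'
#' @inheritParams gammaIndex
#' @param stepFraction dense-lattice step as a fraction of `dtaMm`.
#' @return A [GammaResult-class].
#' @export
gammaBruteForce <- function(reference, evaluated, criteria = gammaCriteria(),
                            stepFraction = 1 / 20) {
  s <- .gammaSetup(reference, evaluated, criteria)
  g <- .gammaBruteCpp(
    as.numeric(s$refVals), dim(s$refVals), spacing(reference),
    origin(reference), as.numeric(values(evaluated)),
    dim(values(evaluated)), spacing(evaluated), origin(evaluated),
    as.logical(s$analyzed), as.numeric(s$tol), criteria@dtaMm,
    stepFraction * criteria@dtaMm)
  .gammaResult(g, reference, s$analyzed, criteria)
}

#' Gamma analysis under multiple criteria
#'
#' Runs [gammaIndex()] for each criterion (by default the clinical trio
#' 3%/3 mm, 2%/2 mm and 1%/1 mm with 10% low-dose threshold) and tabulates
#' the pass rates against the clinical acceptance level.
#'
#' @inheritParams gammaIndex
#' @param criteriaList list of [GammaCriteria-class].
#' @param acceptance clinical acceptance pass rate, percent (default 95).
#' @return `list(results = list of GammaResult, table = data.frame)` where
#'   the table has columns `criterion`, `passRate`, `analyzedVoxels`,
#'   `meetsAcceptance`.
#' @export
multiCriteriaReport <- function(reference, evaluated,
                                criteriaList = defaultCriteria(),
                                acceptance = 95) {
  if (!length(criteriaList)) stop("empty criteria list")
  results <- lapply(criteriaList, function(cr)
    gammaIndex(reference, evaluated, cr))
  tab <- data.frame(
    criterion = vapply(criteriaList, function(cr)
      sprintf("%g%%/%g mm", cr@doseDiffPct, cr@dtaMm), character(1)),
    passRate = vapply(results, passRate, numeric(1)),
    analyzedVoxels = vapply(results, analyzedVoxels, integer(1)),
    meetsAcceptance = vapply(results, function(r)
      passRate(r) >= acceptance, logical(1)),
    row.names = NULL)
  list(results = results, table = tab)
}

#' The clinical criteria trio
#'
#' 3%/3 mm, 2%/2 mm and 1%/1 mm, each with a 10% low-dose threshold.
#'
#' @param lowDoseThreshold shared threshold fraction.
#' @param normalization shared normalization mode.
#' @return list of three [GammaCriteria-class].
#' @export
defaultCriteria <- function(lowDoseThreshold = 0.1,
                            normalization = "global") {
  lapply(c(3, 2, 1), function(k)
    gammaCriteria(doseDiffPct = k, dtaMm = k,
                  lowDoseThreshold = lowDoseThreshold,
                  normalization = normalization))
}
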