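.roiPair <- function(pct, sct, roi) {
  .stopIfIncompatible(pct, sct, "planning and synthetic CT")
  if (is.null(roi)) {
    list(p = as.vector(values(pct)), s = as.vector(values(sct)))
  } else {
    .stopIfIncompatible(pct, roi, "CT and ROI mask")
    sel <- values(roi)
    if (!any(sel)) stop("ROI mask is empty")
    list(p = values(pct)[sel], s = values(sct)[sel])
  }
}

#' HU image-quality metrics for a planning/synthetic CT pair
#'
#' `computeME`, `computeMAE` and `computeRMSE` summarize the voxel-wise HU
#' difference (synthetic minus planning) over the ROI: the mean error gives
#' the direction of deviation (positive when the synthetic CT reads high),
#' the mean absolute error its magnitude, and the root mean squared error
#' weights large deviations more heavily. `computePSNR` is
#' `10*log10(peak^2 / MSE)` in dB, with `peak` defaulting to the maximum
#' synthetic-CT value over the ROI; identical inputs return `Inf`.
#' `computeSSIM` is the structural similarity index; see its own help.
#'
#' The ROI defaults to the entire common grid (`roi = NULL`); restricting
#' to a BODY mask removes the surrounding air, which otherwise flatters the
#' error metrics.
#'
#' @param pct,sct planning and synthetic CT [ScalarVolume-class] on one
#'   grid.
#' @param roi optional [BinaryMask-class]; `NULL` uses every voxel.
#' @return A single numeric value in HU (ME/MAE/RMSE) or dB (PSNR).
#' @examples
#' p <- ScalarVolume(array(c(0, 100), c(2, 1, 1)))
#' s <- ScalarVolume(array(c(10, -30), c(2, 1, 1)))
#' computeME(p, s)    # -60
#' computeMAE(p, s)   # 70
#' computeRMSE(p, s)  # sqrt(8500)
#' @export
computeME <- function(pct, sct, roi = NULL) {
  v <- .roiPair(pct, sct, roi)
  mean(v$s - v$p)
}

#' @rdname computeME
#' @export
computeMAE <- function(pct, sct, roi = NULL) {
  v <- .roiPair(pct, sct, roi)
  mean(abs(v$s - v$p))
}

#' @rdname computeME
#' @export
computeRMSE <- function(pct, sct, roi = NULL) {
  v <- .roiPair(pct, sct, roi)
  sqrt(mean((v$s - v$p)^2))
}

#' @rdname computeME
#' @param peak peak value for PSNR; `NULL` uses the maximum synthetic-CT
#'   value over the ROI. Fix it (e.g. 3000 HU) for cross-case
#'   comparability.
#' @export
computePSNR <- function(pct, sct, roi = NULL, peak = NULL) {
  v <- .roiPair(pct, sct, roi)
  mse <- mean((v$s - v$p)^2)
  if (mse == 0) return(Inf)
  if (is.null(peak)) peak <- max(v$s)
  10 * log10(peak^2 / mse)
}

#' SSIM stabilization constants
#'
#' The standard convention `C1 = (k1*L)^2`, `C2 = (k2*L)^2` with
#' `k1 = 0.01`, `k2 = 0.03`; `L` is the dynamic range (defaulting, when
#' `NULL`, to the observed planning-CT range over the ROI).
#'
#' @param k1,k2 dimensionless positive constants.
#' @param L dynamic range in HU, or `NULL` for the observed range.
#' @return `list(k1, k2, L)`.
#' @export
ssimConstants <- function(k1 = 0.01, k2 = 0.03, L = NULL) {
  stopifnot(k1 > 0, k2 > 0, is.null(L) || L > 0)
  list(k1 = k1, k2 = k2, L = L)
}

.ssimFormula <- function(muP, muS, varP, varS, covPS, C1, C2) {
  ((2 * muS * muP + C1) * (2 * covPS + C2)) /
    ((muS^2 + muP^2 + C1) * (varS + varP + C2))
}

# mask-aware local box sums via 3D integral volumes
.boxSum <- function(arr, w) {
  for (ax in 1:3) {
    arr <- apply(arr, setdiff(1:3, ax), function(col) {
      cs <- cumsum(col)
      n <- length(col)
      hi <- pmin(seq_len(n) + w, n)
      lo <- pmax(seq_len(n) - w - 1L, 0L)
      cs[hi] - c(0, cs)[lo + 1L]
    })
    arr <- aperm(arr, order(c(ax, setdiff(1:3, ax))))
  }
  arr
}

#' Structural similarity index for a CT pair
#'
#' In `"global"` mode (the default) the SSIM formula is evaluated once from
#' ROI-wide means, variances and the cross-covariance, yielding one scalar
#' per case. In `"windowed"` mode it is averaged over sliding cubic local
#' windows (mask-aware: window statistics use only ROI voxels), which is
#' sensitive to local structural disagreement that the global statistics
#' wash out.
#'
#' @inheritParams computeME
#' @param constants see [ssimConstants()].
#' @param mode `"global"` or `"windowed"`.
#' @param windowHalfWidth half-width of the cubic window in voxels
#'   (windowed mode; window edge = `2*windowHalfWidth + 1`).
#' @param normalize if `TRUE`, both images are jointly min-max rescaled to
#'   [0, 1] before comparison (with `L = 1`).
#' @return SSIM in [-1, 1].
#' @export
computeSSIM <- function(pct, sct, roi = NULL, constants = ssimConstants(),
                        mode = c("global", "windowed"), windowHalfWidth = 3L,
                        normalize = FALSE) {
  mode <- match.arg(mode)
  v <- .roiPair(pct, sct, roi)
  p <- v$p; s <- v$s
  if (normalize) {
    lo <- min(p, s); hi <- max(p, s)
    if (hi > lo) { p <- (p - lo) / (hi - lo); s <- (s - lo) / (hi - lo) }
    else { p <- p * 0; s <- s * 0 }
    L <- 1
  } else {
    L <- constants$L
    if (is.null(L)) L <- max(diff(range(p)), 1)
  }
  C1 <- (constants$k1 * L)^2
  C2 <- (constants$k2 * L)^2
  if (mode == "global") {
    n <- length(p)
    muP <- mean(p); muS <- mean(s)
    varP <- sum((p - muP)^2) / n
    varS <- sum((s - muS)^2) / n
    covPS <- sum((p - muP) * (s - muS)) / n
    return(.ssimFormula(muP, muS, varP, varS, covPS, C1, C2))
  }
  # windowed mode on the full arrays, restricted to the ROI
  pa <- values(pct); sa <- values(sct)
  if (normalize) {
    lo <- min(pa, sa); hi <- max(pa, sa)
    if (hi > lo) { pa <- (pa - lo) / (hi - lo); sa <- (sa - lo) / (hi - lo) }
  }
  sel <- if (is.null(roi)) array(TRUE, dim(pa)) else values(roi)
  w <- as.integer(windowHalfWidth)
  mskN <- .boxSum(array(as.numeric(sel), dim(pa)), w)
  pa0 <- pa; pa0[!sel] <- 0
  sa0 <- sa; sa0[!sel] <- 0
  sumP <- .boxSum(pa0, w); sumS <- .boxSum(sa0, w)
  sumP2 <- .boxSum(pa0^2, w); sumS2 <- .boxSum(sa0^2, w)
  sumPS <- .boxSum(pa0 * sa0, w)
  n <- pmax(mskN, 1)
  muP <- sumP / n; muS <- sumS / n
  varP <- pmax(sumP2 / n - muP^2, 0)
  varS <- pmax(sumS2 / n - muS^2, 0)
  covPS <- sumPS / n - muP * muS
  ssimMap <- .ssimFormula(muP, muS, varP, varS, covPS, C1, C2)
  mean(ssimMap[sel & mskN > 0])
}

#' Full image-quality report for a CT pair
#'
#' Computes all five HU metrics over one ROI and returns them as a
#' validated [QualityReport-class].
#'
#' @inheritParams computeSSIM
#' @param peak PSNR peak; `NULL` uses the ROI maximum of the synthetic CT.
#' @return A [QualityReport-class].
#' @export
imageQuality <- function(pct, sct, roi = NULL, constants = ssimConstants(),
                         mode = "global", peak = NULL, normalize = FALSE) {
  v <- .roiPair(pct, sct, roi)
  new("QualityReport",
      me = computeME(pct, sct, roi),
      mae = computeMAE(pct, sct, roi),
      rmse = computeRMSE(pct, sct, roi),
      psnr = computePSNR(pct, sct, roi, peak = peak),
      ssim = computeSSIM(pct, sct, roi, constants = constants, mode = mode,
                         normalize = normalize),
      roiVoxels = length(v$p))
}
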