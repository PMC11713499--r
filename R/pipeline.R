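.critLabel <- function(cr) sprintf("%g%%/%g mm", cr@doseDiffPct, cr@dtaMm)
.critColumn <- function(cr) sprintf("pass_%g_%g", cr@doseDiffPct, cr@dtaMm)

#' Run the full QA workflow on one case
#'
#' Sequences the per-case pipeline on an already-preprocessed
#' [CaseBundle-class]: HU image-quality metrics, DVH metric differences for
#' every structure (BODY excluded), and gamma pass rates for every
#' configured criterion. A structure whose mask is empty is skipped with a
#' logged message, never silently and never fatally.
#'
#' @param bundle a [CaseBundle-class].
#' @param config a configuration list from [sctqaConfig()].
#' @param caseId case identifier carried into the report row.
#' @return `list(caseId, quality, dvh, gamma, row, exclusions)`: `quality`
#'   a [QualityReport-class], `dvh` a named list of [diffMetrics()] data
#'   frames, `gamma` the [multiCriteriaReport()] table, `row` a one-row
#'   data.frame of the scalar per-case values, `exclusions` a character
#'   vector of skipped structures with reasons.
#' @export
runCase <- function(bundle, config = sctqaConfig(), caseId = "case") {
  validObject(bundle)
  roi <- if (config$roiMode == "body") bundle@structures$BODY else NULL
  q <- imageQuality(bundle@planningCT, bundle@syntheticCT, roi = roi,
                    constants = config$ssimK, mode = config$ssimMode,
                    peak = config$psnrPeak)
  dvh <- list()
  exclusions <- character()
  for (nm in setdiff(names(bundle@structures), "BODY")) {
    res <- tryCatch({
      mr <- doseMetrics(bundle@doseReference, bundle@structures[[nm]],
                        bundle@prescriptionDose, config$dvhFractions)
      me <- doseMetrics(bundle@doseEvaluated, bundle@structures[[nm]],
                        bundle@prescriptionDose, config$dvhFractions)
      diffMetrics(mr, me)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      exclusions <- c(exclusions,
                      sprintf("%s/%s skipped: %s", caseId, nm, res))
      message("structure skipped: ", caseId, "/", nm, " (", res, ")")
    } else {
      dvh[[nm]] <- res
    }
  }
  g <- multiCriteriaReport(bundle@doseReference, bundle@doseEvaluated,
                           config$criteria, config$acceptance)
  row <- data.frame(caseId = caseId, me = q@me, mae = q@mae, rmse = q@rmse,
                    psnr = q@psnr, ssim = q@ssim, row.names = NULL)
  for (k in seq_along(config$criteria))
    row[[.critColumn(config$criteria[[k]])]] <- g$table$passRate[k]
  list(caseId = caseId, quality = q, dvh = dvh, gamma = g$table, row = row,
       exclusions = exclusions)
}

.groupSummary <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) c(mean = NA_real_, sd = NA_real_)
  else c(mean = mean(x), sd = if (length(x) > 1) sd(x) else NA_real_)
}

#' Run the QA workflow over a cohort of cases
#'
#' Applies [runCase()] to every bundle, then assembles the cohort report:
#' per-case rows, per-group descriptive statistics with between-group
#' t-tests (Bonferroni-corrected within each comparison family),
#' within-cohort Wilcoxon signed-rank tests of reference vs evaluated DVH
#' metrics per structure, and the Spearman correlation table between
#' image-quality metrics and gamma pass rates. Tests that cannot be run
#' (fewer than 3 cases per group, constant values, all paired differences
#' zero) are flagged `NA`, never fabricated; no case is silently dropped.
#'
#' @param bundles named list of [CaseBundle-class] objects.
#' @param config a configuration list from [sctqaConfig()].
#' @param groups optional character vector (one label per bundle, e.g.
#'   `"IMRT/VMAT"` / `"SRS"`); `NULL` treats the cohort as one group.
#' @return A list with elements `perCase` (data.frame, one row per case),
#'   `groupStats` (data.frame of group means/sds and between-group tests),
#'   `pairedTests` (data.frame of reference-vs-evaluated DVH tests),
#'   `correlations` (data.frame of metric-vs-pass-rate Spearman results),
#'   `exclusions` (character log) and `config`.
#' @export
runCohort <- function(bundles, config = sctqaConfig(), groups = NULL) {
  stopifnot(length(bundles) >= 1L)
  ids <- names(bundles)
  if (is.null(ids)) ids <- sprintf("case%02d", seq_along(bundles))
  if (is.null(groups)) groups <- rep("all", length(bundles))
  stopifnot(length(groups) == length(bundles))
  caseResults <- lapply(seq_along(bundles), function(i)
    runCase(bundles[[i]], config, caseId = ids[i]))
  perCase <- do.call(rbind, lapply(caseResults, `[[`, "row"))
  perCase$group <- groups
  exclusions <- unlist(lapply(caseResults, `[[`, "exclusions"))

  qualityMetrics <- c("me", "mae", "rmse", "psnr", "ssim")
  gammaCols <- vapply(config$criteria, .critColumn, character(1))
  glev <- unique(groups)
  famQ <- if (is.null(config$qualityFamilySize)) length(qualityMetrics)
          else config$qualityFamilySize
  famG <- if (is.null(config$gammaFamilySize)) length(gammaCols)
          else config$gammaFamilySize

  groupStats <- do.call(rbind, lapply(c(qualityMetrics, gammaCols),
                                      function(mcol) {
    fam <- if (mcol %in% qualityMetrics) famQ else famG
    vals <- lapply(glev, function(g) perCase[[mcol]][groups == g])
    row <- data.frame(metric = mcol, row.names = NULL)
    for (i in seq_along(glev)) {
      s <- .groupSummary(vals[[i]])
      row[[paste0("mean_", glev[i])]] <- s["mean"]
      row[[paste0("sd_", glev[i])]] <- s["sd"]
    }
    p <- pAdj <- NA_real_
    if (length(glev) == 2L) {
      a <- vals[[1]][is.finite(vals[[1]])]; b <- vals[[2]][is.finite(vals[[2]])]
      tt <- if (length(a) >= 3L && length(b) >= 3L)
        tryCatch(independentTTest(a, b, alpha = config$alpha,
                                  familySize = fam),
                 error = function(e) NULL) else NULL
      if (!is.null(tt)) { p <- tt@pValue; pAdj <- tt@pAdjusted }
    }
    row$p <- p; row$pAdjusted <- pAdj
    row
  }))

  # reference vs evaluated DVH metrics, paired across cases per structure
  dvhLong <- do.call(rbind, lapply(caseResults, function(cr)
    do.call(rbind, lapply(names(cr$dvh), function(nm)
      cbind(caseId = cr$caseId, structure = nm, cr$dvh[[nm]])))))
  pairedTests <- NULL
  if (!is.null(dvhLong) && nrow(dvhLong)) {
    keys <- unique(dvhLong[, c("structure", "metric")])
    pairedTests <- do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
      sel <- dvhLong$structure == keys$structure[i] &
        dvhLong$metric == keys$metric[i]
      ref <- dvhLong$reference[sel]; ev <- dvhLong$evaluated[sel]
      out <- data.frame(structure = keys$structure[i],
                        metric = keys$metric[i], n = sum(sel),
                        meanDifference = mean(ev - ref),
                        p = NA_real_, applicable = FALSE, row.names = NULL)
      if (sum(sel) >= 3L) {
        wt <- wilcoxonSignedRank(ref, ev, alpha = config$alpha)
        if (wt@applicable) { out$p <- wt@pValue; out$applicable <- TRUE }
      }
      out
    }))
  }

  # image quality vs gamma pass rate, per group (the correlation stage
  # consumes exactly the per-case values emitted above)
  correlations <- do.call(rbind, lapply(glev, function(g) {
    sel <- groups == g
    do.call(rbind, lapply(qualityMetrics, function(qm) {
      do.call(rbind, lapply(seq_along(gammaCols), function(k) {
        x <- perCase[[qm]][sel]; y <- perCase[[gammaCols[k]]][sel]
        ok <- is.finite(x) & is.finite(y)
        res <- if (sum(ok) >= 3L && diff(range(x[ok])) > 0 &&
                   diff(range(y[ok])) > 0)
          spearmanCorrelation(x[ok], y[ok],
                              labels = c(qm, .critLabel(config$criteria[[k]])))
        else NULL
        data.frame(group = g, metric = qm,
                   criterion = .critLabel(config$criteria[[k]]),
                   rS = if (is.null(res)) NA_real_ else res@coefficient,
                   p = if (is.null(res)) NA_real_ else res@pValue,
                   row.names = NULL)
      }))
    }))
  }))

  list(perCase = perCase, groupStats = groupStats,
       pairedTests = pairedTests, correlations = correlations,
       exclusions = exclusions, config = config)
}

#' Generate a seeded two-group demonstration cohort
#'
#' Builds paired phantom cases in two groups that emulate the contrast
#' between a well-reproduced setup (mild conversion error) and a
#' compromised one (larger bias/noise, bone-interface misclassification
#' and a contour shift), with per-case parameter jitter so cohort
#' statistics are non-degenerate. Deterministic given `seed`.
#'
#' @param nPerGroup cases per group.
#' @param seed integer seed.
#' @param gridShape,spacing phantom grid (passed to [phantomSpec()]).
#' @return `list(bundles =, groups =)` ready for [runCohort()].
#' @export
demoCohort <- function(nPerGroup = 9, seed = 1L,
                       gridShape = c(32L, 32L, 32L), spacing = c(6, 6, 6)) {
  set.seed(as.integer(seed))
  bundles <- list()
  groups <- character()
  for (i in seq_len(2 * nPerGroup)) {
    grpA <- i <= nPerGroup
    model <- if (grpA) {
      errorModel(globalBias = rnorm(1, 23, 3),
                 noiseSigma = abs(rnorm(1, 30, 5)))
    } else {
      errorModel(globalBias = rnorm(1, 28, 4),
                 noiseSigma = abs(rnorm(1, 50, 8)),
                 boneDilation = 6, contourShift = 6)
    }
    spec <- phantomSpec(gridShape = gridShape, spacing = spacing,
                        seed = seed * 1000L + i)
    bundles[[sprintf("%s%02d", if (grpA) "IM" else "SR", i)]] <-
      generateCase(spec, model, beamSpec())
    groups <- c(groups, if (grpA) "IMRT_VMAT" else "SRS")
  }
  list(bundles = bundles, groups = groups)
}

#' Monotone error-severity sweep
#'
#' Generates a sequence of cases whose conversion-error severity increases
#' strictly step by step (global bias and noise scaled together), the
#' harness used to verify that image-quality degradation propagates to
#' gamma pass-rate degradation with the expected correlation signs.
#'
#' @param nSteps number of severity steps.
#' @param seed integer seed.
#' @param biasStep HU of additional global bias per step.
#' @param noiseStep HU of additional noise SD per step.
#' @param gridShape,spacing phantom grid.
#' @return named list of [CaseBundle-class], severity increasing.
#' @export
severitySweep <- function(nSteps = 10, seed = 1L,
                          gridShape = c(32L, 32L, 32L), spacing = c(6, 6, 6),
                          biasStep = 8, noiseStep = 3) {
  bundles <- lapply(seq_len(nSteps), function(t) {
    spec <- phantomSpec(gridShape = gridShape, spacing = spacing,
                        seed = seed * 1000L + t)
    generateCase(spec, errorModel(globalBias = biasStep * t,
                                  noiseSigma = noiseStep * t),
                 beamSpec())
  })
  names(bundles) <- sprintf("sweep%02d", seq_len(nSteps))
  bundles
}
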