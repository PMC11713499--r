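#' Pipeline configuration
#'
#' Bundles every tunable of the per-case and cohort workflow into one
#' validated list, embedded verbatim in each report for provenance.
#'
#' @param criteria list of [GammaCriteria-class] (default: the clinical
#'   3%/3 mm, 2%/2 mm, 1%/1 mm trio at 10% threshold).
#' @param roiMode `"all"` (full common grid, the default comparison ROI) or
#'   `"body"` (restrict HU metrics to the BODY mask).
#' @param ssimMode `"global"` or `"windowed"`.
#' @param ssimK see [ssimConstants()].
#' @param dvhFractions isodose fractions for target-coverage V metrics.
#' @param dvhBinWidth DVH bin width, Gy.
#' @param psnrPeak fixed PSNR peak in HU, or `NULL` for the per-case
#'   synthetic-CT maximum.
#' @param alpha significance level.
#' @param acceptance clinical gamma acceptance level, percent.
#' @param qualityFamilySize,gammaFamilySize Bonferroni family sizes for the
#'   image-quality and gamma comparison tables; `NULL` uses the number of
#'   comparisons in the table.
#' @return A named list with class checks applied.
#' @export
sctqaConfig <- function(criteria = defaultCriteria(), roiMode = c("all", "body"),
                        ssimMode = c("global", "windowed"),
                        ssimK = ssimConstants(), dvhFractions = c(0.93, 1, 1.1),
                        dvhBinWidth = 0.01, psnrPeak = NULL, alpha = 0.05,
                        acceptance = 95, qualityFamilySize = NULL,
                        gammaFamilySize = NULL) {
  stopifnot(length(criteria) >= 1L,
            all(vapply(criteria, is, TRUE, "GammaCriteria")),
            dvhBinWidth > 0, alpha > 0, alpha < 1)
  list(criteria = criteria, roiMode = match.arg(roiMode),
       ssimMode = match.arg(ssimMode), ssimK = ssimK,
       dvhFractions = dvhFractions, dvhBinWidth = dvhBinWidth,
       psnrPeak = psnrPeak, alpha = alpha, acceptance = acceptance,
       qualityFamilySize = qualityFamilySize,
       gammaFamilySize = gammaFamilySize)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Accepts a document with any subset of the [sctqaConfig()] fields;
#' `criteria` is given as a list of `[doseDiffPct, dtaMm]` pairs plus
#' optional `lowDoseThreshold` / `normalization` keys.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A configuration list as from [sctqaConfig()].
#' @export
readConfig <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(raw$criteria)) {
    thr <- if (is.null(raw$lowDoseThreshold)) 0.1 else raw$lowDoseThreshold
    nrm <- if (is.null(raw$normalization)) "global" else raw$normalization
    crit <- raw$criteria
    if (is.matrix(crit)) crit <- asplit(crit, 1)
    args$criteria <- lapply(crit, function(p)
      gammaCriteria(doseDiffPct = p[[1]], dtaMm = p[[2]],
                    lowDoseThreshold = thr, normalization = nrm))
  }
  for (f in c("roiMode", "ssimMode", "dvhFractions", "dvhBinWidth",
              "psnrPeak", "alpha", "acceptance", "qualityFamilySize",
              "gammaFamilySize"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  do.call(sctqaConfig, args)
}
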