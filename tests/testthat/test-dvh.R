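test_that("uniform dose yields the step-function DVH", {
  d <- vol(rep(10, 8), unit = "Gy")
  m <- mask(rep(TRUE, 8), name = "PTV")
  curve <- computeDVH(d, m, binWidth = 1)
  expect_equal(curve@cumulativeVolumeFraction[curve@doseEdges <= 10],
               rep(1, sum(curve@doseEdges <= 10)))
  expect_equal(curve@cumulativeVolumeFraction[curve@doseEdges > 10],
               rep(0, sum(curve@doseEdges > 10)))
})

test_that("two-voxel DVH matches the enumeration oracle", {
  d <- vol(c(2, 4), unit = "Gy")
  m <- mask(c(TRUE, TRUE), name = "PTV")
  curve <- computeDVH(d, m, binWidth = 0.5)
  f <- approxfun(curve@doseEdges, curve@cumulativeVolumeFraction,
                 method = "constant")
  expect_equal(f(1.5), 1.0)
  expect_equal(f(2.5), 0.5)
  expect_equal(f(4.5), 0.0)
  # n voxels at 1 mm spacing -> n/1000 cm^3
  expect_equal(curve@totalVolume, 2 / 1000)
})

test_that("DVH curves are monotone with normalized endpoints", {
  set.seed(31)
  for (i in 1:4) {
    d <- ScalarVolume(array(runif(6^3, 0, 60), c(6, 6, 6)), unit = "Gy")
    m <- BinaryMask("s", array(runif(6^3) > 0.5, c(6, 6, 6)))
    curve <- computeDVH(d, m, binWidth = 0.25)
    expect_true(all(diff(curve@cumulativeVolumeFraction) <= 1e-12))
    expect_equal(curve@cumulativeVolumeFraction[1], 1)
    expect_equal(curve@cumulativeVolumeFraction[length(curve@doseEdges)], 0)
  }
})

test_that("dose metrics agree with per-voxel enumeration on random masks", {
  set.seed(33)
  for (i in 1:6) {
    shape <- c(10L, 10L, 10L)
    dv <- array(runif(prod(shape), 0, 50), shape)
    mv <- array(runif(prod(shape)) > 0.6, shape)
    if (!any(mv)) mv[1] <- TRUE
    d <- ScalarVolume(dv, spacing = c(2, 2, 3), unit = "Gy")
    m <- BinaryMask("s", mv, spacing = c(2, 2, 3))
    presc <- 40
    fr <- c(0.5, 0.93, 1, 1.1)
    got <- doseMetrics(d, m, presc, fr)
    sel <- dv[mv]
    expect_equal(got@dMean, mean(sel), tolerance = 1e-12)
    expect_equal(got@dMax, max(sel), tolerance = 1e-12)
    for (k in seq_along(fr))
      expect_equal(unname(got@vAt[k]), 100 * mean(sel >= fr[k] * presc),
                   tolerance = 1e-12)
    # V is non-increasing in the isodose fraction
    expect_true(all(diff(got@vAt) <= 1e-12))
    # d_max matches the highest DVH edge with mass, within one bin
    curve <- computeDVH(d, m, binWidth = 0.01)
    hi <- max(curve@doseEdges[curve@cumulativeVolumeFraction > 0])
    expect_lt(abs(hi - got@dMax), 0.01 + 1e-9)
  }
})

test_that("prescription-level doses give the textbook V values", {
  d <- vol(rep(4, 10), unit = "Gy")
  m <- mask(rep(TRUE, 10), name = "PTV")
  got <- doseMetrics(d, m, prescription = 4)
  expect_equal(unname(got@vAt), c(100, 100, 0))
  expect_equal(got@dMean, 4)
  expect_equal(got@dMax, 4)
  # two voxels (2, 4), prescription 4
  d2 <- vol(c(2, 4), unit = "Gy")
  m2 <- mask(c(TRUE, TRUE))
  got2 <- doseMetrics(d2, m2, 4, isodoseFractions = c(0.5, 1))
  expect_equal(got2@dMean, 3)
  expect_equal(got2@dMax, 4)
  expect_equal(unname(got2@vAt), c(100, 50))
  # everything below the 93% level
  d3 <- vol(rep(3.7, 4), unit = "Gy")
  got3 <- doseMetrics(d3, mask(rep(TRUE, 4)), 4)
  expect_equal(unname(got3@vAt["0.93"]), 0)
})

test_that("refining the bin width leaves D-mean/D-max and V unchanged", {
  set.seed(35)
  d <- ScalarVolume(array(runif(5^3, 0, 20), c(5, 5, 5)), unit = "Gy")
  m <- BinaryMask("s", array(TRUE, c(5, 5, 5)))
  coarse <- computeDVH(d, m, binWidth = 0.5)
  fine <- computeDVH(d, m, binWidth = 0.01)
  expect_equal(coarse@totalVolume, fine@totalVolume)
  # the curves agree at shared edges
  fc <- approxfun(fine@doseEdges, fine@cumulativeVolumeFraction,
                  method = "constant", rule = 2)
  expect_equal(fc(coarse@doseEdges), coarse@cumulativeVolumeFraction,
               tolerance = 1e-12)
})

test_that("metric differencing reports absolute and normalized columns", {
  d <- vol(c(2, 4), unit = "Gy")
  m <- mask(c(TRUE, TRUE), name = "lens")
  a <- doseMetrics(d, m, 4)
  b <- doseMetrics(vol(c(2.02, 4.02), unit = "Gy"), m, 4)
  out <- diffMetrics(a, b)
  expect_equal(out$difference[out$metric == "dMean"], 0.02,
               tolerance = 1e-9)
  expect_equal(out$normalizedDifferencePct[out$metric == "dMean"],
               100 * 0.02 / 3, tolerance = 1e-6)
  # identical metrics -> all differences zero
  same <- diffMetrics(a, a)
  expect_true(all(same$difference == 0))
  expect_true(all(same$normalizedDifferencePct[!is.na(
    same$normalizedDifferencePct)] == 0))
  # reference V110% = 0 -> normalized difference undefined, flagged NA
  expect_true(is.na(out$normalizedDifferencePct[out$metric == "V1.1"]))
  expect_equal(out$reference[out$metric == "V1.1"], 0)
})

test_that("empty structures raise the structure-absent error", {
  d <- vol(c(1, 2), unit = "Gy")
  empty <- mask(c(FALSE, FALSE), name = "chiasm")
  expect_error(computeDVH(d, empty), "structure absent")
  expect_error(doseMetrics(d, empty, 4), "structure absent")
})

test_that("identity phantom cases have identical reference/evaluated metrics", {
  cb <- generateCase(smallSpec(seed = 6L), errorModel(), beamSpec())
  for (nm in c("PTV", "brainstem")) {
    a <- doseMetrics(cb@doseReference, cb@structures[[nm]],
                     cb@prescriptionDose)
    b <- doseMetrics(cb@doseEvaluated, cb@structures[[nm]],
                     cb@prescriptionDose)
    out <- diffMetrics(a, b)
    expect_true(all(out$difference == 0))
  }
})
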