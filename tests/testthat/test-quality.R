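test_that("error metrics match the direct summation oracle", {
  p <- vol(c(0, 100))
  s <- vol(c(10, -30))
  expect_equal(computeME(p, s), (10 + (-130)) / 2)   # -60
  expect_equal(computeMAE(p, s), (10 + 130) / 2)     # 70
  expect_equal(computeRMSE(p, s), sqrt((100 + 16900) / 2))  # sqrt(8500)
})

test_that("identical inputs give the identity metric tuple", {
  set.seed(6)
  p <- ScalarVolume(array(rnorm(4^3, 0, 300), c(4, 4, 4)))
  expect_equal(computeME(p, p), 0)
  expect_equal(computeMAE(p, p), 0)
  expect_equal(computeRMSE(p, p), 0)
  expect_identical(computePSNR(p, p), Inf)
  expect_equal(computeSSIM(p, p), 1, tolerance = 1e-12)
})

test_that("constant offsets behave as closed forms predict", {
  set.seed(8)
  p <- ScalarVolume(array(rnorm(5^3, 0, 100), c(5, 5, 5)))
  s <- ScalarVolume(values(p) + 10)
  expect_equal(computeME(p, s), 10, tolerance = 1e-12)
  expect_equal(computeMAE(p, s), 10, tolerance = 1e-12)
  expect_equal(computeRMSE(p, s), 10, tolerance = 1e-12)
})

test_that("RMSE >= MAE >= |ME| on random pairs, with symmetry structure", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- ScalarVolume(array(rnorm(6^3, 0, 200), c(6, 6, 6)))
    s <- ScalarVolume(values(p) + array(rnorm(6^3, 20, 80), c(6, 6, 6)))
    me <- computeME(p, s); mae <- computeMAE(p, s); rmse <- computeRMSE(p, s)
    expect_gte(mae, abs(me))
    expect_gte(rmse, mae)
    # ME anti-symmetric; MAE/RMSE symmetric
    expect_equal(computeME(s, p), -me, tolerance = 1e-12)
    expect_equal(computeMAE(s, p), mae, tolerance = 1e-12)
    expect_equal(computeRMSE(s, p), rmse, tolerance = 1e-12)
  }
})

test_that("PSNR follows its closed form and decreases with MSE", {
  # peak 1000, RMSE 100 -> 20 dB
  p <- vol(rep(0, 1000))
  s <- vol(rep(100, 1000))
  expect_equal(computePSNR(p, s, peak = 1000), 20)
  # doubling RMSE at fixed peak lowers PSNR by 20*log10(2) = 6.02 dB
  s2 <- vol(rep(200, 1000))
  expect_equal(computePSNR(p, s, peak = 1000) -
                 computePSNR(p, s2, peak = 1000),
               20 * log10(2), tolerance = 1e-9)
  # default peak is the synthetic-CT maximum over the ROI
  sv <- vol(c(100, 1000))
  pv <- vol(c(0, 1000))
  expect_equal(computePSNR(pv, sv),
               10 * log10(1000^2 / mean(c(100, 0)^2)))
})

test_that("SSIM hits its limits: equality, constants, anti-correlation", {
  # two equal constant volumes are perfectly similar (stabilized by C1, C2)
  cst <- vol(rep(50, 64))
  expect_equal(computeSSIM(cst, cst), 1)
  # anti-correlated exactly-zero-mean pair with variance >> C2 tends to -1
  # (the luminance term is then C1/C1 = 1 and the structure term -> -1)
  set.seed(10)
  x <- rnorm(5000, 0, 1000)
  x <- x - mean(x)
  p <- vol(x)
  s <- vol(-x)
  got <- computeSSIM(p, s, constants = ssimConstants(L = 1))
  expect_lt(got, -0.99)
  expect_gte(got, -1 - 1e-12)
})

test_that("windowed SSIM under joint min-max normalization ignores a common offset", {
  # with the inputs rescaled to [0,1] (constants scaling with that range),
  # a shared additive constant cancels exactly
  set.seed(12)
  arr <- array(rnorm(8^3, 100, 150), c(8, 8, 8))
  p <- ScalarVolume(arr)
  s <- ScalarVolume(arr + array(rnorm(8^3, 0, 50), c(8, 8, 8)))
  a <- computeSSIM(p, s, mode = "windowed", normalize = TRUE)
  b <- computeSSIM(ScalarVolume(values(p) + 300),
                   ScalarVolume(values(s) + 300),
                   mode = "windowed", normalize = TRUE)
  expect_equal(a, b, tolerance = 1e-9)
  expect_lt(a, 1)
})

test_that("global SSIM agrees with a direct evaluation of the formula", {
  set.seed(14)
  pv <- rnorm(500, 40, 90)
  sv <- pv + rnorm(500, 10, 60)
  p <- vol(pv); s <- vol(sv)
  L <- diff(range(pv))
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  n <- length(pv)
  muP <- mean(pv); muS <- mean(sv)
  varP <- sum((pv - muP)^2) / n; varS <- sum((sv - muS)^2) / n
  covPS <- sum((pv - muP) * (sv - muS)) / n
  want <- ((2 * muS * muP + C1) * (2 * covPS + C2)) /
    ((muS^2 + muP^2 + C1) * (varS + varP + C2))
  expect_equal(computeSSIM(p, s), want, tolerance = 1e-12)
})

test_that("ROI restriction and empty-ROI guard work", {
  p <- vol(c(0, 0, 0, 0))
  s <- vol(c(100, 0, 0, 0))
  roi <- mask(c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(computeMAE(p, s), 25)
  expect_equal(computeMAE(p, s, roi), 0)
  expect_error(computeME(p, s, mask(rep(FALSE, 4))), "empty")
})

test_that("the full report satisfies its internal invariants", {
  anat <- buildAnatomy(smallSpec())
  sct <- applyErrorModel(anat$ct, anat$structures$BODY,
                         errorModel(globalBias = 24, noiseSigma = 35),
                         seed = 2L)
  q <- imageQuality(anat$ct, sct, roi = anat$structures$BODY)
  expect_s4_class(q, "QualityReport")
  expect_gte(q@mae, abs(q@me))
  expect_gte(q@rmse, q@mae)
  expect_equal(q@roiVoxels, voxelCount(anat$structures$BODY))
  expect_true(q@ssim <= 1 && q@ssim >= -1)
})
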