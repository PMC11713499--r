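test_that("anatomy construction places the expected tissue classes", {
  spec <- phantomSpec(gridShape = c(24L, 24L, 24L), spacing = c(7, 7, 7),
                      airCavityRadii = numeric(0), seed = 2L)
  anat <- buildAnatomy(spec)
  ct <- anat$ct
  # probe at head center: soft tissue
  expect_equal(interpolateAt(ct, c(0, 0, 0)), spec@huSoft)
  # BODY excludes every background-air voxel
  body <- anat$structures$BODY
  expect_true(all(values(ct)[values(body)] > spec@huAir + 50))
  expect_true(all(values(ct)[!values(body)] == spec@huAir))
  # skull shell voxels carry exactly huBone before error injection
  shell <- values(ct) == spec@huBone
  expect_gt(sum(shell), 0)
  expect_equal(sort(unique(as.vector(values(ct)))),
               c(spec@huAir, spec@huSoft, spec@huBone))
})

test_that("target sphere outside the body is rejected", {
  spec <- smallSpec()
  expect_error(buildAnatomy(spec, targetCenter = c(500, 0, 0)),
               "outside the body")
})

test_that("all-zero error model returns the input exactly", {
  anat <- buildAnatomy(smallSpec())
  sct <- applyErrorModel(anat$ct, anat$structures$BODY, errorModel(),
                         seed = 9L)
  expect_identical(values(sct), values(anat$ct))
})

test_that("bias-only model forces ME equal to the injected bias", {
  anat <- buildAnatomy(smallSpec())
  sct <- applyErrorModel(anat$ct, anat$structures$BODY,
                         errorModel(globalBias = 25), seed = 1L)
  expect_equal(computeME(anat$ct, sct, anat$structures$BODY), 25,
               tolerance = 1e-12)
  # outside BODY untouched
  out <- !values(anat$structures$BODY)
  expect_identical(values(sct)[out], values(anat$ct)[out])
})

test_that("noise-only model gives MAE near the half-normal mean", {
  spec <- phantomSpec(gridShape = c(48L, 48L, 48L), spacing = c(4, 4, 4),
                      seed = 3L)
  anat <- buildAnatomy(spec)
  sct <- applyErrorModel(anat$ct, anat$structures$BODY,
                         errorModel(noiseSigma = 50), seed = 4L)
  mae <- computeMAE(anat$ct, sct, anat$structures$BODY)
  expect_equal(mae, 50 * sqrt(2 / pi), tolerance = 0.03)
})

test_that("error model is deterministic given the seed", {
  anat <- buildAnatomy(smallSpec())
  m <- errorModel(globalBias = 10, noiseSigma = 40, boneDilation = 7,
                  contourShift = 7)
  a <- applyErrorModel(anat$ct, anat$structures$BODY, m, seed = 11L)
  b <- applyErrorModel(anat$ct, anat$structures$BODY, m, seed = 11L)
  expect_identical(values(a), values(b))
  c2 <- applyErrorModel(anat$ct, anat$structures$BODY, m, seed = 12L)
  expect_false(identical(values(a), values(c2)))
})

test_that("bone dilation grows and erosion shrinks the bone compartment", {
  anat <- buildAnatomy(smallSpec())
  body <- anat$structures$BODY
  nBone <- function(v) sum(values(v) > 200 & values(body))
  grown <- applyErrorModel(anat$ct, body, errorModel(boneDilation = 7))
  shrunk <- applyErrorModel(anat$ct, body, errorModel(boneDilation = -7))
  expect_gt(nBone(grown), nBone(anat$ct))
  expect_lt(nBone(shrunk), nBone(anat$ct))
})

test_that("metal artifact carves the declared void", {
  anat <- buildAnatomy(smallSpec())
  m <- errorModel(metalArtifact = c(0, 0, 0, 15, -950))
  sct <- applyErrorModel(anat$ct, anat$structures$BODY, m)
  expect_equal(interpolateAt(sct, c(0, 0, 0)), -950)
})

test_that("toy dose follows the closed-form exponential in uniform media", {
  # vacuum at -1000 HU inside a forced body: no attenuation
  arr <- array(-1000, c(20, 3, 3))
  ct <- ScalarVolume(arr, spacing = c(5, 5, 5), unit = "HU")
  beam <- beamSpec(direction = "x+", entranceDose = 10,
                   attenuationScale = 0.005)
  d <- computeToyDose(ct, beam, bodyThreshold = -1500)
  expect_true(all(abs(values(d) - 10) < 1e-9))
  # uniform water: dose = entrance * exp(-scale * depth-to-voxel-center)
  arrW <- array(0, c(25, 3, 3))
  ctW <- ScalarVolume(arrW, spacing = c(8, 8, 8), unit = "HU")
  dW <- computeToyDose(ctW, beam, bodyThreshold = -500)
  depth <- (seq_len(25) - 0.5) * 8
  expect_equal(values(dW)[, 2, 2], 10 * exp(-0.005 * depth),
               tolerance = 1e-12)
  # the voxel centered 100 mm deep matches entrance * e^-0.5
  expect_equal(values(dW)[13, 2, 2], 10 * exp(-0.5), tolerance = 1e-12)
})

test_that("a +1000 HU offset attenuates dose by the closed-form ratio", {
  arrA <- array(0, c(30, 3, 3))
  arrB <- array(1000, c(30, 3, 3))
  sp <- c(4, 4, 4)
  beam <- beamSpec(direction = "x+", entranceDose = 1,
                   attenuationScale = 0.004)
  dA <- computeToyDose(ScalarVolume(arrA, spacing = sp), beam, -500)
  dB <- computeToyDose(ScalarVolume(arrB, spacing = sp), beam, -500)
  depth <- (seq_len(30) - 0.5) * 4
  ratio <- values(dB)[, 2, 2] / values(dA)[, 2, 2]
  expect_equal(ratio, exp(-0.004 * depth), tolerance = 1e-12)
})

test_that("dose is zero outside the body and non-increasing along rays", {
  anat <- buildAnatomy(smallSpec())
  d <- computeToyDose(anat$ct, beamSpec())
  outside <- values(anat$ct) <= -950
  expect_true(all(values(d)[outside] == 0))
  expect_true(all(values(d) >= 0))
  # in homogeneous runs dose never increases with depth
  mid <- values(d)[, 12, 12]
  inside <- which(mid > 0)
  expect_true(all(diff(mid[inside]) <= 1e-9))
})

test_that("generated cases are deterministic and identity maps to equality", {
  spec <- smallSpec(seed = 8L)
  cb1 <- generateCase(spec, errorModel(), beamSpec())
  cb2 <- generateCase(spec, errorModel(), beamSpec())
  expect_identical(values(cb1@planningCT), values(cb2@planningCT))
  expect_identical(values(cb1@doseEvaluated), values(cb2@doseEvaluated))
  expect_identical(values(cb1@doseReference), values(cb1@doseEvaluated))
  expect_gt(cb1@prescriptionDose, 0)
})

test_that("increasing global bias monotonically increases the pair MAE", {
  spec <- smallSpec(seed = 5L)
  maes <- vapply(c(5, 15, 30, 60), function(b) {
    cb <- generateCase(spec, errorModel(globalBias = b), beamSpec())
    computeMAE(cb@planningCT, cb@syntheticCT)
  }, numeric(1))
  expect_true(all(diff(maes) > 0))
})
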