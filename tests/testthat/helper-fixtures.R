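# shared fixture builders; everything is generated in code at test time

# tiny volume with explicit values, default unit grid
vol <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                unit = "") {
  if (is.null(dim(values))) dim(values) <- c(length(values), 1L, 1L)
  ScalarVolume(values, spacing = spacing, origin = origin, unit = unit)
}

mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                 name = "roi") {
  if (is.null(dim(values))) dim(values) <- c(length(values), 1L, 1L)
  BinaryMask(name, values, spacing = spacing, origin = origin)
}

# smooth, gently graded dose pair: broad Gaussian blobs on a high plateau,
# the evaluated member perturbed in blob amplitude/position and overall
# scale; gradients are kept shallow so lattice-sampling error stays well
# inside the gamma oracle-equivalence band
makeDosePair <- function(seed, shape = c(12, 12, 12), sp = 2.5,
                         ampJitter = 0.01, posJitter = 0.3,
                         scaleJitter = 0.005) {
  set.seed(seed)
  nb <- 3L
  ctr <- matrix(runif(3 * nb, 0.2, 0.8), nb) * rep((shape - 1) * sp,
                                                   each = nb)
  amp <- runif(nb, 0.03, 0.05)
  sg <- runif(nb, 12, 18)
  da <- rnorm(nb, 0, ampJitter) * amp
  dc <- matrix(rnorm(3 * nb, 0, posJitter), nb)
  scl <- 1 + rnorm(1, 0, scaleJitter)
  blobs <- function(ctr, amp) {
    xs <- (seq_len(shape[1]) - 1) * sp
    ys <- (seq_len(shape[2]) - 1) * sp
    zs <- (seq_len(shape[3]) - 1) * sp
    v <- array(0.85, shape)
    for (b in seq_len(nb)) {
      r2 <- outer(outer((xs - ctr[b, 1])^2, (ys - ctr[b, 2])^2, "+"),
                  (zs - ctr[b, 3])^2, "+")
      v <- v + amp[b] * exp(-r2 / (2 * sg[b]^2))
    }
    v
  }
  list(ref = ScalarVolume(50 * blobs(ctr, amp), spacing = rep(sp, 3),
                          unit = "Gy"),
       ev = ScalarVolume(50 * scl * blobs(ctr + dc, amp + da),
                         spacing = rep(sp, 3), unit = "Gy"))
}

# small phantom used across tests (fast to build, all tissue classes)
smallSpec <- function(seed = 1L) {
  phantomSpec(gridShape = c(24L, 24L, 24L), spacing = c(7, 7, 7), seed = seed)
}

gammaValuesAt <- function(result) {
  g <- values(gammaField(result))
  g[g >= 0]
}

# cross-test cache so expensive cohort runs are computed once per session
.fixtureCache <- new.env(parent = emptyenv())
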