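# Temporal feature pyramid and gated dynamic fusion.

test_that("pyramid level lengths follow the floor-halving law", {
  for (T_ in 4:64) {
    expect_identical(fpn_level_lengths(T_), c(T_, T_ %/% 2L, T_ %/% 4L))
  }
  expect_identical(fpn_level_lengths(7L), c(7L, 3L, 1L))
})

test_that("fpn_level1 preserves length and defaults to the identity", {
  set.seed(1)
  x <- matrix(rnorm(8 * 4), 8, 4)
  # identity kernel, eval BN, no dropout; BN's variance epsilon leaves a
  # relative wobble of ~5e-6
  expect_equal(fpn_level1(x), x, tolerance = 1e-4)
  w <- matrix(rnorm(4 * 3), 4, 3)
  got <- fpn_level1(x, convw = w)
  expect_identical(dim(got), dim(x))
  # sliding-window oracle for the depthwise same-padded convolution
  xp <- rbind(0, x, 0)
  want <- sapply(1:4, function(c)
    sapply(1:8, function(t) sum(w[c, ] * xp[t:(t + 2), c])))
  expect_equal(got, want, tolerance = 1e-4)
})

test_that("fpn_downsample pools to floor(L/2) with elementwise max", {
  expect_identical(nrow(fpn_downsample(matrix(0, 500, 2))), 250L)
  x7 <- matrix(rnorm(7 * 2), 7, 2)
  d1 <- fpn_downsample(x7)
  expect_identical(nrow(d1), 3L)
  expect_identical(nrow(fpn_downsample(d1)), 1L)
  expect_warning(res <- fpn_downsample(d1[1, , drop = FALSE]), "omitted")
  expect_null(res)
  # brute-force max over non-overlapping pairs (identity conv)
  x <- matrix(c(1, 5, 2, 2, 9, 0, 3, 3, -1, 4, 7, 7), 6, 2)
  got <- fpn_downsample(x)
  want <- rbind(pmax(x[1, ], x[2, ]), pmax(x[3, ], x[4, ]), pmax(x[5, ], x[6, ]))
  expect_equal(got, want)
})

test_that("nearest upsampling enumerates the expected index map", {
  x <- matrix(c(1, 2, 10, 20), 2, 2)   # rows a, b
  up <- upsample_seq(x, 4L)
  expect_equal(up, x[c(1, 1, 2, 2), ])
  expect_equal(upsample_seq(x, 2L), x)
  # exact-target trimming for odd reference lengths
  expect_identical(nrow(upsample_seq(matrix(0, 3, 1), 7L)), 7L)
})

test_that("fpn_fuse aligns levels to the reference length", {
  set.seed(2)
  pyr_a <- list(matrix(rnorm(16), 8, 2), matrix(rnorm(8), 4, 2),
                matrix(rnorm(4), 2, 2))
  pyr_v <- lapply(pyr_a, function(m) m + 1)
  r <- fpn_fuse(pyr_a, pyr_v, d_level = 3L, D_f = 5L)
  expect_identical(dim(r$features), c(8L, 5L))
  expect_identical(r$T_ref, 8L)
  # all-zero input maps to the broadcast output bias
  z <- lapply(pyr_a, function(m) m * 0)
  b_out <- c(1, -2, 0.5, 3, 0)
  r0 <- fpn_fuse(z, z, b_out = b_out, d_level = 3L, D_f = 5L)
  expect_equal(r0$features, matrix(b_out, 8, 5, byrow = TRUE))
})

test_that("gated fusion obeys the sigmoid gate laws", {
  set.seed(4)
  a <- matrix(rnorm(10 * 6), 10, 6)
  v <- matrix(rnorm(10 * 6), 10, 6)
  # zero gate logits: gamma exactly 0.5, fused = elementwise average
  r <- gated_fusion(a, v)
  expect_identical(r$gamma, rep(0.5, 6))
  expect_equal(r$fused, (a + v) / 2)
  # saturated logits: fused converges to the audio stream
  r <- gated_fusion(a, v, bg = rep(50, 6))
  expect_equal(r$fused, a, tolerance = 1e-12)
  # random case against the direct arithmetic oracle
  Wg <- matrix(rnorm(12 * 6, sd = 0.3), 12, 6); bg <- rnorm(6)
  r <- gated_fusion(a, v, Wg, bg)
  gam <- 1 / (1 + exp(-(drop(c(colMeans(a), colMeans(v)) %*% Wg) + bg)))
  expect_equal(r$gamma, gam)
  expect_equal(r$fused, sweep(a, 2, gam, "*") + sweep(v, 2, 1 - gam, "*"))
  expect_true(all(r$gamma > 0 & r$gamma < 1))
  # timestep granularity produces a T x D gate
  rt <- gated_fusion(a, v, Wg, bg, granularity = "timestep")
  expect_identical(dim(rt$gamma), c(10L, 6L))
  expect_error(gated_fusion(a, v[1:5, ]), "length mismatch")
})

test_that("gradient of the fused stream w.r.t. audio equals gamma", {
  set.seed(5)
  a <- matrix(rnorm(50 * 4), 50, 4); v <- matrix(rnorm(50 * 4), 50, 4)
  # with a constant gate the derivative is exactly gamma
  base <- gated_fusion(a, v)
  eps <- 1e-6
  a2 <- a; a2[3, 2] <- a2[3, 2] + eps
  expect_equal((gated_fusion(a2, v)$fused[3, 2] - base$fused[3, 2]) / eps,
               0.5, tolerance = 1e-6)
  # with a learned gate the pooled-gate correction is O(1/T)
  Wg <- matrix(rnorm(8 * 4, sd = 0.3), 8, 4)
  base <- gated_fusion(a, v, Wg)
  got <- (gated_fusion(a2, v, Wg)$fused[3, 2] - base$fused[3, 2]) / eps
  expect_equal(got, base$gamma[2], tolerance = 1e-2)
})

test_that("fusion paths widen and ablate as configured", {
  dims <- function(fusion) {
    m <- tiny_model(fusion = fusion)
    nrow(get("fuse.W", envir = m$P))
  }
  D <- 8L
  expect_identical(dims("dual"), 2L * D)      # FPN path + gated path
  expect_identical(dims("fpn_only"), D)       # ablation halves the width
  expect_identical(dims("gd_only"), D)
  expect_identical(dims("concat"), 2L * D)    # plain-concat baseline
  expect_error(asym_model(load_config(overrides = tiny_overrides(
    fusion = "concat", modality = "audio")), 3L, 5L), "both modalities")
})

test_that("model fusion output composes the two path oracles", {
  m <- tiny_model(seed = 9L)
  p <- rand_pair(T_ = 16L)
  fw <- asym:::asym_forward_cache(m, p$audio, p$video)
  A <- fw$cache$A_al; V <- fw$cache$V_al
  # gated path recomputed with the exported op and the model's own gate
  gd <- gated_fusion(A, V, get("gate.W", envir = m$P),
                     get("gate.b", envir = m$P))
  expect_equal(fw$cache$gate$gam, gd$gamma, tolerance = 1e-10)
  # fuse input = [fpn path, gated path] on channels
  expect_equal(fw$cache$fu$X[, 9:16], gd$fused, tolerance = 1e-10)
  expect_equal(fw$cache$fu$X[, 1:8], fw$cache$fo$out, tolerance = 1e-10)
})
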