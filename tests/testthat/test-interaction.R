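# Front-end projection, cross-modal attention, merge, co-interaction.

test_that("frontend_project maps to the common width per time step", {
  set.seed(1)
  x <- matrix(rnorm(10 * 25), 10, 25)
  y <- frontend_project(x, out_width = 256L)
  expect_identical(dim(y), c(10L, 256L))
  # identity map on matching widths
  expect_equal(frontend_project(x, W = diag(25)), x)
  # explicit per-step matrix-multiply oracle
  W <- matrix(rnorm(25 * 7), 25, 7); b <- rnorm(7)
  got <- frontend_project(x, W, b)
  want <- t(apply(x, 1L, function(r) drop(r %*% W) + b))
  expect_equal(got, want)
})

test_that("attention weights are row-stochastic and reduce correctly", {
  # single query / single context step: weight 1, aligned = the value row
  r <- scaled_dot_attention(matrix(1, 1, 2), matrix(2, 1, 2),
                            matrix(c(3, 4), 1, 2), n_heads = 1L)
  expect_equal(drop(r$map[[1L]]), 1)
  expect_equal(r$aligned, matrix(c(3, 4), 1, 2))
  # identical keys: uniform weights, aligned = mean of value rows
  K <- matrix(1, 3, 2)
  V <- matrix(rnorm(6), 3, 2)
  r <- scaled_dot_attention(matrix(rnorm(4), 2, 2), K, V, n_heads = 1L)
  expect_equal(r$map[[1L]], matrix(1 / 3, 2, 3))
  expect_equal(r$aligned, rbind(colMeans(V), colMeans(V)))
  # random maps: every (head, query) row sums to one
  set.seed(5)
  r <- scaled_dot_attention(matrix(rnorm(12 * 8), 12, 8),
                            matrix(rnorm(20 * 8), 20, 8),
                            matrix(rnorm(20 * 8), 20, 8), n_heads = 2L)
  for (P in r$map) {
    expect_true(all(abs(rowSums(P) - 1) < 1e-5))
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("a 2x3 hand case matches the brute-force softmax oracle", {
  Q <- matrix(c(1, 0, 0, 1), 2, 2)
  K <- matrix(c(1, 2, -1, 0, 1, 1), 3, 2)
  V <- matrix(c(1, 0, 2, -1, 3, 0.5), 3, 2)
  got <- scaled_dot_attention(Q, K, V, n_heads = 1L)
  want <- attn_oracle(Q, K, V)
  expect_equal(got$map[[1L]], want$P, tolerance = 1e-12)
  expect_equal(got$aligned, want$O, tolerance = 1e-12)
})

test_that("attention is permutation-equivariant in the context axis", {
  set.seed(6)
  Q <- matrix(rnorm(8 * 4), 8, 4)
  K <- matrix(rnorm(10 * 4), 10, 4)
  V <- matrix(rnorm(10 * 4), 10, 4)
  perm <- sample(10)
  a <- scaled_dot_attention(Q, K, V, n_heads = 2L)
  b <- scaled_dot_attention(Q, K[perm, ], V[perm, ], n_heads = 2L)
  expect_equal(b$aligned, a$aligned)
  for (h in 1:2) expect_equal(b$map[[h]], a$map[[h]][, perm])
})

test_that("cross_attention keeps the query length and exposes direction", {
  set.seed(2)
  a <- matrix(rnorm(7 * 6), 7, 6); v <- matrix(rnorm(11 * 6), 11, 6)
  r <- cross_attention(a, v, attention_config(2L, 3L, "audio_to_video"))
  expect_identical(dim(r$aligned), c(7L, 6L))
  expect_identical(dim(r$map[[1L]]), c(7L, 11L))
  expect_identical(r$direction, "audio_to_video")
})

test_that("merge_aligned is residual-add + layer norm", {
  set.seed(3)
  ctx <- matrix(rnorm(5 * 6), 5, 6)
  al <- matrix(rnorm(5 * 6), 5, 6)
  expect_equal(merge_aligned(ctx, 0 * al), ln_oracle(ctx), tolerance = 1e-7)
  expect_equal(merge_aligned(ctx, ctx), merge_aligned(ctx, ctx))
  expect_equal(merge_aligned(ctx, al), ln_oracle(ctx + al), tolerance = 1e-7)
  expect_error(merge_aligned(ctx, al[1:3, ]), "shape mismatch")
})

test_that("co_interact preserves per-modality lengths and shares dynamics", {
  set.seed(8)
  cfg <- bimamba_config(8L, state_dim = 4L, dt_rank = 2L)
  a <- matrix(rnorm(40 * 8), 40, 8)
  v <- matrix(rnorm(60 * 8), 60, 8)
  r <- co_interact(a, v, cfg, seed = 3L)
  expect_identical(dim(r$audio_ctx), c(40L, 8L))
  expect_identical(dim(r$video_ctx), c(60L, 8L))
  # finite-difference: the shared transition entries move BOTH outputs
  eps <- 1e-3
  Al <- get("bmShared.fwd.A_log", envir = r$pair$a$store)
  assign("bmShared.fwd.A_log", Al + eps, envir = r$pair$a$store)
  da <- sum(abs(bimamba_forward(r$pair$a, a) - r$audio_ctx))
  dv <- sum(abs(bimamba_forward(r$pair$b, v) - r$video_ctx))
  expect_gt(da / eps, 1e-6)
  expect_gt(dv / eps, 1e-6)
})

test_that("attention maps are bit-for-bit reproducible", {
  m <- tiny_model(seed = 5L)
  p <- rand_pair()
  a1 <- asym_predict(m, p$audio, p$video, return_attention = TRUE)$attn
  a2 <- asym_predict(m, p$audio, p$video, return_attention = TRUE)$attn
  expect_identical(a1, a2)
})

test_that("swapping private parameters swaps the co-block outputs exactly", {
  cfg <- bimamba_config(8L, state_dim = 4L, dt_rank = 2L)
  pr <- make_shared_pair(cfg, seed = 19L)
  set.seed(2)
  x <- matrix(rnorm(12 * 8), 12, 8)
  ya <- bimamba_forward(pr$a, x)
  yb <- bimamba_forward(pr$b, x)
  # swap every private tensor between the two blocks (shared ones stay put)
  st <- pr$a$store
  priv <- function(pfx) grep(sprintf("^%s\\.", pfx), ls(st), value = TRUE)
  pa <- priv("bmA"); pb <- priv("bmB")
  suff <- function(n) sub("^[^.]+\\.", "", n)
  expect_setequal(vapply(pa, suff, "", USE.NAMES = FALSE),
                  vapply(pb, suff, "", USE.NAMES = FALSE))
  for (n in pa) {
    twin <- paste0("bmB.", suff(n))
    tmp <- get(n, envir = st)
    assign(n, get(twin, envir = st), envir = st)
    assign(twin, tmp, envir = st)
  }
  expect_equal(bimamba_forward(pr$a, x), yb, tolerance = 1e-12)
  expect_equal(bimamba_forward(pr$b, x), ya, tolerance = 1e-12)
})
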