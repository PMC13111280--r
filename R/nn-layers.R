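# Internal differentiable primitives.
#
# Every layer comes as a `*_f` forward returning (out, cache) and a `*_b`
# backward mapping the upstream gradient plus the cache to gradients for
# inputs and parameters. Sequences are T x D matrices (time in rows).
# These are deliberately plain-matrix functions: all heavy lifting is BLAS
# matmuls or the compiled scan kernels in src/.

lin_f <- function(X, W, b = NULL) {
  Y <- X %*% W
  if (!is.null(b)) Y <- sweep(Y, 2L, b, "+")
  list(out = Y, X = X)
}

lin_b <- function(dY, cache, W, has_bias = TRUE) {
  list(dX = dY %*% t(W),
       dW = crossprod(cache$X, dY),
       db = if (has_bias) colSums(dY) else NULL)
}

# Depthwise (channel-wise) 1-D convolution, zero padded.
# w: D x k. mode "causal" uses taps x[t-k+1..t]; "same" centers odd kernels.
dw_offsets <- function(k, mode) {
  if (mode == "causal") seq_len(k) - k else seq_len(k) - (k + 1L) %/% 2L
}

dwconv_f <- function(X, w, b, mode = c("causal", "same")) {
  mode <- match.arg(mode)
  list(out = dwconv_fwd_cpp(X, w, b, mode == "causal"), X = X, mode = mode)
}

dwconv_b <- function(dY, cache, w) {
  dwconv_bwd_cpp(dY, cache$X, w, cache$mode == "causal")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

silu_f <- function(X) {
  s <- sigmoid(X)
  list(out = X * s, X = X, s = s)
}

silu_b <- function(dY, cache) {
  s <- cache$s
  dY * (s * (1 + cache$X * (1 - s)))
}

relu_f <- function(X) list(out = pmax(X, 0), mask = X > 0)

relu_b <- function(dY, cache) dY * cache$mask

# Layer normalization over channels, per time step, with affine transform.
ln_f <- function(X, g, b, eps = 1e-5) {
  mu <- .rowMeans(X, nrow(X), ncol(X))
  xc <- X - mu
  v <- .rowMeans(xc^2, nrow(X), ncol(X))
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  Y <- sweep(xhat * matrix(g, nrow(X), ncol(X), byrow = TRUE), 2L, b, "+")
  list(out = Y, xhat = xhat, istd = istd)
}

ln_b <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- dY * matrix(g, nrow(dY), ncol(dY), byrow = TRUE)
  m1 <- .rowMeans(dxhat, nrow(dY), ncol(dY))
  m2 <- .rowMeans(dxhat * xhat, nrow(dY), ncol(dY))
  dX <- (dxhat - m1 - xhat * m2) * cache$istd
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

# Batch-norm stand-in that never mixes samples: statistics are taken over
# the time axis of the current sequence in training mode, and over the
# tracked running moments in eval mode. Keeps predictions invariant to
# batch composition and makes fresh eval-mode BN an exact identity.
bn_f <- function(X, g, b, state, key, training, momentum = 0.1, eps = 1e-5) {
  D <- ncol(X)
  if (is.null(state[[paste0(key, ".rm")]])) {
    state[[paste0(key, ".rm")]] <- numeric(D)
    state[[paste0(key, ".rv")]] <- rep(1, D)
  }
  if (training && nrow(X) > 1L) {
    mu <- colMeans(X)
    xc <- sweep(X, 2L, mu)
    v <- colMeans(xc^2)
    state[[paste0(key, ".rm")]] <- (1 - momentum) * state[[paste0(key, ".rm")]] + momentum * mu
    state[[paste0(key, ".rv")]] <- (1 - momentum) * state[[paste0(key, ".rv")]] + momentum * v
    istd <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2L, istd, "*")
    train_stats <- TRUE
  } else {
    mu <- state[[paste0(key, ".rm")]]
    istd <- 1 / sqrt(state[[paste0(key, ".rv")]] + eps)
    xhat <- sweep(sweep(X, 2L, mu), 2L, istd, "*")
    train_stats <- FALSE
  }
  Y <- sweep(xhat * matrix(g, nrow(X), D, byrow = TRUE), 2L, b, "+")
  list(out = Y, xhat = xhat, istd = istd, train_stats = train_stats)
}

bn_b <- function(dY, cache, g) {
  xhat <- cache$xhat
  gm <- matrix(g, nrow(dY), ncol(dY), byrow = TRUE)
  dxhat <- dY * gm
  if (cache$train_stats) {
    m1 <- matrix(colMeans(dxhat), nrow(dY), ncol(dY), byrow = TRUE)
    m2 <- matrix(colMeans(dxhat * xhat), nrow(dY), ncol(dY), byrow = TRUE)
    dX <- sweep(dxhat - m1 - xhat * m2, 2L, cache$istd, "*")
  } else {
    dX <- sweep(dxhat, 2L, cache$istd, "*")
  }
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

dropout_f <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, mask = NULL))
  mask <- matrix(stats::rbinom(length(X), 1L, 1 - rate), nrow(X), ncol(X)) / (1 - rate)
  list(out = X * mask, mask = mask)
}

dropout_b <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

# Non-overlapping max pooling, window 2 stride 2; drops a trailing odd step.
maxpool2_f <- function(X) {
  L <- nrow(X) %/% 2L
  a <- X[seq(1L, 2L * L, by = 2L), , drop = FALSE]
  b <- X[seq(2L, 2L * L, by = 2L), , drop = FALSE]
  take_a <- a >= b
  list(out = ifelse(take_a, a, b), take_a = take_a, T_in = nrow(X))
}

maxpool2_b <- function(dY, cache) {
  L <- nrow(dY)
  dX <- matrix(0, cache$T_in, ncol(dY))
  dX[seq(1L, 2L * L, by = 2L), ] <- dY * cache$take_a
  dX[seq(2L, 2L * L, by = 2L), ] <- dY * !cache$take_a
  dX
}

# Nearest-neighbor upsampling of an L x D sequence to L_ref rows.
# Index map: row t of the output copies row ceiling(t*L/L_ref) of the input,
# so [a, b] upsampled to length 4 is [a, a, b, b].
upsample_idx <- function(L, L_ref) pmax(1L, as.integer(ceiling(seq_len(L_ref) * L / L_ref)))

upsample_f <- function(X, L_ref) {
  idx <- upsample_idx(nrow(X), L_ref)
  list(out = X[idx, , drop = FALSE], idx = idx, L_in = nrow(X))
}

upsample_b <- function(dY, cache) {
  dX <- matrix(0, cache$L_in, ncol(dY))
  agg <- rowsum(dY, group = cache$idx)
  dX[as.integer(rownames(agg)), ] <- agg
  dX
}

softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / .rowSums(E, nrow(E), ncol(E))
}

# Multi-head scaled dot-product attention on already-projected Q, K, V
# (T_q x d, T_k x d). Heads split the feature axis. Returns the concatenated
# head outputs plus the per-head attention weights.
mha_f <- function(Q, K, V, n_heads) {
  d <- ncol(Q)
  stopifnot(d %% n_heads == 0L)
  dh <- d %/% n_heads
  O <- matrix(0, nrow(Q), d)
  Ps <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
    P <- softmax_rows(S)
    O[, cols] <- P %*% V[, cols, drop = FALSE]
    Ps[[h]] <- P
  }
  list(out = O, P = Ps, Q = Q, K = K, V = V, n_heads = n_heads, dh = dh)
}

mha_b <- function(dO, cache) {
  dh <- cache$dh
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (h in seq_len(cache$n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    P <- cache$P[[h]]
    dOh <- dO[, cols, drop = FALSE]
    dV[, cols] <- crossprod(P, dOh)
    dP <- tcrossprod(dOh, cache$V[, cols, drop = FALSE])
    dS <- P * (dP - .rowSums(dP * P, nrow(P), ncol(P)))
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE] / sqrt(dh)
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE]) / sqrt(dh)
  }
  list(dQ = dQ, dK = dK, dV = dV)
}
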