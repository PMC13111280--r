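# Shared fixtures and independent oracles.

# Literal step-by-step recursion oracle for the constant-parameter scan:
# an R loop written directly from the recurrences, independent of the
# compiled kernel.
naive_scan <- function(A, B, C, x, reverse = FALSE) {
  if (is.vector(A)) A <- diag(A, nrow = length(A))
  T_ <- nrow(x); D <- ncol(x); N <- nrow(A)
  expand <- function(M) {
    if (is.vector(M)) M <- matrix(M, N, 1L)
    if (ncol(M) == D) M else matrix(M[, 1L], N, D)
  }
  B <- expand(B); C <- expand(C)
  y <- matrix(0, T_, D)
  steps <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  for (d in seq_len(D)) {
    h <- numeric(N)
    for (t in steps) {
      h <- drop(A %*% h) + B[, d] * x[t, d]
      y[t, d] <- sum(C[, d] * h)
    }
  }
  y
}

# Plain layer-norm oracle (per row, identity affine).
ln_oracle <- function(X, eps = 1e-5) {
  t(apply(X, 1L, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps)))
}

# Explicit single-head softmax-attention oracle.
attn_oracle <- function(Q, K, V) {
  S <- Q %*% t(K) / sqrt(ncol(Q))
  P <- t(apply(S, 1L, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  list(P = P, O = P %*% V)
}

tiny_overrides <- function(...) {
  utils::modifyList(
    list(d_model = 8L, state_dim = 4L, n_heads = 2L, d_attn = 4L,
         n_blocks = 1L, d_level = 2L, d_head = 4L, dropout = 0),
    list(...))
}

tiny_model <- function(seed = 42L, f_audio = 3L, f_video = 5L, ...) {
  cfg <- load_config(profile = "synth", overrides = tiny_overrides(...))
  asym_model(cfg, f_audio = f_audio, f_video = f_video, seed = seed)
}

rand_pair <- function(T_ = 12L, f_audio = 3L, f_video = 5L, seed = 7L) {
  set.seed(seed)
  list(audio = matrix(rnorm(T_ * f_audio), T_, f_audio),
       video = matrix(rnorm(T_ * f_video), T_, f_video))
}
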