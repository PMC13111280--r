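# User-facing building-block operations. These are thin, stateless
# counterparts of the layers used inside the full model, exposed so that
# each architectural contract can be exercised (and tested) in isolation.

#' Construct a modality sequence record
#'
#' @param features `T x F` numeric matrix of per-frame features.
#' @param modality `"audio"` or `"video"`.
#' @param sample_id Sample identifier.
#' @param label Optional binary label (0/1).
#' @return A `modal_sequence` list.
#' @export
modal_sequence <- function(features, modality = c("audio", "video"),
                           sample_id = "s1", label = NULL) {
  modality <- match.arg(modality)
  features <- as.matrix(features)
  if (nrow(features) < 1L) stop("sequence must have T >= 1")
  check_finite_seq(features, sprintf("%s features of sample '%s'", modality, sample_id))
  if (!is.null(label) && !label %in% c(0L, 1L)) stop("label must be 0 or 1")
  structure(list(sample_id = sample_id, modality = modality,
                 features = features, label = label),
            class = "modal_sequence")
}

seq_features <- function(x) {
  if (inherits(x, "modal_sequence")) x$features else as.matrix(x)
}

#' Per-time-step linear projection to a common width
#'
#' The front-end of each modality: a 1x1 convolution over time, i.e. the
#' same linear map applied at every time step, taking `F` input channels to
#' `out_width` output channels.
#'
#' @param x A `T x F` matrix or [modal_sequence()].
#' @param W `F x out_width` weight matrix; when `NULL` a fresh
#'   Glorot-initialized matrix is drawn.
#' @param b Length-`out_width` bias (default zeros).
#' @param out_width Output channel count (required when `W` is `NULL`).
#' @return `T x out_width` matrix.
#' @export
frontend_project <- function(x, W = NULL, b = NULL, out_width = 256L) {
  X <- seq_features(x)
  if (is.null(W)) W <- glorot(ncol(X), out_width)
  if (is.null(b)) b <- numeric(ncol(W))
  lin_f(X, W, b)$out
}

#' Cross-modal attention configuration
#' @param n_heads Number of attention heads.
#' @param d_k Per-head key width.
#' @param direction `"audio_to_video"` or `"video_to_audio"` (metadata tag).
#' @return An `attention_config` list.
#' @export
attention_config <- function(n_heads = 2L, d_k = 8L,
                             direction = c("audio_to_video", "video_to_audio")) {
  stopifnot(n_heads >= 1L, d_k >= 1L)
  structure(list(n_heads = as.integer(n_heads), d_k = as.integer(d_k),
                 direction = match.arg(direction)),
            class = "attention_config")
}

#' Scaled dot-product attention on given Q, K, V
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V` per head (heads split the feature
#' axis). This is the bare attention equation; [cross_attention()] adds the
#' learned projections.
#'
#' @param Q,K,V Matrices `T_q x d`, `T_k x d`, `T_k x d`.
#' @param n_heads Number of heads (`d` must be divisible).
#' @return List with `aligned` (`T_q x d`) and `map` (list of per-head
#'   `T_q x T_k` row-stochastic weight matrices).
#' @export
scaled_dot_attention <- function(Q, K, V, n_heads = 1L) {
  m <- mha_f(as.matrix(Q), as.matrix(K), as.matrix(V), n_heads)
  list(aligned = m$out, map = m$P)
}

#' Cross-modal attention between two sequences
#'
#' Queries come from `query_seq`, keys and values from `context_seq`; the
#' output has the query's temporal length. Projection weights may be
#' supplied (as used inside a trained model) or drawn fresh.
#'
#' @param query_seq,context_seq `T x D` sequences at a common model width.
#' @param cfg An [attention_config()].
#' @param weights Optional named list `Wq, Wk, Wv, Wo` (`D x d_attn`, and
#'   `d_attn x D` for `Wo`) with optional biases `bq, bk, bv, bo`.
#' @return List with `aligned` (`T_q x D`) and `map`.
#' @export
cross_attention <- function(query_seq, context_seq, cfg = attention_config(),
                            weights = NULL) {
  Q0 <- seq_features(query_seq); C0 <- seq_features(context_seq)
  if (ncol(Q0) != ncol(C0)) stop("query and context must share model width")
  da <- cfg$n_heads * cfg$d_k
  if (is.null(weights)) {
    weights <- list(Wq = glorot(ncol(Q0), da), Wk = glorot(ncol(Q0), da),
                    Wv = glorot(ncol(Q0), da), Wo = glorot(da, ncol(Q0)))
  }
  zb <- function(b, n) if (is.null(b)) numeric(n) else b
  Q <- lin_f(Q0, weights$Wq, zb(weights$bq, da))$out
  K <- lin_f(C0, weights$Wk, zb(weights$bk, da))$out
  V <- lin_f(C0, weights$Wv, zb(weights$bv, da))$out
  m <- mha_f(Q, K, V, cfg$n_heads)
  aligned <- lin_f(m$out, weights$Wo, zb(weights$bo, ncol(Q0)))$out
  list(aligned = aligned, map = m$P, direction = cfg$direction)
}

#' Merge attention-aligned features back into a stream
#'
#' Residual addition followed by layer normalization (default), or
#' concatenation + projection when `W` is supplied.
#'
#' @param ctx,aligned Equal-shape `T x D` matrices.
#' @param g,b Layer-norm affine parameters (default identity).
#' @param W Optional `2D x D` projection enabling the `concat_project`
#'   merge variant.
#' @return Merged `T x D` matrix.
#' @export
merge_aligned <- function(ctx, aligned, g = NULL, b = NULL, W = NULL) {
  if (!all(dim(ctx) == dim(aligned))) stop("shape mismatch between ctx and aligned")
  D <- ncol(ctx)
  if (is.null(g)) g <- rep(1, D)
  if (is.null(b)) b <- numeric(D)
  pre <- if (is.null(W)) ctx + aligned else lin_f(cbind(ctx, aligned), W)$out
  ln_f(pre, g, b)$out
}

#' Co-process two modality streams with shared-dynamics Bi-Mamba blocks
#'
#' Each stream is transformed by its own Bi-Mamba block, where the two
#' blocks share their state-transition parameterization (see
#' [make_shared_pair()]). Temporal lengths may differ; shapes are
#' preserved.
#'
#' @param audio,video `T x D` sequences at a common model width.
#' @param cfg A [bimamba_config()].
#' @param seed Integer seed for the pair's parameters.
#' @param pair Optional existing pair from [make_shared_pair()].
#' @return List with `audio_ctx`, `video_ctx` and the `pair` used.
#' @export
co_interact <- function(audio, video, cfg = NULL, seed = 1L, pair = NULL) {
  audio <- as.matrix(audio); video <- as.matrix(video)
  if (ncol(audio) != ncol(video)) stop("modality streams must share model width")
  if (is.null(pair)) {
    if (is.null(cfg)) cfg <- bimamba_config(ncol(audio))
    pair <- make_shared_pair(cfg, seed = seed)
  }
  list(audio_ctx = bimamba_forward(pair$a, audio),
       video_ctx = bimamba_forward(pair$b, video),
       pair = pair)
}

# ---- pyramid ---------------------------------------------------------------

#' Temporal pyramid level lengths
#' @param T_in Input length.
#' @param levels Number of levels (default 3).
#' @return Integer vector `c(T, floor(T/2), floor(T/4), ...)`.
#' @export
fpn_level_lengths <- function(T_in, levels = 3L) {
  out <- integer(levels)
  out[1L] <- as.integer(T_in)
  for (l in seq_len(levels - 1L)) out[l + 1L] <- out[l] %/% 2L
  out
}

identity_kernel <- function(D, k) {
  w <- matrix(0, D, k)
  w[, (k + 1L) %/% 2L] <- 1
  w
}

#' Finest pyramid level: length-preserving convolution block
#'
#' Depthwise convolution (kernel 3, stride 1, same padding) followed by
#' batch normalization and dropout; the temporal length is preserved.
#' With the default `NULL` weights the convolution is the identity kernel
#' and BN is in (identity) eval mode, so the operation reduces to the
#' input.
#'
#' @param x `T x D` sequence.
#' @param convw `D x k` depthwise kernel (default identity).
#' @param convb Length-`D` bias.
#' @param dropout Dropout rate (applied only when `training = TRUE`).
#' @param training Logical.
#' @return `T x D` matrix.
#' @export
fpn_level1 <- function(x, convw = NULL, convb = NULL, dropout = 0.1,
                       training = FALSE) {
  X <- as.matrix(x)
  D <- ncol(X)
  if (is.null(convw)) convw <- identity_kernel(D, 3L)
  if (is.null(convb)) convb <- numeric(D)
  cv <- dwconv_f(X, convw, convb, "same")
  st <- new.env(parent = emptyenv())
  bn <- bn_f(cv$out, rep(1, D), numeric(D), st, "bn", training = FALSE)
  dropout_f(bn$out, dropout, training)$out
}

#' Downsample a pyramid level by two
#'
#' Convolution (kernel 3, same padding) followed by max pooling with
#' window and stride 2; the output length is `floor(L / 2)`.
#'
#' @param x_prev `L x D` sequence with `L >= 2`.
#' @param convw,convb Optional depthwise kernel and bias (default
#'   identity).
#' @return `floor(L/2) x D` matrix, or `NULL` (with a warning) when
#'   `L < 2`.
#' @export
fpn_downsample <- function(x_prev, convw = NULL, convb = NULL) {
  X <- as.matrix(x_prev)
  if (nrow(X) < 2L) {
    warning("pyramid level omitted: input length < 2")
    return(NULL)
  }
  D <- ncol(X)
  if (is.null(convw)) convw <- identity_kernel(D, 3L)
  if (is.null(convb)) convb <- numeric(D)
  cv <- dwconv_f(X, convw, convb, "same")
  maxpool2_f(cv$out)$out
}

#' Nearest-neighbor upsampling of a sequence
#' @param x `L x D` sequence.
#' @param L_ref Target length.
#' @param mode `"nearest"` or `"linear"`.
#' @return `L_ref x D` matrix.
#' @export
upsample_seq <- function(x, L_ref, mode = "nearest") {
  resample_f(as.matrix(x), as.integer(L_ref), mode)$out
}

#' Sigmoid-gated dynamic fusion of two modality streams
#'
#' Computes per-channel fusion weights
#' \eqn{\gamma = \sigma(W_g [a \oplus v])} from the temporally mean-pooled
#' concatenated features (or per time step with
#' `granularity = "timestep"`), then fuses
#' \eqn{\gamma \odot a + (1-\gamma) \odot v}.
#'
#' @param audio_feat,video_feat Equal-length `T x D` sequences.
#' @param Wg `2D x D` gate weight matrix (default zeros, giving the
#'   neutral gate `gamma = 0.5`).
#' @param bg Length-`D` gate bias.
#' @param granularity `"channel"` (one weight vector, broadcast over time)
#'   or `"timestep"`.
#' @return List with `gamma` and `fused` (the pre-projection weighted
#'   stream).
#' @export
gated_fusion <- function(audio_feat, video_feat, Wg = NULL, bg = NULL,
                         granularity = c("channel", "timestep")) {
  granularity <- match.arg(granularity)
  a <- as.matrix(audio_feat); v <- as.matrix(video_feat)
  if (!all(dim(a) == dim(v))) stop("length mismatch after alignment")
  D <- ncol(a)
  if (is.null(Wg)) Wg <- matrix(0, 2L * D, D)
  if (is.null(bg)) bg <- numeric(D)
  if (granularity == "channel") {
    pooled <- c(colMeans(a), colMeans(v))
    gamma <- sigmoid(drop(pooled %*% Wg) + bg)
    gm <- matrix(gamma, nrow(a), D, byrow = TRUE)
  } else {
    gamma <- sigmoid(sweep(cbind(a, v) %*% Wg, 2L, bg, "+"))
    gm <- gamma
  }
  list(gamma = gamma, fused = gm * a + (1 - gm) * v)
}

#' Linear classification head with temporal pooling
#'
#' Temporal pooling (mean by default) followed by a linear map and a
#' sigmoid; predictions use the threshold-0.5 convention with ties going
#' to the positive class.
#'
#' @param enhanced `T x D` sequence.
#' @param w Length-`D` weight vector (default zeros).
#' @param b Scalar bias.
#' @param pool `"mean"`, `"max"` or `"last"`.
#' @return List with `logit`, `probability`, `predicted_label`.
#' @export
classify <- function(enhanced, w = NULL, b = 0, pool = c("mean", "max", "last")) {
  pool <- match.arg(pool)
  X <- as.matrix(enhanced)
  if (is.null(w)) w <- numeric(ncol(X))
  pooled <- switch(pool, mean = colMeans(X), max = apply(X, 2L, max),
                   last = X[nrow(X), ])
  logit <- sum(pooled * w) + b
  p <- sigmoid(logit)
  list(logit = logit, probability = p, predicted_label = as.integer(p >= 0.5))
}

#' Fuse two modality pyramids into a single reference-resolution stream
#'
#' Per level, the two modalities' features are concatenated on channels
#' and passed through a (level-shared) 1x1 convolution; coarser levels are
#' upsampled to the bottom-level reference length; the three level outputs
#' are concatenated on channels and projected to `D_f` channels.
#'
#' @param pyr_audio,pyr_video Lists of pyramid levels (`T x D`,
#'   `floor(T/2) x D`, `floor(T/4) x D`); `pyr_video = NULL` fuses a single
#'   modality. Omitted (`NULL`) levels contribute zeros.
#' @param W_lvl,b_lvl Level-shared 1x1 convolution (`C_in x d_level`);
#'   defaults to an all-ones-free random draw when `NULL`.
#' @param W_out,b_out Output projection (`3*d_level x D_f`).
#' @param d_level,D_f Channel widths when weights are drawn.
#' @param upsample `"nearest"` or `"linear"`.
#' @return List with `features` (`T_ref x D_f`) and `T_ref`.
#' @export
fpn_fuse <- function(pyr_audio, pyr_video = NULL, W_lvl = NULL, b_lvl = NULL,
                     W_out = NULL, b_out = NULL, d_level = 8L, D_f = 16L,
                     upsample = "nearest") {
  stopifnot(length(pyr_audio) >= 1L)
  nlev <- length(pyr_audio)
  lv_in <- lapply(seq_len(nlev), function(l) {
    a <- pyr_audio[[l]]
    if (is.null(pyr_video)) return(a)
    v <- pyr_video[[l]]
    if (is.null(a) || is.null(v)) return(NULL)
    if (ncol(a) != ncol(v)) stop("channel widths differ between modalities")
    cbind(a, v)
  })
  c_in <- ncol(lv_in[[1L]])
  if (is.null(W_lvl)) W_lvl <- glorot(c_in, d_level)
  if (is.null(b_lvl)) b_lvl <- numeric(ncol(W_lvl))
  if (is.null(W_out)) W_out <- glorot(nlev * ncol(W_lvl), D_f)
  if (is.null(b_out)) b_out <- numeric(ncol(W_out))
  T_ref <- nrow(lv_in[[1L]])
  parts <- lapply(lv_in, function(x) {
    if (is.null(x)) return(matrix(0, T_ref, ncol(W_lvl)))
    y <- lin_f(x, W_lvl, b_lvl)$out
    if (nrow(y) != T_ref) y <- resample_f(y, T_ref, upsample)$out
    y
  })
  feats <- lin_f(do.call(cbind, parts), W_out, b_out)$out
  list(features = feats, T_ref = T_ref)
}

#' Residual convolution block
#'
#' conv -> BN -> ReLU -> conv -> BN, an identity skip, and a final ReLU;
#' the shape is preserved. With the default zero-initialized convolutions
#' and fresh (identity) eval-mode BN the block reduces to `ReLU(x)`.
#'
#' @param x `T x D` sequence.
#' @param w1,b1,w2,b2 Depthwise kernels (`D x k`, odd `k`) and biases;
#'   default zeros with `k = 3`.
#' @param training Logical (affects BN statistics only; fresh BN in eval
#'   mode is the identity map).
#' @return `T x D` matrix.
#' @export
res_block <- function(x, w1 = NULL, b1 = NULL, w2 = NULL, b2 = NULL,
                      training = FALSE) {
  X <- as.matrix(x)
  D <- ncol(X)
  if (is.null(w1)) w1 <- matrix(0, D, 3L)
  if (is.null(w2)) w2 <- matrix(0, D, 3L)
  if (is.null(b1)) b1 <- numeric(D)
  if (is.null(b2)) b2 <- numeric(D)
  if (ncol(w1) %% 2L == 0L || ncol(w2) %% 2L == 0L) stop("kernel must be odd")
  st <- new.env(parent = emptyenv())
  c1 <- dwconv_f(X, w1, b1, "same")
  n1 <- bn_f(c1$out, rep(1, D), numeric(D), st, "bn1", training)
  r1 <- relu_f(n1$out)
  c2 <- dwconv_f(r1$out, w2, b2, "same")
  n2 <- bn_f(c2$out, rep(1, D), numeric(D), st, "bn2", training)
  pmax(n2$out + X, 0)
}

#' Augment a training pool with random segments
#'
#' Applies [augment_random_segments()] to every sample with a per-sample
#' seed derived from the spec seed, and returns the original samples
#' followed by their segments (originals are always retained).
#'
#' @param samples List of samples.
#' @param spec An [augment_spec()].
#' @return Augmented sample list.
#' @export
augment_training_pool <- function(samples, spec = augment_spec()) {
  out <- samples
  for (i in seq_along(samples)) {
    sp_i <- spec
    sp_i$seed <- spec$seed + i
    out <- c(out, augment_random_segments(samples[[i]], sp_i))
  }
  out
}
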