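# Bi-Mamba block: two directional selective-SSM streams over a channel
# split of the input, concatenated and passed through a linear projection
# plus layer normalization.
#
# Parameters live in an environment ("store") keyed by dotted names, so
# that two blocks constructed with the same `shared_prefix` literally alias
# one state-transition parameterization (the log-spaced diagonal of A and
# its discretization projection); everything else stays private.

new_store <- function() new.env(parent = emptyenv())

p_set <- function(P, name, value) assign(name, value, envir = P)
p_get <- function(P, name) get(name, envir = P)
p_has <- function(P, name) exists(name, envir = P, inherits = FALSE)

g_add <- function(G, name, value) {
  if (exists(name, envir = G, inherits = FALSE)) {
    assign(name, get(name, envir = G) + value, envir = G)
  } else {
    assign(name, value, envir = G)
  }
}

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

# Inverse softplus, used to seed the discretization-step bias so that the
# initial delta is log-uniform on [dt_min, dt_max] (Mamba convention).
inv_softplus <- function(y) y + log(-expm1(-y))

init_stream_shared <- function(P, spfx, dir, Ds, N, R,
                               dt_min = 1e-3, dt_max = 0.1) {
  key <- function(s) paste0(spfx, ".", dir, ".", s)
  if (p_has(P, key("A_log"))) return(invisible(NULL))  # already shared in
  p_set(P, key("A_log"), matrix(rep(log(seq_len(N)), each = Ds), Ds, N))
  p_set(P, key("dtW"), glorot(R, Ds))
  dt0 <- exp(stats::runif(Ds, log(dt_min), log(dt_max)))
  p_set(P, key("dtb"), inv_softplus(dt0))
  invisible(NULL)
}

init_stream_private <- function(P, pfx, dir, Ds, N, R, k) {
  key <- function(s) paste0(pfx, ".", dir, ".", s)
  p_set(P, key("convw"), matrix(stats::runif(Ds * k, -1, 1) / sqrt(k), Ds, k))
  p_set(P, key("convb"), numeric(Ds))
  p_set(P, key("xW"), glorot(Ds, R + 2L * N))
  p_set(P, key("Dskip"), rep(1, Ds))
  invisible(NULL)
}

init_static_stream <- function(P, spfx, pfx, dir, Ds, N) {
  skey <- function(s) paste0(spfx, ".", dir, ".", s)
  if (!p_has(P, skey("A_diag"))) {
    p_set(P, skey("A_diag"), stats::runif(N, 0.3, 0.95))
  }
  p_set(P, paste0(pfx, ".", dir, ".B"), glorot(N, Ds))
  p_set(P, paste0(pfx, ".", dir, ".C"), glorot(N, Ds))
}

#' Bi-Mamba block configuration
#'
#' @param model_width Channel width `D` of the stream (must be even: the
#'   two directional streams each process one channel half).
#' @param state_dim Hidden state dimension `N` per channel.
#' @param conv_kernel Temporal width of the depthwise convolution in each
#'   stream.
#' @param n_blocks Number of stacked blocks when used as a stage.
#' @param share_group Optional identifier; blocks carrying the same
#'   identifier inside one store share their state-transition
#'   parameterization.
#' @param static_ssm If `TRUE`, freeze the scan to constant
#'   \eqn{\bar{A}, \bar{B}, C} so the printed recursions apply literally
#'   (inference/testing mode; training always uses the selective
#'   parameterization).
#' @param dt_rank Rank of the discretization-step projection; default
#'   `max(1, model_width / 16)`.
#' @param bidirectional If `FALSE`, the second stream also runs causally
#'   (the plain unidirectional Mamba ablation, with a matched parameter
#'   count).
#' @return A `bimamba_config` list.
#' @export
bimamba_config <- function(model_width, state_dim = 16L, conv_kernel = 4L,
                           n_blocks = 2L, share_group = NULL,
                           static_ssm = FALSE, dt_rank = NULL,
                           bidirectional = TRUE) {
  stopifnot(model_width > 0L, state_dim > 0L, conv_kernel >= 1L)
  if (model_width %% 2L != 0L) stop("model_width must be even")
  if (is.null(dt_rank)) dt_rank <- max(1L, model_width %/% 16L)
  structure(list(model_width = as.integer(model_width),
                 state_dim = as.integer(state_dim),
                 conv_kernel = as.integer(conv_kernel),
                 n_blocks = as.integer(n_blocks),
                 share_group = share_group,
                 static_ssm = isTRUE(static_ssm),
                 dt_rank = as.integer(dt_rank),
                 bidirectional = isTRUE(bidirectional)),
            class = "bimamba_config")
}

#' Create a Bi-Mamba block
#'
#' @param cfg A [bimamba_config()].
#' @param seed Optional integer seed for parameter initialization.
#' @param store Parameter environment to create the block in (one is
#'   created when omitted). Blocks in the same store can share parameters.
#' @param prefix Name prefix for this block's private parameters.
#' @param shared_prefix Name prefix for the state-transition
#'   parameterization; defaults to `prefix` (no sharing).
#' @return A `bimamba_block` object.
#' @export
bimamba_init <- function(cfg, seed = NULL, store = NULL, prefix = "bm",
                         shared_prefix = NULL) {
  stopifnot(inherits(cfg, "bimamba_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(store)) store <- new_store()
  if (is.null(shared_prefix)) shared_prefix <- prefix
  D <- cfg$model_width; Ds <- D %/% 2L
  N <- cfg$state_dim; R <- cfg$dt_rank; k <- cfg$conv_kernel
  for (dir in c("fwd", "bwd")) {
    if (cfg$static_ssm) {
      init_static_stream(store, shared_prefix, prefix, dir, Ds, N)
      p_set(store, paste0(prefix, ".", dir, ".convw"),
            matrix(stats::runif(Ds * k, -1, 1) / sqrt(k), Ds, k))
      p_set(store, paste0(prefix, ".", dir, ".convb"), numeric(Ds))
    } else {
      init_stream_shared(store, shared_prefix, dir, Ds, N, R)
      init_stream_private(store, prefix, dir, Ds, N, R, k)
    }
  }
  p_set(store, paste0(prefix, ".out.W"), glorot(D, D))
  p_set(store, paste0(prefix, ".out.b"), numeric(D))
  p_set(store, paste0(prefix, ".ln.g"), rep(1, D))
  p_set(store, paste0(prefix, ".ln.b"), numeric(D))
  structure(list(cfg = cfg, store = store, prefix = prefix,
                 shared_prefix = shared_prefix),
            class = "bimamba_block")
}

#' Build two Bi-Mamba blocks with shared state-transition dynamics
#'
#' The returned blocks alias one state-transition parameterization (the
#' diagonal `A_log` and its discretization projection, per direction) while
#' keeping all other parameters independent. Mutating the shared matrices
#' through one block is observed by the other: this is the mechanism that
#' forces the two modality streams toward a common latent state space.
#'
#' @param cfg A [bimamba_config()].
#' @param seed Optional integer seed.
#' @param store Optional shared parameter environment.
#' @param prefixes Length-2 character vector of private prefixes.
#' @param shared_prefix Prefix of the shared parameterization.
#' @return List with elements `a` and `b`, both `bimamba_block`s.
#' @export
make_shared_pair <- function(cfg, seed = NULL, store = NULL,
                             prefixes = c("bmA", "bmB"),
                             shared_prefix = "bmShared") {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(store)) store <- new_store()
  a <- bimamba_init(cfg, store = store, prefix = prefixes[1L],
                    shared_prefix = shared_prefix)
  b <- bimamba_init(cfg, store = store, prefix = prefixes[2L],
                    shared_prefix = shared_prefix)
  list(a = a, b = b)
}

#' Number of parameters held by a block (shared ones counted once)
#' @param block A `bimamba_block`.
#' @return Named integer vector of parameter counts per tensor.
#' @export
bimamba_param_census <- function(block) {
  nms <- ls(block$store)
  own <- nms[startsWith(nms, paste0(block$prefix, ".")) |
             startsWith(nms, paste0(block$shared_prefix, "."))]
  vapply(own, function(n) length(p_get(block$store, n)), integer(1L))
}

# Forward pass of one block. Returns list(out, cache).
bimamba_f <- function(block, x, training = FALSE) {
  cfg <- block$cfg
  D <- cfg$model_width
  if (ncol(x) != D) {
    stop(sprintf("input width %d does not match model_width %d", ncol(x), D))
  }
  check_finite_seq(x)
  P <- block$store
  pf <- block$prefix; sf <- block$shared_prefix
  Ds <- D %/% 2L
  T_ <- nrow(x)
  xf <- x[, seq_len(Ds), drop = FALSE]
  xb <- x[, Ds + seq_len(Ds), drop = FALSE]
  rev_rows <- function(M) M[rev(seq_len(nrow(M))), , drop = FALSE]
  # in the unidirectional ablation the second stream also runs causally
  rev_if <- function(M) if (cfg$bidirectional) rev_rows(M) else M

  # forward stream: conv -> SiLU -> causal scan
  cf <- dwconv_f(xf, p_get(P, paste0(pf, ".fwd.convw")),
                 p_get(P, paste0(pf, ".fwd.convb")), "causal")
  af <- silu_f(cf$out)
  # backward stream: conv on the time-reversed sequence, flipped back,
  # SiLU, then the anticausal scan
  cb <- dwconv_f(rev_if(xb), p_get(P, paste0(pf, ".bwd.convw")),
                 p_get(P, paste0(pf, ".bwd.convb")), "causal")
  ab <- silu_f(rev_if(cb$out))

  if (cfg$static_ssm) {
    scan_static <- function(u, dir) {
      A <- diag(p_get(P, paste0(sf, ".", dir, ".A_diag")),
                nrow = cfg$state_dim)
      static_scan_cpp(u, A, p_get(P, paste0(pf, ".", dir, ".B")),
                      p_get(P, paste0(pf, ".", dir, ".C")),
                      reverse = (dir == "bwd" && cfg$bidirectional))
    }
    yf <- scan_static(af$out, "fwd")
    yb <- scan_static(ab$out, "bwd")
    sfw <- sbw <- NULL
  } else {
    stream_pp <- function(dir) {
      list(A_log = p_get(P, paste0(sf, ".", dir, ".A_log")),
           xW = p_get(P, paste0(pf, ".", dir, ".xW")),
           dtW = p_get(P, paste0(sf, ".", dir, ".dtW")),
           dtb = p_get(P, paste0(sf, ".", dir, ".dtb")),
           Dskip = p_get(P, paste0(pf, ".", dir, ".Dskip")))
    }
    sfw <- sel_stream_f(af$out, stream_pp("fwd"), block$cfg$dt_rank,
                        cfg$state_dim)
    yf <- sfw$out
    # anticausal scan == reverse, causal scan, reverse back
    sbw <- sel_stream_f(rev_if(ab$out), stream_pp("bwd"),
                        block$cfg$dt_rank, cfg$state_dim)
    yb <- rev_if(sbw$out)
  }

  z <- cbind(yf, yb)
  lo <- lin_f(z, p_get(P, paste0(pf, ".out.W")), p_get(P, paste0(pf, ".out.b")))
  ln <- ln_f(lo$out, p_get(P, paste0(pf, ".ln.g")), p_get(P, paste0(pf, ".ln.b")))
  list(out = ln$out,
       cache = list(cf = cf, af = af, cb = cb, ab = ab, sfw = sfw, sbw = sbw,
                    lo = lo, ln = ln, T_ = T_, Ds = Ds))
}

bimamba_b <- function(block, cache, dY, G) {
  cfg <- block$cfg
  if (cfg$static_ssm) stop("backward pass is not available in static-ssm mode")
  P <- block$store
  pf <- block$prefix; sf <- block$shared_prefix
  Ds <- cache$Ds
  rev_rows <- function(M) M[rev(seq_len(nrow(M))), , drop = FALSE]
  rev_if <- function(M) if (cfg$bidirectional) rev_rows(M) else M

  lb <- ln_b(dY, cache$ln, p_get(P, paste0(pf, ".ln.g")))
  g_add(G, paste0(pf, ".ln.g"), lb$dg); g_add(G, paste0(pf, ".ln.b"), lb$db)
  ob <- lin_b(lb$dX, cache$lo, p_get(P, paste0(pf, ".out.W")))
  g_add(G, paste0(pf, ".out.W"), ob$dW); g_add(G, paste0(pf, ".out.b"), ob$db)
  dyf <- ob$dX[, seq_len(Ds), drop = FALSE]
  dyb <- ob$dX[, Ds + seq_len(Ds), drop = FALSE]

  stream_pp <- function(dir) {
    list(A_log = p_get(P, paste0(sf, ".", dir, ".A_log")),
         xW = p_get(P, paste0(pf, ".", dir, ".xW")),
         dtW = p_get(P, paste0(sf, ".", dir, ".dtW")),
         dtb = p_get(P, paste0(sf, ".", dir, ".dtb")),
         Dskip = p_get(P, paste0(pf, ".", dir, ".Dskip")))
  }
  acc_stream <- function(dir, sb) {
    g_add(G, paste0(sf, ".", dir, ".A_log"), sb$dA_log)
    g_add(G, paste0(sf, ".", dir, ".dtW"), sb$ddtW)
    g_add(G, paste0(sf, ".", dir, ".dtb"), sb$ddtb)
    g_add(G, paste0(pf, ".", dir, ".xW"), sb$dxW)
    g_add(G, paste0(pf, ".", dir, ".Dskip"), sb$dDskip)
  }

  # forward stream
  sbf <- sel_stream_b(dyf, cache$sfw, stream_pp("fwd"))
  acc_stream("fwd", sbf)
  daf <- silu_b(sbf$du, cache$af)
  cbf <- dwconv_b(daf, cache$cf, p_get(P, paste0(pf, ".fwd.convw")))
  g_add(G, paste0(pf, ".fwd.convw"), cbf$dw)
  g_add(G, paste0(pf, ".fwd.convb"), cbf$db)

  # backward stream (mirror the forward-pass flips)
  sbb <- sel_stream_b(rev_if(dyb), cache$sbw, stream_pp("bwd"))
  acc_stream("bwd", sbb)
  dab <- silu_b(rev_if(sbb$du), cache$ab)
  cbb <- dwconv_b(rev_if(dab), cache$cb, p_get(P, paste0(pf, ".bwd.convw")))
  g_add(G, paste0(pf, ".bwd.convw"), cbb$dw)
  g_add(G, paste0(pf, ".bwd.convb"), cbb$db)

  cbind(cbf$dX, rev_if(cbb$dX))
}

#' Apply a Bi-Mamba block to a sequence
#'
#' @param block A block from [bimamba_init()] or [make_shared_pair()].
#' @param x Numeric `T x D` sequence, `D = model_width`.
#' @return The transformed `T x D` sequence.
#' @export
bimamba_forward <- function(block, x) {
  stopifnot(inherits(block, "bimamba_block"))
  bimamba_f(block, as.matrix(x))$out
}
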