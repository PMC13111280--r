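#' Constant-parameter state-space scan parameters
#'
#' Bundles the discretized state-space matrices of one directional scan:
#' the state-transition matrix `A_bar`, the per-channel input map `B_bar`
#' and the per-channel output map `C`. Each feature channel is an
#' independent single-input single-output system with `n_state` hidden
#' states; `A_bar` is shared across channels while `B_bar` and `C` may be
#' channel-specific.
#'
#' @param A_bar State-transition matrix: an `n_state x n_state` matrix or a
#'   length-`n_state` vector interpreted as a diagonal.
#' @param B_bar Input map: length-`n_state` vector (recycled over channels)
#'   or an `n_state x D` matrix.
#' @param C Output map, same shapes as `B_bar`.
#' @param direction `"forward"` (causal recursion from the first step) or
#'   `"backward"` (anticausal recursion from the last step).
#' @return An object of class `ssm_params`.
#' @examples
#' p <- ssm_params(A_bar = 0.5, B_bar = 1, C = 1)
#' ssm_scan(p, matrix(c(1, 0, 0), ncol = 1))
#' @export
ssm_params <- function(A_bar, B_bar, C, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (is.vector(A_bar)) A_bar <- diag(A_bar, nrow = length(A_bar))
  A_bar <- as.matrix(A_bar)
  n <- nrow(A_bar)
  if (ncol(A_bar) != n || n < 1L) stop("A_bar must be square with n_state >= 1")
  norm_map <- function(M, what) {
    if (is.vector(M)) M <- matrix(M, nrow = n, ncol = 1L)
    M <- as.matrix(M)
    if (nrow(M) != n) stop(sprintf("%s must have n_state = %d rows", what, n))
    M
  }
  structure(list(A_bar = A_bar, B_bar = norm_map(B_bar, "B_bar"),
                 C = norm_map(C, "C"), n_state = n, direction = direction),
            class = "ssm_params")
}

check_finite_seq <- function(x, what = "input") {
  bad <- which(!is.finite(x), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-finite %s at time step %d, channel %d",
                 what, bad[1L, 1L], bad[1L, 2L]))
  }
  invisible(TRUE)
}

#' Run a constant-parameter selective-state-space scan
#'
#' Applies the linear recurrence
#' \deqn{h_t = \bar{A} h_{t-1} + \bar{B} x_t, \qquad y_t = C h_t}
#' channel by channel over a `T x D` sequence, with `h_0 = 0`. For
#' `direction = "backward"` the mirrored anticausal recursion
#' \eqn{h_i = \bar{A}_b h_{i+1} + \bar{B}_b x_i} is used, so the scan
#' consumes the sequence from its last step towards the first.
#'
#' @param params An [ssm_params()] object.
#' @param x Numeric `T x D` matrix (or a vector, treated as `T x 1`).
#' @return A `T x D` matrix of outputs `y`.
#' @export
ssm_scan <- function(params, x) {
  stopifnot(inherits(params, "ssm_params"))
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  x <- as.matrix(x)
  check_finite_seq(x)
  D <- ncol(x)
  expand <- function(M) if (ncol(M) == D) M else matrix(M[, 1L], params$n_state, D)
  static_scan_cpp(x, params$A_bar, expand(params$B_bar), expand(params$C),
                  reverse = identical(params$direction, "backward"))
}

# ---- Selective (input-dependent) directional stream ------------------------
#
# One directional stream of a Bi-Mamba block: the hidden state follows a
# diagonal recurrence whose discretization step delta, input map B and
# output map C are all produced from the input by learned projections
# (zero-order-hold discretization of the diagonal state matrix
# A = -exp(A_log)). `pp` is a named list of stream parameters:
#   A_log (Ds x N), xW (Ds x (R + 2N)), dtW (R x Ds), dtb (Ds), Dskip (Ds).

sel_stream_f <- function(u, pp, R, N) {
  xp <- u %*% pp$xW
  dtr <- xp[, seq_len(R), drop = FALSE]
  Bm <- xp[, R + seq_len(N), drop = FALSE]
  Cm <- xp[, R + N + seq_len(N), drop = FALSE]
  dpre <- sweep(dtr %*% pp$dtW, 2L, pp$dtb, "+")
  delta <- softplus(dpre)
  A <- -exp(pp$A_log)
  sc <- sel_scan_fwd(u, delta, Bm, Cm, A, pp$Dskip)
  list(out = sc$y, u = u, delta = delta, Bm = Bm, Cm = Cm, A = A,
       dpre = dpre, dtr = dtr, h = sc$h, ab = sc$ab, R = R, N = N)
}

sel_stream_b <- function(dy, cache, pp) {
  g <- sel_scan_bwd(dy, cache$u, cache$delta, cache$Bm, cache$Cm, cache$A,
                    pp$Dskip, cache$h, cache$ab)
  dA_log <- g$dA * cache$A                     # dA/dA_log = -exp(A_log) = A
  dpre <- g$ddelta * sigmoid(cache$dpre)       # softplus'
  ddtW <- crossprod(cache$dtr, dpre)
  ddtb <- colSums(dpre)
  ddtr <- dpre %*% t(pp$dtW)
  dxp <- cbind(ddtr, g$dB, g$dC)
  dxW <- crossprod(cache$u, dxp)
  du <- g$du + dxp %*% t(pp$xW)
  list(du = du, dA_log = dA_log, dxW = dxW, ddtW = ddtW, ddtb = ddtb,
       dDskip = g$dDskip)
}
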