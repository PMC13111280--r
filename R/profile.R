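# Efficiency profiling: trainable-parameter census and analytic FLOP
# counts. Convention: FLOPs = 2 x multiply-accumulates, counted over the
# matrix multiplications, convolutions and scan recurrences (elementwise
# activations and normalizations are excluded); stated in every report.

flops_block <- function(T_, D, N, R, k) {
  T_ <- as.numeric(T_)
  Ds <- D %/% 2L
  per_dir <- T_ * Ds * k +            # depthwise conv
    T_ * Ds * (R + 2L * N) +          # x-projection (delta, B, C)
    T_ * R * Ds +                     # delta projection
    3 * T_ * Ds * N +                 # scan: decay, state update, input
    T_ * Ds * N +                     # output contraction with C
    T_ * Ds                           # skip connection
  2 * per_dir + T_ * D * D            # two streams + output projection
}

flops_asym <- function(cfg, f_audio, f_video, T_) {
  T_ <- as.numeric(T_)
  D <- cfg$d_model; N <- cfg$state_dim
  R <- cfg_dt_rank(cfg, D); k <- cfg$conv_kernel
  da <- cfg$d_attn; dl <- cfg$d_level; dh <- cfg$d_head
  Rh <- cfg_dt_rank(cfg, dh)
  mac <- 0
  both <- identical(cfg$modality, "both")
  n_streams <- if (both) 2L else 1L
  if (cfg$modality %in% c("both", "audio")) mac <- mac + T_ * f_audio * D
  if (cfg$modality %in% c("both", "video")) mac <- mac + T_ * f_video * D
  mac <- mac + n_streams * cfg$n_blocks * flops_block(T_, D, N, R, k)
  if (cfg$cma && both) {
    mac <- mac + 2 * (3 * T_ * D * da) +      # Q, K, V per modality
      2 * (2 * T_ * T_ * da) +                # scores + weighted values, 2 dirs
      2 * (T_ * da * D)                       # output projection, 2 dirs
  }
  use_fpn <- cfg$fusion %in% c("dual", "fpn_only") || !both
  use_gd <- cfg$fusion %in% c("dual", "gd_only") && both
  if (use_fpn) {
    lens <- as.numeric(fpn_level_lengths(T_))
    mac <- mac + n_streams * (lens[1L] * D * cfg$fpn_kernel +
                              lens[1L] * D * cfg$fpn_kernel +
                              lens[2L] * D * cfg$fpn_kernel)
    c_lvl <- n_streams * D
    mac <- mac + sum(lens) * c_lvl * dl + T_ * 3 * dl * D
  }
  if (use_gd) mac <- mac + 2 * D * D + 3 * T_ * D
  c_fuse <- if (!both) 2L * D else
    switch(cfg$fusion, dual = 2L * D, fpn_only = D, gd_only = D, concat = 2L * D)
  mac <- mac + T_ * c_fuse * dh
  if (cfg$enhance) {
    mac <- mac + 2 * T_ * dh * 3 +
      cfg$n_blocks * flops_block(T_, dh, N, Rh, k)
  }
  mac <- mac + dh
  2 * mac
}

#' Profile model size and computational cost
#'
#' Reports the trainable-parameter census (total and per submodule; shared
#' tensors counted once) and analytic FLOPs at the requested sequence
#' lengths. FLOP convention: 2 x multiply-accumulates over projections,
#' convolutions and scan recurrences.
#'
#' @param model An [asym_model()].
#' @param lengths Sequence lengths to profile (defaults to the published
#'   grid 0.5k-50k).
#' @return List with `params` (count), `params_M` (millions),
#'   `by_submodule`, `flops` (data frame with `length`, `flops_G`), and
#'   `convention`.
#' @export
profile_efficiency <- function(model,
                               lengths = c(500L, 1000L, 10000L, 20000L, 50000L)) {
  census <- asym_param_census(model)
  total <- asym_num_params(model)
  fl <- vapply(lengths, function(T_) {
    flops_asym(model$cfg, model$f_audio %||% 0L, model$f_video %||% 0L, T_)
  }, numeric(1L))
  list(params = total,
       params_M = total / 1e6,
       by_submodule = census,
       flops = data.frame(length = lengths, flops_G = fl / 1e9),
       convention = "FLOPs = 2 x MAC (projections, convolutions, scans)")
}
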