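# Layered run configuration: package defaults <- named profile <- config
# file (JSON) <- explicit overrides, in that order of precedence.

asym_default_config <- function() {
  list(
    profile = "synth",
    d_model = 32L,        # common channel width D after the 1x1 front-end
    state_dim = 8L,       # SSM hidden states per channel
    n_heads = 2L,
    d_attn = 16L,         # total attention width (d_k = d_attn / n_heads)
    n_blocks = 1L,        # Bi-Mamba blocks per stage
    conv_kernel = 4L,     # depthwise conv width inside Mamba streams
    dt_rank = NULL,       # discretization projection rank; NULL = D/16
    fpn_kernel = 3L,
    fpn_dilation = 1L,
    d_level = 8L,         # per-level fused channels in the pyramid
    d_head = 16L,         # width of the enhancement head
    dropout = 0.1,
    static_ssm = FALSE,
    merge = "residual",           # or "concat_project"
    upsample = "nearest",         # or "linear"
    gate_granularity = "channel", # or "timestep"
    fusion = "dual",              # dual | fpn_only | gd_only | concat
    modality = "both",            # both | audio | video
    cma = TRUE,
    enhance = TRUE,
    bidirectional = TRUE,
    pool = "mean",                # mean | max | last
    epochs = 20L,
    lr = 2e-3,
    weight_decay = 1e-4,
    batch_size = 16L,
    max_segments = 5L,
    min_seg_length = 500L,
    seed = 1L
  )
}

asym_profiles <- function() {
  list(
    synth = list(),
    dvlog = list(profile = "dvlog", d_model = 256L, state_dim = 16L,
                 n_heads = 2L, d_attn = 128L, n_blocks = 2L, d_level = 48L,
                 d_head = 128L, epochs = 16L, lr = 8e-5, weight_decay = 1e-3,
                 batch_size = 16L),
    lmvd = list(profile = "lmvd", d_model = 256L, state_dim = 12L,
                n_heads = 2L, d_attn = 128L, n_blocks = 2L, d_level = 48L,
                d_head = 128L, epochs = 12L, lr = 8e-5, weight_decay = 1e-3,
                batch_size = 16L)
  )
}

apply_over <- function(cfg, over, origin) {
  valid <- names(asym_default_config())
  bad <- setdiff(names(over), valid)
  if (length(bad) > 0L) {
    stop(sprintf("unknown config key(s) from %s: %s\nvalid keys: %s",
                 origin, paste(bad, collapse = ", "),
                 paste(valid, collapse = ", ")))
  }
  cfg[names(over)] <- over
  cfg
}

#' Build a resolved run configuration
#'
#' Precedence (lowest to highest): package defaults, the named profile,
#' the JSON config file, explicit overrides.
#'
#' @param path Optional path to a JSON configuration file.
#' @param profile One of `"synth"`, `"dvlog"`, `"lmvd"`.
#' @param overrides Named list of configuration values.
#' @return A named configuration list of class `asym_config`.
#' @examples
#' cfg <- load_config(profile = "dvlog")
#' cfg$state_dim   # 16
#' @export
load_config <- function(path = NULL, profile = "synth", overrides = list()) {
  profs <- asym_profiles()
  if (!profile %in% names(profs)) {
    stop(sprintf("unknown profile '%s' (valid: %s)", profile,
                 paste(names(profs), collapse = ", ")))
  }
  cfg <- asym_default_config()
  cfg$profile <- profile
  cfg <- apply_over(cfg, profs[[profile]], sprintf("profile '%s'", profile))
  if (!is.null(path)) {
    filecfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- apply_over(cfg, filecfg, path)
  }
  cfg <- apply_over(cfg, overrides, "overrides")
  int_keys <- c("d_model", "state_dim", "n_heads", "d_attn", "n_blocks",
                "conv_kernel", "fpn_kernel", "fpn_dilation", "d_level",
                "d_head", "epochs", "batch_size", "max_segments",
                "min_seg_length", "seed")
  for (k in int_keys) cfg[[k]] <- as.integer(cfg[[k]])
  if (!is.null(cfg$dt_rank)) cfg$dt_rank <- as.integer(cfg$dt_rank)
  structure(cfg, class = c("asym_config", "list"))
}

#' Save a resolved configuration to JSON
#' @param cfg An `asym_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
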