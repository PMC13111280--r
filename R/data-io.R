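# Dataset plumbing: the seeded synthetic multimodal generator, random
# segment augmentation, stratified splitting with round-half-up
# arithmetic, and a CSV manifest + per-sample delimited array layout for
# external corpora.

round_half_up <- function(x) floor(x + 0.5)

#' Specification of the synthetic multimodal generator
#'
#' The generator emulates two temporally aligned behavioral streams whose
#' cross-modal correlation is class-dependently lagged and whose
#' within-stream structure mixes transient events, periodic amplitude
#' modulation and slow drift (the three degradation scales of depressive
#' behavior: micro-expression transients, periodic abnormalities,
#' long-term attenuation).
#'
#' Per sample, a shared latent AR(1) signal drives both streams. For the
#' positive (depressed) class the video stream is the latent delayed by
#' `lag` steps (audio leads video), the video amplitude is modulated by a
#' decaying periodic envelope, the audio stream carries Poisson transient
#' spikes at an elevated rate, and both streams drift downwards. The
#' negative class has zero lag, a stationary envelope, baseline transient
#' rate and no drift. Observations are a rank-one linear mixing to the
#' channel counts plus Gaussian noise.
#'
#' @param n_per_class Samples per class.
#' @param t_range Length-2 integer range of sequence lengths.
#' @param f_audio,f_video Channel counts of the two streams.
#' @param lag Positive-class audio-leads-video offset in time steps.
#' @param transient_rate Length-2 vector `c(neg, pos)`: per-step Poisson
#'   spike probability in the audio stream.
#' @param mod_decay Length-2 `c(neg, pos)`: decay rate of the periodic
#'   video amplitude envelope over the sequence.
#' @param drift_slope Length-2 `c(neg, pos)`: end-of-sequence drift.
#' @param mod_depth Amplitude of the periodic envelope.
#' @param mod_period Period (steps) of the envelope.
#' @param ar_phi AR(1) coefficient of the shared latent.
#' @param noise Observation noise standard deviation.
#' @param seed Integer seed; the whole dataset is a pure function of the
#'   spec including this seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_class = 50L, t_range = c(500L, 800L),
                           f_audio = 24L, f_video = 48L, lag = 8L,
                           transient_rate = c(neg = 0.005, pos = 0.02),
                           mod_decay = c(neg = 0, pos = 2),
                           drift_slope = c(neg = 0, pos = -0.8),
                           mod_depth = 0.5, mod_period = 64L,
                           ar_phi = 0.95, noise = 0.6, seed = 1L) {
  stopifnot(lag < min(t_range), all(transient_rate >= 0), n_per_class >= 1L)
  structure(list(n_per_class = as.integer(n_per_class),
                 t_range = as.integer(t_range),
                 f_audio = as.integer(f_audio), f_video = as.integer(f_video),
                 lag = as.integer(lag), transient_rate = transient_rate,
                 mod_decay = mod_decay, drift_slope = drift_slope,
                 mod_depth = mod_depth, mod_period = as.integer(mod_period),
                 ar_phi = ar_phi, noise = noise, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic multimodal dataset
#'
#' @param spec A [synthetic_spec()].
#' @return List with `samples` (list of `list(sample_id, audio, video,
#'   label)`) and `manifest` (data frame of ids and labels). Fully
#'   reproducible from the spec.
#' @export
generate_synthetic <- function(spec = synthetic_spec()) {
  set.seed(spec$seed)
  # fixed mixing loadings per dataset, drawn once
  wa <- stats::rnorm(spec$f_audio); wa <- wa / sqrt(mean(wa^2))
  wv <- stats::rnorm(spec$f_video); wv <- wv / sqrt(mean(wv^2))
  n <- 2L * spec$n_per_class
  labels <- rep(c(0L, 1L), each = spec$n_per_class)
  samples <- vector("list", n)
  burn <- 100L
  for (i in seq_len(n)) {
    y <- labels[i]
    cls <- y + 1L       # 1 = negative, 2 = positive
    T_ <- sample_one(spec$t_range[1L]:spec$t_range[2L])
    lag_i <- if (y == 1L) spec$lag else 0L
    # shared latent AR(1), long enough for the maximal lag
    ztot <- burn + T_ + spec$lag
    e <- stats::rnorm(ztot)
    z <- stats::filter(e, spec$ar_phi, method = "recursive")
    z <- as.numeric(z)[(burn + 1L):ztot] * sqrt(1 - spec$ar_phi^2)
    s_a <- z[spec$lag + seq_len(T_)]
    s_v <- z[spec$lag - lag_i + seq_len(T_)]
    tt <- seq_len(T_) / T_
    drift <- spec$drift_slope[cls] * tt
    # audio: latent + transient spikes + drift
    spikes <- stats::rbinom(T_, 1L, spec$transient_rate[cls]) *
      3 * abs(stats::rnorm(T_)) * sample(c(-1, 1), T_, replace = TRUE)
    src_a <- s_a + spikes + drift
    # video: lagged latent with (possibly decaying) periodic envelope + drift
    env <- 1 + spec$mod_depth * cos(2 * pi * seq_len(T_) / spec$mod_period) *
      exp(-spec$mod_decay[cls] * tt)
    src_v <- env * s_v + drift
    audio <- outer(src_a, wa) +
      matrix(stats::rnorm(T_ * spec$f_audio, sd = spec$noise), T_, spec$f_audio)
    video <- outer(src_v, wv) +
      matrix(stats::rnorm(T_ * spec$f_video, sd = spec$noise), T_, spec$f_video)
    samples[[i]] <- list(sample_id = sprintf("synth_%04d", i),
                         audio = audio, video = video, label = y)
  }
  manifest <- data.frame(
    sample_id = vapply(samples, `[[`, character(1L), "sample_id"),
    label = labels, stringsAsFactors = FALSE)
  list(samples = samples, manifest = manifest, spec = spec)
}

#' Random-segment augmentation specification
#' @param max_segments Maximum sub-sequences per sample (default 5).
#' @param min_length Minimum fragment length in time steps (default 500).
#' @param mode `"atleast"` draws the fragment length uniformly from
#'   `[min_length, T]`; `"exact"` fixes it to `min_length`.
#' @param seed Integer seed.
#' @return An `augment_spec` list.
#' @export
augment_spec <- function(max_segments = 5L, min_length = 500L,
                         mode = c("atleast", "exact"), seed = 1L) {
  stopifnot(max_segments >= 1L, min_length >= 1L)
  structure(list(max_segments = as.integer(max_segments),
                 min_length = as.integer(min_length),
                 mode = match.arg(mode), seed = as.integer(seed)),
            class = "augment_spec")
}

#' Random-segment augmentation of an aligned audio/video pair
#'
#' Draws up to `max_segments` sub-sequences, each defined by a random
#' fragment length `f_length >= min_length` and a random start `t_start`
#' (0-based, half-open crop `[t_start, t_start + f_length)`). Audio and
#' video are cropped with the same boundaries so the pair stays aligned,
#' and every segment inherits the sample's label. The crop set is
#' deterministic given the spec's seed, with distinct
#' `(t_start, f_length)` pairs.
#'
#' @param sample List with `audio`, `video` matrices and `label` (the
#'   format produced by [generate_synthetic()]).
#' @param spec An [augment_spec()].
#' @return List of augmented sample lists (possibly empty, with a warning,
#'   when the sequence is shorter than `min_length`).
#' @export
augment_random_segments <- function(sample, spec = augment_spec()) {
  T_ <- min(nrow(sample$audio), nrow(sample$video))
  if (T_ < spec$min_length) {
    warning(sprintf("sample '%s': length %d < min segment length %d; no segments produced",
                    sample$sample_id %||% "?", T_, spec$min_length))
    return(list())
  }
  set.seed(spec$seed)
  # number of feasible distinct (t_start, f_length) crops
  n_feasible <- sum(T_ - seq(spec$min_length, T_) + 1)
  n_seg <- min(spec$max_segments, n_feasible)
  seen <- character(0)
  out <- vector("list", n_seg)
  k <- 0L
  guard <- 0L
  while (k < n_seg && guard < 1000L) {
    guard <- guard + 1L
    f_len <- if (spec$mode == "exact") spec$min_length else
      sample_one(spec$min_length:T_)
    t_start <- sample_one(0:(T_ - f_len))
    key <- paste(t_start, f_len)
    if (key %in% seen) next
    seen <- c(seen, key)
    k <- k + 1L
    rows <- (t_start + 1L):(t_start + f_len)
    out[[k]] <- list(
      sample_id = sprintf("%s_seg%d", sample$sample_id %||% "s", k),
      audio = sample$audio[rows, , drop = FALSE],
      video = sample$video[rows, , drop = FALSE],
      label = sample$label, t_start = t_start, f_length = f_len)
  }
  out[seq_len(k)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() treats a length-1 vector as 1:x; guard degenerate ranges
sample_one <- function(v) if (length(v) == 1L) v else sample(v, 1L)

#' Stratified split specification
#' @param ratios Length-3 numeric `(train, val, test)` ratios summing to 1.
#' @param seed Shuffling seed.
#' @return A `split_spec` list.
#' @export
split_spec <- function(ratios = c(train = 0.7, val = 0.1, test = 0.2),
                       seed = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios > 0), all(ratios < 1),
            abs(sum(ratios) - 1) < 1e-8)
  structure(list(ratios = ratios, seed = as.integer(seed)),
            class = "split_spec")
}

#' Stratified train/validation/test split
#'
#' Per class, `n_train = round(r_train * n)` and `n_test = round(r_test *
#' n)` with round-half-up, and validation takes the remainder — the
#' arithmetic that reproduces the published per-class count tables of the
#' D-Vlog (7:1:2) and LMVD (8:1:1) corpora exactly.
#'
#' @param class_sizes Named integer vector of per-class sample counts.
#' @param spec A [split_spec()].
#' @return List with `counts` (data frame: class, train, val, test) and
#'   `indices` (per class, a list of shuffled index vectors for the three
#'   partitions, indices local to the class).
#' @export
stratified_split <- function(class_sizes, spec = split_spec()) {
  stopifnot(all(class_sizes >= 1L))
  r <- spec$ratios
  set.seed(spec$seed)
  cls <- names(class_sizes) %||% as.character(seq_along(class_sizes))
  if (is.null(names(class_sizes))) names(class_sizes) <- cls
  counts <- data.frame(class = cls, train = NA_integer_, val = NA_integer_,
                       test = NA_integer_, stringsAsFactors = FALSE)
  indices <- list()
  for (i in seq_along(class_sizes)) {
    n <- class_sizes[[i]]
    n_tr <- as.integer(round_half_up(r[[1L]] * n))
    n_te <- as.integer(round_half_up(r[[3L]] * n))
    n_va <- n - n_tr - n_te
    if (min(n_tr, n_va, n_te) < 1L) {
      stop(sprintf("class '%s' (n = %d): a partition would be empty (%d/%d/%d)",
                   cls[i], n, n_tr, n_va, n_te))
    }
    counts$train[i] <- n_tr; counts$val[i] <- n_va; counts$test[i] <- n_te
    ord <- sample.int(n)
    indices[[cls[i]]] <- list(train = sort(ord[seq_len(n_tr)]),
                              val = sort(ord[n_tr + seq_len(n_va)]),
                              test = sort(ord[n_tr + n_va + seq_len(n_te)]))
  }
  totals <- data.frame(class = "all", train = sum(counts$train),
                       val = sum(counts$val), test = sum(counts$test),
                       stringsAsFactors = FALSE)
  list(counts = counts, totals = totals, indices = indices, spec = spec)
}

# ---- manifest + array files ------------------------------------------------

#' Write a dataset to a directory (CSV manifest + per-sample arrays)
#'
#' Arrays are stored as headerless comma-delimited text, one file per
#' modality per sample.
#'
#' @param dataset List with `samples` as produced by
#'   [generate_synthetic()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest file, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(dataset$samples, function(s) {
    ap <- file.path(dir, paste0(s$sample_id, "_audio.csv"))
    vp <- file.path(dir, paste0(s$sample_id, "_video.csv"))
    utils::write.table(s$audio, ap, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    utils::write.table(s$video, vp, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    data.frame(sample_id = s$sample_id, audio_path = basename(ap),
               video_path = basename(vp), label = s$label,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read and validate a dataset manifest
#'
#' @param path Path to a manifest CSV with columns `sample_id`,
#'   `audio_path`, `video_path`, `label` and optional `split`.
#' @return A validated data frame of class `asym_manifest` (paths resolved
#'   relative to the manifest's directory).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path))
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "audio_path", "video_path", "label")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0L) {
    stop(sprintf("manifest missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(m$sample_id)) {
    stop(sprintf("duplicate sample_id at row %d", anyDuplicated(m$sample_id)))
  }
  bad <- which(!m$label %in% c(0L, 1L))
  if (length(bad) > 0L) {
    stop(sprintf("non-binary label '%s' at manifest row %d", m$label[bad[1L]], bad[1L]))
  }
  base <- dirname(path)
  for (col in c("audio_path", "video_path")) {
    full <- ifelse(file.exists(m[[col]]), m[[col]], file.path(base, m[[col]]))
    missing_f <- which(!file.exists(full))
    if (length(missing_f) > 0L) {
      stop(sprintf("row %d: %s file not found: %s", missing_f[1L], col,
                   m[[col]][missing_f[1L]]))
    }
    m[[col]] <- full
  }
  class(m) <- c("asym_manifest", "data.frame")
  m
}

#' Load one sample's modality pair from a manifest row
#' @param row One-row slice of an [read_manifest()] data frame.
#' @return List with `sample_id`, `audio`, `video`, `label`.
#' @export
load_sample <- function(row) {
  read_arr <- function(p, what) {
    a <- as.matrix(utils::read.csv(p, header = FALSE))
    if (length(dim(a)) != 2L || !is.numeric(a)) {
      stop(sprintf("%s array '%s' is not a 2-D numeric matrix", what, p))
    }
    dimnames(a) <- NULL
    a
  }
  list(sample_id = row$sample_id,
       audio = read_arr(row$audio_path, "audio"),
       video = read_arr(row$video_path, "video"),
       label = as.integer(row$label))
}

#' Load all samples referenced by a manifest
#' @param manifest An [read_manifest()] data frame.
#' @return List of samples.
#' @export
load_dataset <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) load_sample(manifest[i, ]))
}
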