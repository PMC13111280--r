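# Evaluation protocol: the five classification metrics, stratified k-fold
# cross-validation, exact one-sided Wilcoxon signed-rank tests, calibration
# binning, attention-direction statistics, and the ablation harness.

#' Confusion counts
#' @param TP,FP,TN,FN Non-negative integer counts.
#' @return A `confusion_counts` list.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  v <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(as.list(v), class = "confusion_counts")
}

#' Confusion counts from predictions
#' @param pred,truth Binary 0/1 vectors of equal length.
#' @return A [confusion_counts()] object.
#' @export
confusion_from_pred <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  confusion_counts(TP = sum(pred == 1 & truth == 1),
                   FP = sum(pred == 1 & truth == 0),
                   TN = sum(pred == 0 & truth == 0),
                   FN = sum(pred == 0 & truth == 1))
}

#' The five classification metrics, as percentages
#'
#' Accuracy, precision, recall (sensitivity), specificity and F1 (the
#' harmonic mean of precision and recall), each in percent, plus their
#' unweighted arithmetic mean (`avg`). A metric whose denominator is zero
#' is reported as `NA` (undefined), never silently as 0.
#'
#' @param cc A [confusion_counts()] object.
#' @return A `metrics_report` list of percentages.
#' @export
compute_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  n <- cc$TP + cc$TN + cc$FP + cc$FN
  sdiv <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  acc <- sdiv(cc$TP + cc$TN, n)
  prec <- sdiv(cc$TP, cc$TP + cc$FP)
  rec <- sdiv(cc$TP, cc$TP + cc$FN)
  spec <- sdiv(cc$TN, cc$TN + cc$FP)
  f1 <- if (is.na(prec) || is.na(rec) || (prec + rec) == 0) NA_real_ else
    2 * prec * rec / (prec + rec)
  m <- list(accuracy = acc, precision = prec, recall = rec,
            specificity = spec, f1 = f1)
  m$avg <- mean(unlist(m))
  m$n <- n
  structure(m, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  precision %.2f%%  recall %.2f%%  specificity %.2f%%  F1 %.2f%%  avg %.2f%%  (n = %d)\n",
              x$accuracy, x$precision, x$recall, x$specificity, x$f1, x$avg, x$n))
  invisible(x)
}

#' F1 from precision and recall (percent scale)
#' @param precision,recall Percentages.
#' @return F1 percentage.
#' @export
f1_from_pr <- function(precision, recall) {
  2 * precision * recall / (precision + recall)
}

#' One-sided Wilcoxon signed-rank test (exact by enumeration)
#'
#' Tests whether paired scores `a` exceed `b` (alternative: `a` greater).
#' Zero differences are dropped; ties among absolute differences receive
#' average ranks. For `n <= 25` retained pairs the p-value is exact,
#' computed by full enumeration of the 2^n sign assignments of the
#' observed ranks (via a generating-function convolution); larger n uses
#' the normal approximation with continuity and tie corrections. All
#' differences zero yields p = 1 (no evidence).
#'
#' @param a,b Equal-length numeric vectors of paired scores.
#' @return List with `statistic` (W+, the positive-rank sum), `p_value`,
#'   `n` (retained pairs), `exact` flag.
#' @export
wilcoxon_onesided <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, n = 0L, exact = TRUE))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    # distribution of the positive-rank sum over all sign assignments;
    # ranks doubled so that average (half-integer) ranks stay integral
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1L)  # counts[w + 1] = #assignments with sum w
    counts[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(total + 1L - ri)])
      counts <- counts + shifted
    }
    W2 <- as.integer(round(2 * W))
    p <- sum(counts[(W2 + 1L):(total + 1L)]) / 2^n
    list(statistic = W, p_value = p, n = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - 0.5) / sqrt(sig2)
    list(statistic = W, p_value = stats::pnorm(z, lower.tail = FALSE),
         n = n, exact = FALSE)
  }
}

#' Calibration table over equal-width probability bins
#'
#' Partitions predicted probabilities into `n_bins` equal-width intervals
#' ([0, 0.1), ..., [0.9, 1.0], the last bin right-closed) and reports, per
#' bin, the count, the mean predicted probability and the observed
#' positive rate.
#'
#' @param probs Predicted probabilities in \[0, 1\].
#' @param labels Binary 0/1 outcomes.
#' @param n_bins Number of bins (default 10).
#' @return Data frame with columns `bin`, `lower`, `upper`, `count`,
#'   `mean_pred`, `pos_rate` (empty bins have count 0 and `NaN` rates).
#' @export
calibration_table <- function(probs, labels, n_bins = 10L) {
  stopifnot(length(probs) == length(labels),
            all(probs >= 0 & probs <= 1))
  edges <- seq(0, 1, length.out = n_bins + 1L)
  idx <- pmin(findInterval(probs, edges, rightmost.closed = TRUE), n_bins)
  out <- data.frame(bin = seq_len(n_bins),
                    lower = edges[-(n_bins + 1L)], upper = edges[-1L],
                    count = 0L, mean_pred = NaN, pos_rate = NaN)
  for (b in seq_len(n_bins)) {
    in_b <- idx == b
    out$count[b] <- sum(in_b)
    if (out$count[b] > 0L) {
      out$mean_pred[b] <- mean(probs[in_b])
      out$pos_rate[b] <- mean(labels[in_b])
    }
  }
  out
}

#' Stratified k-fold assignments
#' @param labels Binary label vector.
#' @param k Number of folds.
#' @param seed Shuffling seed.
#' @return Integer vector of fold ids (1..k), class-stratified.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  stopifnot(k >= 2L)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    ids <- which(labels == cl)
    ids <- sample(ids)
    fold[ids] <- rep_len(seq_len(k), length(ids))
  }
  if (any(table(fold, labels) == 0L)) stop("a class is absent from a fold")
  fold
}

#' k-fold cross-validated evaluation
#'
#' @param model_factory Function `(seed) -> asym_model` returning a fresh
#'   model.
#' @param samples Sample list (see [asym_train()]).
#' @param k Number of folds (default 5).
#' @param seed Fold-assignment and training seed.
#' @param train_args Named list passed to [asym_train()].
#' @return List with `per_fold` (data frame of the five metrics per fold)
#'   and `summary` (mean and sd per metric).
#' @export
kfold_evaluate <- function(model_factory, samples, k = 5L, seed = 1L,
                           train_args = list()) {
  labels <- vapply(samples, `[[`, numeric(1L), "label")
  fold <- stratified_folds(labels, k, seed)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- samples[fold != f]; te <- samples[fold == f]
    model <- model_factory(seed + f)
    model <- do.call(asym_train,
                     c(list(model = model, samples = tr, seed = seed + f),
                       train_args))
    pr <- asym_predict_many(model, te)
    m <- compute_metrics(confusion_from_pred(pr$label, labels[fold == f]))
    rows[[f]] <- data.frame(fold = f, accuracy = m$accuracy,
                            precision = m$precision, recall = m$recall,
                            specificity = m$specificity, f1 = m$f1)
  }
  per_fold <- do.call(rbind, rows)
  mets <- c("accuracy", "precision", "recall", "specificity", "f1")
  summary <- data.frame(
    metric = mets,
    mean = vapply(mets, function(m) mean(per_fold[[m]]), numeric(1L)),
    sd = vapply(mets, function(m) stats::sd(per_fold[[m]]), numeric(1L)))
  list(per_fold = per_fold, summary = summary, fold = fold)
}

# intensity of one head map: mean over queries of the maximum weight
map_intensity <- function(maps) {
  mean(vapply(maps, function(P) mean(apply(P, 1L, max)), numeric(1L)))
}

map_concentration <- function(maps) {
  mean(vapply(maps, function(P) {
    Tq <- nrow(P); Tk <- ncol(P)
    am <- apply(P, 1L, which.max)
    expected <- seq_len(Tq) * Tk / Tq
    mean(abs(am - expected)) / Tk
  }, numeric(1L)))
}

#' Directional statistics of cross-modal attention maps
#'
#' Summarizes, per sample and direction, the attention intensity (mean
#' over queries of the row-maximum weight, averaged over heads) and the
#' diagonal-concentration index (mean normalized distance between each
#' query's argmax key position and the diagonal), then compares the two
#' directions with a paired one-sided Wilcoxon signed-rank test
#' (audio-to-video greater).
#'
#' @param maps_av,maps_va Lists (one element per sample) of per-head
#'   attention maps, audio-to-video and video-to-audio.
#' @return List with `per_sample` data frame, `mean_av`, `mean_va`,
#'   `concentration_av`, `concentration_va`, `p_value` (one-sided),
#'   `p_two_sided`.
#' @export
attention_direction_stats <- function(maps_av, maps_va) {
  stopifnot(length(maps_av) == length(maps_va))
  i_av <- vapply(maps_av, map_intensity, numeric(1L))
  i_va <- vapply(maps_va, map_intensity, numeric(1L))
  c_av <- vapply(maps_av, map_concentration, numeric(1L))
  c_va <- vapply(maps_va, map_concentration, numeric(1L))
  wt <- wilcoxon_onesided(i_av, i_va)
  list(per_sample = data.frame(intensity_av = i_av, intensity_va = i_va,
                               concentration_av = c_av,
                               concentration_va = c_va),
       mean_av = mean(i_av), mean_va = mean(i_va),
       concentration_av = mean(c_av), concentration_va = mean(c_va),
       p_value = wt$p_value,
       p_two_sided = min(1, 2 * min(wt$p_value, 1 - wt$p_value)))
}

ablation_switch_cfg <- function(switches) {
  valid <- c("audio_only", "video_only", "no_cma", "uni_mamba", "no_fpn",
             "no_gd", "no_enhance")
  bad <- setdiff(switches, valid)
  if (length(bad) > 0L) stop(sprintf("unknown switch(es): %s", paste(bad, collapse = ", ")))
  if (all(c("audio_only", "video_only") %in% switches)) {
    stop("contradictory switches: audio_only and video_only")
  }
  ov <- list()
  if ("audio_only" %in% switches) ov$modality <- "audio"
  if ("video_only" %in% switches) ov$modality <- "video"
  if ("no_cma" %in% switches) ov$cma <- FALSE
  if ("uni_mamba" %in% switches) ov$bidirectional <- FALSE
  if (all(c("no_fpn", "no_gd") %in% switches)) {
    ov$fusion <- "concat"   # the plain-concatenation baseline row
  } else if ("no_fpn" %in% switches) {
    ov$fusion <- "gd_only"
  } else if ("no_gd" %in% switches) {
    ov$fusion <- "fpn_only"
  }
  if ("no_enhance" %in% switches) ov$enhance <- FALSE
  ov
}

#' Run an ablation study
#'
#' Trains and evaluates one model per switch combination on a fixed
#' train/test split, mirroring the modality and architecture ablation
#' tables (unimodal inputs, no cross-modal attention, unidirectional
#' Mamba, FPN/gated-fusion removal with a plain-concatenation baseline,
#' no enhancement head).
#'
#' @param train_samples,test_samples Sample lists.
#' @param variants Named list: variant label -> character vector of
#'   switches (empty vector = full model).
#' @param profile Configuration profile for all variants.
#' @param overrides Configuration overrides applied to every variant.
#' @param f_audio,f_video Input channel counts.
#' @param seed Training seed.
#' @param train_args Extra arguments for [asym_train()].
#' @return Data frame: one row of the five metrics per variant.
#' @export
run_ablation <- function(train_samples, test_samples,
                         variants = list(full = character(0),
                                         audio_only = "audio_only",
                                         video_only = "video_only"),
                         profile = "synth", overrides = list(),
                         f_audio, f_video, seed = 1L, train_args = list()) {
  truth <- vapply(test_samples, `[[`, numeric(1L), "label")
  rows <- vector("list", length(variants))
  for (i in seq_along(variants)) {
    sw <- variants[[i]]
    ov <- utils::modifyList(overrides, ablation_switch_cfg(sw))
    cfg <- load_config(profile = profile, overrides = ov)
    model <- asym_model(cfg, f_audio = f_audio, f_video = f_video, seed = seed)
    strip <- function(ss, m) lapply(ss, function(s) {
      if (m == "audio") s$video <- NULL
      if (m == "video") s$audio <- NULL
      s
    })
    tr <- strip(train_samples, cfg$modality)
    te <- strip(test_samples, cfg$modality)
    model <- do.call(asym_train, c(list(model = model, samples = tr,
                                        seed = seed), train_args))
    pr <- asym_predict_many(model, te)
    m <- compute_metrics(confusion_from_pred(pr$label, truth))
    rows[[i]] <- data.frame(variant = names(variants)[i],
                            switches = paste(sw, collapse = "+"),
                            accuracy = m$accuracy, precision = m$precision,
                            recall = m$recall, specificity = m$specificity,
                            f1 = m$f1, params = asym_num_params(model))
  }
  do.call(rbind, rows)
}
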