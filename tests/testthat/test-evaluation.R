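# Metrics, significance testing, calibration, attention statistics.

test_that("compute_metrics applies the printed formulas", {
  cc <- confusion_counts(TP = 10L, FP = 0L, TN = 20L, FN = 0L)
  m <- compute_metrics(cc)
  expect_equal(unlist(m[c("accuracy", "precision", "recall",
                          "specificity", "f1")], use.names = FALSE),
               rep(100, 5))
  cc <- confusion_counts(TP = 94L, FN = 17L, TN = 43L, FP = 38L)
  m <- compute_metrics(cc)
  expect_equal(m$accuracy, 100 * 137 / 192, tolerance = 1e-10)
  expect_equal(m$precision, 100 * 94 / 132, tolerance = 1e-10)
  expect_equal(m$recall, 100 * 94 / 111, tolerance = 1e-10)
  expect_equal(m$specificity, 100 * 43 / 81, tolerance = 1e-10)
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  expect_equal(m$avg, mean(unlist(m[1:5])))
})

test_that("undefined denominators report NA, not zero", {
  m <- compute_metrics(confusion_counts(TP = 0L, FP = 0L, TN = 5L, FN = 5L))
  expect_true(is.na(m$precision))   # no positive predictions
  expect_true(is.na(m$f1))
  expect_false(is.na(m$accuracy))
})

test_that("wilcoxon_onesided is exact on small samples", {
  expect_equal(wilcoxon_onesided(1:6, 1:6)$p_value, 1)   # all-zero differences
  r <- wilcoxon_onesided(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
  expect_true(r$exact)
  expect_equal(r$p_value, 1 / 32)
  # n = 5, four tied positives (average rank 3.5 each) and one negative of
  # rank 1: W+ = 14, and only sign patterns {all +, 1 either way} reach
  # W* >= 14, so p = 2/32 by hand enumeration
  r <- wilcoxon_onesided(c(5, 5, 5, 5, 0.5), c(1, 1, 1, 1, 1))
  expect_equal(r$p_value, 2 / 32)
})

test_that("wilcoxon_onesided matches the reference implementation", {
  set.seed(10)
  for (i in 1:10) {
    n <- sample(6:20, 1L)
    a <- rnorm(n); b <- rnorm(n)        # continuous: tie-free
    got <- wilcoxon_onesided(a, b)
    want <- stats::wilcox.test(a, b, paired = TRUE, alternative = "greater",
                               exact = TRUE)
    expect_equal(got$p_value, unname(want$p.value), tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation paths agree for n >= 20", {
  set.seed(11)
  for (n in c(20L, 23L, 25L)) {
    a <- rnorm(n, 0.3); b <- rnorm(n)
    got <- wilcoxon_onesided(a, b)
    expect_true(got$exact)
    d <- a - b; d <- d[d != 0]; m <- length(d)
    r <- rank(abs(d)); W <- sum(r[d > 0])
    z <- (W - m * (m + 1) / 4 - 0.5) / sqrt(m * (m + 1) * (2 * m + 1) / 24)
    expect_lt(abs(got$p_value - pnorm(z, lower.tail = FALSE)), 0.005)
  }
})

test_that("calibration bins partition [0, 1] without double counting", {
  probs <- c(0, 0.05, 0.1, 0.55, 0.55, 0.95, 1)
  labs <- c(0, 0, 0, 1, 0, 1, 1)
  tab <- calibration_table(probs, labs)
  expect_identical(sum(tab$count), length(probs))
  expect_equal(tab$lower, seq(0, 0.9, by = 0.1))
  expect_equal(tab$upper, seq(0.1, 1, by = 0.1))
  # all probs 0.55: single occupied bin [0.5, 0.6)
  tab <- calibration_table(rep(0.55, 9), rep(1, 9))
  expect_identical(which(tab$count > 0), 6L)
  expect_true(all(is.nan(tab$mean_pred[tab$count == 0])))
  # boundary 1.0 falls in the right-closed last bin
  tab <- calibration_table(1, 1)
  expect_identical(tab$count[10L], 1L)
})

test_that("stratified folds balance classes", {
  labels <- rep(c(0, 1), each = 50)
  fold <- stratified_folds(labels, k = 5L, seed = 2L)
  tab <- table(fold, labels)
  expect_true(all(tab == 10L))
  expect_identical(fold, stratified_folds(labels, k = 5L, seed = 2L))
})

test_that("kfold summary is the arithmetic mean of fold metrics", {
  set.seed(12)
  samples <- lapply(1:20, function(i) {
    y <- i %% 2
    list(audio = matrix(rnorm(15 * 3, mean = y), 15, 3),
         video = matrix(rnorm(15 * 5, mean = -y), 15, 5), label = y)
  })
  cv <- kfold_evaluate(function(s) tiny_model(seed = s), samples, k = 5L,
                       seed = 3L, train_args = list(epochs = 1L, lr = 5e-3))
  expect_identical(nrow(cv$per_fold), 5L)
  expect_equal(cv$summary$mean[cv$summary$metric == "accuracy"],
               mean(cv$per_fold$accuracy))
})

test_that("attention direction statistics behave on canonical maps", {
  ident <- diag(6)
  maps <- replicate(6, list(ident), simplify = FALSE)
  st <- attention_direction_stats(maps, maps)
  expect_equal(st$mean_av - st$mean_va, 0)
  expect_equal(st$p_value, 1)
  expect_equal(st$concentration_av, 0)   # each query attends its own index
})

test_that("attention ridge on lagged synthetic data sits off the diagonal", {
  sp <- synthetic_spec(n_per_class = 2L, t_range = c(400L, 400L), lag = 10L,
                       noise = 0.3, seed = 21L)
  ds <- generate_synthetic(sp)
  labs <- vapply(ds$samples, `[[`, integer(1L), "label")
  # delay-embedded, norm-equalized principal channels as queries/keys: the
  # attention ridge for video queries over audio keys sits `lag` steps off
  # the diagonal on positives and on the diagonal on negatives
  offs <- vapply(ds$samples, function(s) {
    pa <- prcomp(s$audio)$x[, 1L]
    pv <- prcomp(s$video)$x[, 1L]
    # principal components carry a sign ambiguity; align via peak ccf
    cc <- ccf(pv, pa, lag.max = 20L, plot = FALSE)
    pv <- pv * sign(cc$acf[which.max(abs(cc$acf))])
    nrm <- function(E) E / sqrt(rowSums(E^2))
    Ea <- nrm(stats::embed(pa, 16L)); Ev <- nrm(stats::embed(pv, 16L))
    r <- scaled_dot_attention(Ev * 8, Ea * 8, Ea, n_heads = 1L)
    am <- apply(r$map[[1L]], 1L, which.max)
    stats::median(seq_along(am) - am)
  }, numeric(1L))
  expect_true(all(abs(offs[labs == 1L] - 10) <= 2))
  expect_true(all(abs(offs[labs == 0L]) <= 2))
})

test_that("ablation switch mapping covers the published rows", {
  expect_identical(asym:::ablation_switch_cfg("audio_only")$modality, "audio")
  expect_identical(asym:::ablation_switch_cfg(c("no_fpn", "no_gd"))$fusion,
                   "concat")
  expect_identical(asym:::ablation_switch_cfg("no_fpn")$fusion, "gd_only")
  expect_identical(asym:::ablation_switch_cfg("uni_mamba")$bidirectional, FALSE)
  expect_error(asym:::ablation_switch_cfg(c("audio_only", "video_only")),
               "contradictory")
  expect_error(asym:::ablation_switch_cfg("bogus"), "unknown switch")
})

test_that("audio-only models carry no video-branch parameters", {
  m <- tiny_model(modality = "audio")
  expect_false(any(grepl("video|co\\.v\\.", ls(m$P))))
  p <- rand_pair()
  expect_true(is.finite(asym_predict(m, audio = p$audio)$logit))
})
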