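# Synthetic generator, augmentation, splitting, manifest I/O.

test_that("stratified split reproduces the published count tables", {
  # 961 vlogs, 555 depressed / 406 non-depressed, 7:1:2
  s <- stratified_split(c(dep = 555L, nondep = 406L),
                        split_spec(c(0.7, 0.1, 0.2)))
  expect_identical(unlist(s$counts[s$counts$class == "dep", 2:4],
                          use.names = FALSE), c(389L, 55L, 111L))
  expect_identical(unlist(s$counts[s$counts$class == "nondep", 2:4],
                          use.names = FALSE), c(284L, 41L, 81L))
  expect_identical(unlist(s$totals[, 2:4], use.names = FALSE),
                   c(673L, 96L, 192L))
  # 1823 vlogs, 908 / 915, 8:1:1
  s <- stratified_split(c(dep = 908L, nondep = 915L),
                        split_spec(c(0.8, 0.1, 0.1)))
  expect_identical(unlist(s$totals[, 2:4], use.names = FALSE),
                   c(1458L, 182L, 183L))
  # single class of 10 at 8:1:1
  s <- stratified_split(c(a = 10L), split_spec(c(0.8, 0.1, 0.1)))
  expect_identical(unlist(s$counts[1, 2:4], use.names = FALSE), c(8L, 1L, 1L))
  expect_error(stratified_split(c(a = 3L), split_spec(c(0.8, 0.1, 0.1))),
               "empty")
})

test_that("split partitions are disjoint and exhaustive per class", {
  s <- stratified_split(c(x = 57L, y = 23L), split_spec(c(0.7, 0.1, 0.2), seed = 4L))
  for (cl in c("x", "y")) {
    idx <- s$indices[[cl]]
    all_idx <- sort(c(idx$train, idx$val, idx$test))
    expect_identical(all_idx, seq_len(if (cl == "x") 57L else 23L))
    expect_length(intersect(idx$train, idx$test), 0L)
    expect_length(intersect(idx$train, idx$val), 0L)
  }
  # same seed, same assignment
  s2 <- stratified_split(c(x = 57L, y = 23L), split_spec(c(0.7, 0.1, 0.2), seed = 4L))
  expect_identical(s$indices, s2$indices)
})

test_that("random-segment augmentation crops jointly and inherits labels", {
  set.seed(2)
  smp <- list(sample_id = "s", audio = matrix(rnorm(2000 * 3), 2000, 3),
              video = matrix(rnorm(2000 * 4), 2000, 4), label = 1L)
  segs <- augment_random_segments(smp, augment_spec(seed = 5L))
  expect_length(segs, 5L)
  for (sg in segs) {
    expect_identical(sg$label, 1L)
    expect_true(sg$f_length >= 500L && sg$f_length <= 2000L)
    expect_identical(nrow(sg$audio), sg$f_length)
    expect_identical(nrow(sg$video), sg$f_length)
    rows <- (sg$t_start + 1L):(sg$t_start + sg$f_length)
    expect_identical(sg$audio, smp$audio[rows, ])
    expect_identical(sg$video, smp$video[rows, ])
  }
  # same seed -> identical boundaries; different seed -> different
  segs2 <- augment_random_segments(smp, augment_spec(seed = 5L))
  expect_identical(lapply(segs, `[`, c("t_start", "f_length")),
                   lapply(segs2, `[`, c("t_start", "f_length")))
  # T equal to the minimum: the single feasible crop, taken once
  smp5 <- list(sample_id = "t", audio = matrix(0, 500, 2),
               video = matrix(0, 500, 2), label = 0L)
  segs <- augment_random_segments(smp5, augment_spec(seed = 1L))
  expect_length(segs, 1L)
  expect_identical(segs[[1L]]$t_start, 0L)
  expect_identical(segs[[1L]]$f_length, 500L)
  # too short: none, with a warning
  smp4 <- list(sample_id = "u", audio = matrix(0, 400, 2),
               video = matrix(0, 400, 2), label = 0L)
  expect_warning(segs <- augment_random_segments(smp4), "no segments")
  expect_length(segs, 0L)
  # exact mode pins the fragment length
  segs <- augment_random_segments(smp, augment_spec(mode = "exact", seed = 2L))
  expect_true(all(vapply(segs, `[[`, integer(1L), "f_length") == 500L))
})

test_that("augment_training_pool retains originals and varies crops", {
  smp <- list(sample_id = "a", audio = matrix(0, 600, 2),
              video = matrix(0, 600, 2), label = 1L)
  pool <- augment_training_pool(list(smp, smp), augment_spec(min_length = 500L))
  expect_gte(length(pool), 2L)
  expect_identical(pool[[1L]]$sample_id, "a")
})

test_that("synthetic generator honors its contract", {
  sp <- synthetic_spec(n_per_class = 5L, t_range = c(60L, 80L), seed = 7L)
  ds <- generate_synthetic(sp)
  expect_length(ds$samples, 10L)
  labs <- vapply(ds$samples, `[[`, integer(1L), "label")
  expect_identical(sum(labs), 5L)
  for (s in ds$samples) {
    expect_identical(ncol(s$audio), 24L)
    expect_identical(ncol(s$video), 48L)
    expect_identical(nrow(s$audio), nrow(s$video))
    expect_true(nrow(s$audio) >= 60L && nrow(s$audio) <= 80L)
    expect_true(all(is.finite(s$audio)) && all(is.finite(s$video)))
  }
  # bitwise determinism
  ds2 <- generate_synthetic(sp)
  expect_identical(ds, ds2)
})

test_that("cross-correlation of principal channels recovers the class lag", {
  sp <- synthetic_spec(n_per_class = 6L, t_range = c(600L, 600L), lag = 8L,
                       seed = 3L)
  ds <- generate_synthetic(sp)
  est_lag <- function(s) {
    pa <- prcomp(s$audio, center = TRUE)$x[, 1L]
    pv <- prcomp(s$video, center = TRUE)$x[, 1L]
    cc <- ccf(pv, pa, lag.max = 20L, plot = FALSE)
    cc$lag[which.max(abs(cc$acf))]
  }
  lags <- vapply(ds$samples, est_lag, numeric(1L))
  labs <- vapply(ds$samples, `[[`, integer(1L), "label")
  # video trails audio by `lag` on positives (ccf convention: positive lag)
  expect_true(all(abs(abs(lags[labs == 1L]) - 8) <= 1))
  expect_true(all(abs(lags[labs == 0L]) <= 1))
})

test_that("manifest round-trips, validates and loads", {
  sp <- synthetic_spec(n_per_class = 3L, t_range = c(30L, 40L), seed = 2L)
  ds <- generate_synthetic(sp)
  dir <- tempfile("ds")
  mp <- write_dataset(ds, dir)
  m <- read_manifest(mp)
  expect_identical(nrow(m), 6L)
  expect_identical(m$sample_id, ds$manifest$sample_id)
  expect_identical(as.integer(m$label), ds$manifest$label)
  loaded <- load_dataset(m)
  expect_length(loaded, 2L * sp$n_per_class)
  expect_equal(loaded[[1L]]$audio, ds$samples[[1L]]$audio, tolerance = 1e-12)
  # non-binary label rejected with the row number
  m_bad <- utils::read.csv(mp)
  m_bad$label[2L] <- 2L
  bp <- file.path(dir, "bad.csv")
  utils::write.csv(m_bad, bp, row.names = FALSE)
  expect_error(read_manifest(bp), "row 2")
  # missing array file rejected with the row and file
  m_bad <- utils::read.csv(mp)
  m_bad$audio_path[3L] <- "nope.csv"
  utils::write.csv(m_bad, bp, row.names = FALSE)
  expect_error(read_manifest(bp), "row 3.*nope.csv")
  # duplicate ids rejected
  m_bad <- utils::read.csv(mp)
  m_bad$sample_id[2L] <- m_bad$sample_id[1L]
  utils::write.csv(m_bad, bp, row.names = FALSE)
  expect_error(read_manifest(bp), "duplicate")
})
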