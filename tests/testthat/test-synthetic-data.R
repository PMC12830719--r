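test_that("speech segment generation hits the configured speech-free fraction", {
  # fraction 1: nobody ever speaks
  cfg <- generator_config(n_triads = 2, duration_s = 600,
                          target_speech_free_fraction = 1)
  segs <- generate_speech_segments(cfg, triad_seed = 3)
  expect_true(all(vapply(segs, nrow, integer(1)) == 0))

  # determinism
  cfg <- tiny_config()
  s1 <- generate_speech_segments(cfg, triad_seed = 7)
  s2 <- generate_speech_segments(cfg, triad_seed = 7)
  expect_identical(s1, s2)

  # Monte-Carlo: mean per-participant speech-free fraction ~ 0.77
  cfg <- generator_config(n_triads = 1, duration_s = 900, seed = 1)
  fr <- unlist(lapply(1:200, function(i) {
    segs <- generate_speech_segments(cfg, triad_seed = 1000 + i)
    vapply(segs, function(s) {
      1 - sum(s$end_ms - s$start_ms) / (cfg$duration_s * 1000)
    }, numeric(1))
  }))
  expect_lt(abs(mean(fr) - 0.77), 0.02)
})

test_that("speech segments are valid intervals", {
  cfg <- tiny_config(duration_s = 300)
  for (i in 1:20) {
    segs <- generate_speech_segments(cfg, triad_seed = i)
    for (s in segs) {
      if (nrow(s) == 0) next
      expect_true(all(s$start_ms < s$end_ms))
      expect_true(all(s$start_ms >= 0))
      expect_true(all(s$end_ms <= cfg$duration_s * 1000))
      # sorted and non-overlapping within a participant
      expect_true(all(diff(s$start_ms) > 0))
      expect_true(all(utils::head(s$end_ms, -1) <= s$start_ms[-1] + 1e-9))
    }
  }
})

test_that("triad generation respects rate-zero limit and determinism", {
  cfg <- tiny_config()
  ce0 <- condition_effect(rates = c(au4 = 0, au6 = 0, au12 = 0),
                          coactivation = 0)
  cfg$condition_effect <- list("0" = ce0, "1" = ce0)
  tri <- generate_triad(cfg, "t", condition = 0, seed = 5)
  for (p in tri$participants) expect_lt(max(p$values), 0.1)

  cfg <- tiny_config()
  t1 <- generate_triad(cfg, "t", condition = 1, seed = 9)
  t2 <- generate_triad(cfg, "t", condition = 1, seed = 9)
  expect_identical(t1$participants[[2]]$values, t2$participants[[2]]$values)
  expect_error(generate_triad(cfg, "t", condition = 2, seed = 1),
               "condition")
})

test_that("generated AU values stay in [0,1] with a boolean mask", {
  ds <- generate_dataset(tiny_config(n_triads = 4, duration_s = 120))
  for (tr in ds) for (p in tr$participants) {
    expect_true(all(p$values >= 0 & p$values <= 1))
    expect_type(p$speech_mask, "logical")
    expect_length(p$speech_mask, nrow(p$values))
  }
})

test_that("marginals-matched conditions have indistinguishable pooled AU12 values", {
  cfg <- generator_config(n_triads = 100, duration_s = 120, seed = 4)
  ds <- generate_dataset(cfg)
  lab <- dataset_labels(ds)
  pool <- function(cond) {
    unlist(lapply(ds[lab == cond], function(tr)
      lapply(tr$participants, function(p) p$values[, "au12"])))
  }
  D <- ks_two_sample(pool(0), pool(1))$D
  expect_lt(D, 0.05)
})

test_that("dataset condition assignment is balanced with a faithful manifest", {
  # 10 s conversations occasionally have no speaking turn at all; that
  # warning is expected here, the point is the label balance
  ds <- suppressWarnings(
    generate_dataset(tiny_config(n_triads = 28, duration_s = 10)))
  expect_equal(unname(table(dataset_labels(ds))), c(14L, 14L),
               ignore_attr = TRUE)
  ds4 <- generate_dataset(tiny_config(n_triads = 4, duration_s = 10))
  expect_equal(sum(dataset_labels(ds4) == 0), 2)
  expect_error(generate_dataset(tiny_config(n_triads = 1)), "at least 2")

  # manifest round-trips through writer/reader unchanged
  dir <- withr::local_tempdir()
  write_dataset(ds4, dir)
  back <- read_dataset(dir)
  expect_equal(attr(back, "manifest")$condition,
               attr(ds4, "manifest")$condition)
  expect_equal(attr(back, "manifest")$triad_id,
               attr(ds4, "manifest")$triad_id)
  expect_equal(back[[2]]$participants[[1]]$values,
               ds4[[2]]$participants[[1]]$values, tolerance = 1e-12)
  expect_identical(back[[3]]$participants[[2]]$speech_mask,
                   ds4[[3]]$participants[[2]]$speech_mask)
})

test_that("rating tables satisfy the assignment constraints", {
  rt <- generate_rating_table(19, 28, 5, p_correct = 0.8, seed = 2)
  expect_equal(nrow(rt), 95)
  expect_true(all(table(rt$video_id) >= 3))
  expect_equal(unname(table(rt$rater_id)), rep(5L, 19), ignore_attr = TRUE)
  # no rater rates the same video twice
  expect_false(any(duplicated(rt[c("rater_id", "video_id")])))
  expect_true(all(rt$confidence %in% 1:6))
  expect_true(all(rt$decision_time >= 1 & rt$decision_time <= 100))

  all_right <- generate_rating_table(19, 28, 5, p_correct = 1, seed = 3)
  expect_true(all(all_right$correct))

  expect_error(generate_rating_table(3, 28, 5, 0.8, 1), "infeasible")
})

test_that("rating-table accuracy concentrates around p_correct", {
  acc <- vapply(1:50, function(i) {
    rt <- generate_rating_table(19, 28, 5, p_correct = 0.8211, seed = i)
    mean(rt$correct)
  }, numeric(1))
  # binomial 95% band for the mean of 50 x 95 Bernoulli draws
  se <- sqrt(0.8211 * (1 - 0.8211) / (50 * 95))
  expect_lt(abs(mean(acc) - 0.8211), 1.96 * se * 3)
})
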