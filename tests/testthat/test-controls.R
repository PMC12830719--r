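test_that("temporal permutation preserves the value multiset and the mask", {
  set.seed(2)
  vals <- matrix(runif(300), 100, 3)
  mask <- rep(c(TRUE, FALSE), 50)
  s <- new_au_series(vals, fps = 25, speech_mask = mask)
  s$values[mask, ] <- 0
  p <- permute_series(s, seed = 8)
  for (j in 1:3) {
    expect_equal(sort(p$values[, j]), sort(s$values[, j]))
    # masked frames left in place (still zero)
    expect_true(all(p$values[mask, j] == 0))
  }
  expect_false(identical(p$values, s$values))
  # determinism
  expect_identical(permute_series(s, seed = 8)$values, p$values)
  # fully masked series: nothing to shuffle
  s2 <- new_au_series(matrix(0, 50, 3), fps = 25,
                      speech_mask = rep(TRUE, 50))
  expect_identical(permute_series(s2, seed = 1)$values, s2$values)
})

test_that("speech binarization codes zeros for speech and ones for silence", {
  s <- new_au_series(matrix(runif(9), 3, 3), fps = 25,
                     speech_mask = c(TRUE, FALSE, TRUE))
  b <- binarize_speech(s)
  for (j in 1:3) expect_equal(unname(b$values[, j]), c(0, 1, 0))
  s$speech_mask <- rep(TRUE, 3)
  expect_true(all(binarize_speech(s)$values == 0))
  s$speech_mask <- rep(FALSE, 3)
  expect_true(all(binarize_speech(s)$values == 1))
})

test_that("static features match the hand-worked episode example", {
  x <- c(0, .8, .9, 0, .7, 0)
  s <- new_au_series(cbind(x, matrix(0.01, 6, 2)), fps = 25)
  f <- static_features(s, activation_threshold = 0.5)
  expect_equal(unname(f["au4_n_episodes"]), 2)
  expect_equal(unname(f["au4_max_dur"]), 2)
  expect_equal(unname(f["au4_min_dur"]), 1)
  expect_equal(unname(f["au4_mean_dur"]), 1.5)
  expect_equal(unname(f["au4_total_active"]), 3)
  expect_equal(unname(f["au4_max"]), 0.9)
  expect_equal(unname(f["au4_mean"]), 0.4)
  expect_equal(unname(f["au4_sd"]), sd(x))
  expect_equal(round(unname(f["au4_sd"]), 4), 0.4427)

  # no episodes: zero durations plus a flag
  expect_true(attr(f, "no_episodes")["au6"])
  expect_equal(unname(f["au6_n_episodes"]), 0)
  expect_equal(unname(f["au6_max_dur"]), 0)

  # everything above threshold: one episode covering the series
  s2 <- new_au_series(matrix(0.8, 10, 3), fps = 25)
  f2 <- static_features(s2)
  expect_equal(unname(f2["au12_n_episodes"]), 1)
  expect_equal(unname(f2["au12_max_dur"]), 10)
})

test_that("a leaking feature yields perfect baseline classification", {
  ids <- sprintf("t%02d", 1:12)
  labels <- rep(c(0, 1), 6)
  plan <- make_folds(ids, labels, k = 3, seed = 1)
  set.seed(4)
  feats <- data.frame(triad_id = ids, condition = labels,
                      leak = labels + rnorm(12, sd = 1e-4),
                      noise = rnorm(12))
  res <- baseline_classify(feats, plan, "logistic")
  expect_equal(res$metrics$accuracy, 1)
  rf <- baseline_classify(feats, plan, "random_forest", seed = 2)
  expect_equal(rf$metrics$accuracy, 1)
})

test_that("permuted labels put the static-feature baseline at chance", {
  accs <- vapply(1:10, function(i) {
    set.seed(i)
    ids <- sprintf("t%02d", 1:28)
    labels <- sample(rep(c(0, 1), 14))
    feats <- data.frame(triad_id = ids, condition = labels,
                        f1 = rnorm(28), f2 = rnorm(28), f3 = rnorm(28))
    plan <- make_folds(ids, labels, k = 5, seed = i)
    baseline_classify(feats, plan, "logistic")$metrics$accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.35)
  expect_lte(mean(accs), 0.65)
})

test_that("triad-level static feature tables have 24 features per triad", {
  ds <- generate_dataset(tiny_config(n_triads = 4, duration_s = 60))
  ft <- dataset_static_features(ds)
  expect_equal(nrow(ft), 4)
  expect_equal(ncol(ft), 26)  # id + condition + 24 features
  expect_true(all(ft$au12_mean_dur >= 0))
})

test_that("segment grid evaluates every requested cell within range", {
  ds <- generate_dataset(tiny_config(n_triads = 6, duration_s = 180))
  cfg <- classifier_config(side = 16, work_len = 32, max_epochs = 5,
                           patience = 3)
  grid <- segment_accuracy_grid(ds, lengths_min = c(1, 2),
                                positions = c("first", "last"),
                                config = cfg, seed = 1)
  expect_equal(nrow(grid), 4)
  expect_true(all(grid$accuracy_pct >= 0 & grid$accuracy_pct <= 100))
  # full-duration segments are position-invariant
  grid_full <- segment_accuracy_grid(ds, lengths_min = 3,
                                     positions = c("first", "middle",
                                                   "last"),
                                     config = cfg, seed = 1)
  expect_equal(length(unique(grid_full$accuracy_pct)), 1)
})
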