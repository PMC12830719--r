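test_that("rating accuracy reproduces the 78-of-95 overall figure", {
  rt <- generate_rating_table(19, 28, 5, p_correct = 1, seed = 1)
  # force exactly 17 errors to mirror a 78/95 study outcome
  flip <- seq_len(17)
  rt$predicted_topic[flip] <- 1L - rt$predicted_topic[flip]
  rt$correct <- rt$predicted_topic == rt$true_topic
  acc <- rating_accuracy(rt, "rating")
  expect_equal(acc$accuracy_pct, 82.11)
  expect_equal(acc$accuracy, 78 / 95)

  all_right <- generate_rating_table(19, 28, 5, p_correct = 1, seed = 2)
  expect_equal(rating_accuracy(all_right, "rating")$accuracy_pct, 100)
  expect_true(all(rating_accuracy(all_right, "video")$per_video == 1))
  expect_true(all(rating_accuracy(all_right, "rater")$per_rater == 1))
  expect_equal(rating_accuracy(all_right, "video")$n_all_correct, 28)
})

test_that("MCC matches the reference confusion and equals Pearson on indicators", {
  expect_equal(round(mcc(rbind(c(12, 2), c(3, 11))), 2), 0.64)
  expect_equal(mcc(rbind(c(10, 0), c(0, 15))), 1)
  expect_equal(mcc(rbind(c(5, 5), c(5, 5))), 0)

  set.seed(3)
  checked <- 0
  for (rep in 1:200) {
    m <- matrix(rpois(4, 4), 2, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    truth <- rep(c(0, 0, 1, 1), c(m[1, 1], m[1, 2], m[2, 1], m[2, 2]))
    pred <- rep(c(0, 1, 0, 1), c(m[1, 1], m[1, 2], m[2, 1], m[2, 2]))
    if (var(truth) == 0 || var(pred) == 0) next
    expect_equal(mcc(m), cor(truth, pred))
    checked <- checked + 1
  }
  expect_gt(checked, 100)
})

test_that("Fleiss' kappa matches hand computation and degenerate rules", {
  expect_equal(fleiss_kappa(rbind(c(3, 0), c(2, 1)))$kappa, -0.2)
  # unanimous raters on every item
  perfect <- rbind(c(4, 0), c(0, 4), c(4, 0))
  expect_equal(fleiss_kappa(perfect)$kappa, 1)
  # kappa <= 1 on random tables; 1 only under perfect agreement
  set.seed(9)
  for (rep in 1:20) {
    counts <- t(stats::rmultinom(6, size = 4, prob = c(0.5, 0.5)))
    k <- try(fleiss_kappa(counts), silent = TRUE)
    if (inherits(k, "try-error")) next
    expect_lte(k$kappa, 1)
    if (k$kappa == 1) expect_true(all(apply(counts, 1, max) == 4))
  }
  expect_error(fleiss_kappa(rbind(c(3, 0), c(2, 2))), "unequal")
  expect_error(fleiss_kappa(rbind(c(3, 0), c(3, 0))), "one category")
  expect_error(fleiss_kappa(rbind(c(2, 1))), "two items")
})

test_that("summary t-tests reproduce the printed group comparisons", {
  # decision timing: correct (n=78) vs incorrect (n=17) ratings
  timing <- pooled_t_from_summary(78, 17.53, 16.98, 17, 27.59, 21.02)
  expect_equal(timing$df, 93)
  expect_equal(timing$t, 2.119, tolerance = 5e-4)
  expect_equal(round(timing$d, 2), 0.57)
  expect_lt(timing$p, 0.05)

  # confidence: the printed -4.378 reflects rounded inputs; 1% tolerance
  conf <- pooled_t_from_summary(78, 4.77, 0.99, 17, 3.53, 1.33)
  expect_equal(conf$t, -4.378, tolerance = 0.01 * 4.378)
  expect_equal(round(conf$d, 2), -1.17)

  same <- pooled_t_from_summary(10, 5, 1, 10, 5, 1)
  expect_equal(same$t, 0)
  expect_equal(same$d, 0)
  expect_error(pooled_t_from_summary(5, 2, 0, 5, 2, 0), "zero variance")
})

test_that("summary t-test agrees with a raw-data t-test oracle", {
  set.seed(21)
  for (rep in 1:10) {
    x <- rnorm(30, 10, 3); y <- rnorm(12, 12, 3)
    ours <- pooled_t_from_summary(length(x), mean(x), sd(x),
                                  length(y), mean(y), sd(y))
    ref <- t.test(y, x, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Pearson correlation handles exact and hand-checked cases", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4))$r, 0.982, tolerance = 5e-4)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("2x2 chi-square matches the closed form", {
  expect_equal(chi_square_2x2(rbind(c(10, 10), c(10, 10)))$chisq, 0)
  ch <- chi_square_2x2(rbind(c(30, 10), c(10, 30)))
  expect_equal(ch$chisq, 20)
  expect_equal(ch$df, 1)
  set.seed(13)
  for (rep in 1:10) {
    m <- matrix(rpois(4, 8) + 1, 2, 2)
    expect_gte(chi_square_2x2(m)$chisq, 0)
    # Yates-corrected variant is never larger than the uncorrected one
    expect_lte(chi_square_2x2(m, correct = TRUE)$chisq,
               chi_square_2x2(m)$chisq + 1e-12)
  }
  expect_error(chi_square_2x2(rbind(c(0, 0), c(3, 4))), "zero marginal")
})

test_that("the full rater report runs end to end on a synthetic study", {
  rt <- generate_rating_table(19, 28, 5, p_correct = 0.82, seed = 6)
  rep <- rater_report(rt)
  expect_equal(rep$n_ratings, 95)
  expect_equal(sum(rep$confusion), 95)
  expect_true(all(vapply(rep$fleiss, function(k)
    k$raters_per_video %in% 3:5, logical(1))))
  # correct ratings are made with higher confidence and earlier
  expect_lt(rep$confidence_t$t, 0)
  expect_gt(rep$decision_time_t$t, 0)
  expect_lt(rep$conf_time_cor$r, 0)
})
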