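test_that("fold plans keep triads intact, test each exactly once, and are stratified", {
  ids <- sprintf("t%02d", 1:28)
  labels <- rep(c(0, 1), 14)
  plan <- make_folds(ids, labels, k = 5, seed = 3)
  tested <- unlist(lapply(plan, `[[`, "test"))
  expect_setequal(tested, ids)
  expect_equal(anyDuplicated(tested), 0)
  for (f in plan) {
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$val, f$test), 0)
    expect_length(intersect(f$train, f$val), 0)
    expect_true(length(f$test) %in% 5:6)
    # both classes present in training
    expect_length(unique(labels[match(f$train, ids)]), 2)
  }
  # determinism
  expect_identical(plan, make_folds(ids, labels, k = 5, seed = 3))
  expect_error(make_folds(ids[1:3], labels[1:3], k = 5), "folds")
  expect_error(make_folds(ids, rep(1, 28), k = 5), "both labels")
})

test_that("confusion metrics reproduce the reference machine result", {
  m <- compute_metrics(c(tp = 11, fp = 2, tn = 12, fn = 3))
  expect_equal(round(m$accuracy_pct, 2), 82.14)
  expect_equal(m$accuracy, 23 / 28)
  expect_equal(m$mcc, 126 / sqrt(38220))
  expect_equal(round(m$mcc, 2), 0.64)

  perfect <- compute_metrics(c(tp = 14, fp = 0, tn = 14, fn = 0),
                             probabilities = rep(c(0.9, 0.1), 14),
                             labels = rep(c(1, 0), 14))
  expect_equal(perfect$accuracy_pct, 100)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$auc, 1)

  expect_warning(one_class <- compute_metrics(c(tp = 10, fp = 10,
                                                tn = 0, fn = 0)),
                 "degenerate")
  expect_equal(one_class$mcc, 0)
})

test_that("MCC is symmetric under class swap and matches matrix input", {
  set.seed(7)
  for (rep in 1:20) {
    cm <- list(tp = sample(0:10, 1), fp = sample(0:10, 1),
               tn = sample(0:10, 1), fn = sample(0:10, 1))
    if (sum(unlist(cm)) == 0) next
    a <- suppressWarnings(mcc(tp = cm$tp, fp = cm$fp,
                              tn = cm$tn, fn = cm$fn))
    # swapping classes swaps tp<->tn and fp<->fn and keeps MCC
    b <- suppressWarnings(mcc(tp = cm$tn, fp = cm$fn,
                              tn = cm$tp, fn = cm$fp))
    expect_equal(a, b)
    m <- matrix(c(cm$tn, cm$fn, cm$fp, cm$tp), 2, 2)
    expect_equal(suppressWarnings(mcc(m)), a)
  }
})

test_that("rank AUC equals brute-force pair counting and survives monotone maps", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    p <- runif(n)
    auc <- faudyn:::auc_rank(p, labels)
    pos <- p[labels == 1]; neg <- p[labels == 0]
    brute <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(auc, brute)
    # strictly monotone transform leaves the AUC unchanged
    expect_equal(faudyn:::auc_rank(qlogis(p * 0.98 + 0.01), labels), auc)
  }
})

test_that("DeLong interval agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(5)
  labels <- rbinom(40, 1, 0.5)
  labels[1:2] <- c(0, 1)
  p <- plogis(labels + rnorm(40))
  ours <- faudyn:::auc_delong_ci(p, labels)
  ref <- suppressMessages(pROC::ci.auc(labels, p, method = "delong"))
  expect_equal(unname(ours["auc"]), as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(unname(ours["lo"]), max(0, as.numeric(ref[1])),
               tolerance = 1e-8)
  expect_equal(unname(ours["hi"]), min(1, as.numeric(ref[3])),
               tolerance = 1e-8)
})

test_that("fold-level confidence intervals use the 2.05 multiplier", {
  probs <- c(0.9, 0.8, 0.2, 0.1, 0.7, 0.6, 0.3, 0.4)
  labels <- c(1, 1, 0, 0, 1, 0, 0, 1)
  folds <- rep(1:2, each = 4)
  pred <- as.integer(probs >= 0.5)
  m <- compute_metrics(c(tp = sum(pred & labels),
                         fp = sum(pred & !labels),
                         tn = sum(!pred & !labels),
                         fn = sum(!pred & labels)),
                       probabilities = probs, labels = labels,
                       folds = folds)
  fold_acc <- tapply(pred == labels, folds, mean)
  half <- 2.05 * sd(fold_acc) / sqrt(2)
  expect_equal(m$accuracy_ci,
               pmin(1, pmax(0, m$accuracy + c(-1, 1) * half)))
})

test_that("the scratch CNN learns a separable image problem deterministically", {
  set.seed(99)
  make_img <- function(cls) {
    base <- matrix(rnorm(16 * 16, sd = 0.1), 16, 16)
    if (cls == 1) base[4:12, 4:12] <- base[4:12, 4:12] + 1
    img <- array(0, c(16, 16, 3))
    for (j in 1:3) img[, , j] <- pmin(1, pmax(-1, base))
    structure(img, class = "gaf_image", triad_id = "x", condition = cls)
  }
  y <- rep(c(0, 1), 20)
  imgs <- lapply(y, make_img)
  cfg <- classifier_config(max_epochs = 60, patience = 15, seed = 2)
  fit <- cnn_fit(imgs, y, imgs[1:8], y[1:8], cfg)
  p <- predict(fit, imgs)
  expect_gt(mean((p >= 0.5) == y), 0.9)
  # same seed, same everything
  fit2 <- cnn_fit(imgs, y, imgs[1:8], y[1:8], cfg)
  expect_identical(predict(fit2, imgs), p)
  # single-class training folds are refused
  expect_error(cnn_fit(imgs[y == 1], y[y == 1], imgs[1:2], y[1:2], cfg),
               "single class|single-class")
})
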