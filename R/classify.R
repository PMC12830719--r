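#' Plan leakage-free cross-group folds
#'
#' Whole triads are assigned to folds, stratified by condition label, so
#' no participant of a test triad is ever seen in training.  Each triad
#' appears in exactly one test set; within each fold the remaining triads
#' are split into train and validation sets honoring the requested
#' fractions up to integer rounding.
#'
#' @param triad_ids character vector of triad ids.
#' @param labels 0/1 labels, same length/order.
#' @param k number of folds (default 5).
#' @param fractions train/validation/test fractions (default
#'   `c(0.7, 0.1, 0.2)`); the test fraction is realized by the k-way
#'   split, the validation fraction is carved from the non-test triads.
#' @param seed integer seed.
#' @return An object of class `fold_plan`: list of k folds, each with
#'   `train`, `val`, `test` triad-id vectors.
#' @export
make_folds <- function(triad_ids, labels, k = 5,
                       fractions = c(0.7, 0.1, 0.2), seed = 1L) {
  n <- length(triad_ids)
  stopifnot(length(labels) == n, all(labels %in% c(0, 1)),
            length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  if (k > n) stop("more folds than triads")
  if (length(unique(labels)) < 2) stop("both labels must be present")
  set.seed(seed)
  # deal shuffled triads of each class round-robin into k test groups
  test_group <- integer(n)
  offset <- 0L
  for (lab in c(0, 1)) {
    ids <- sample(which(labels == lab))
    test_group[ids] <- ((seq_along(ids) - 1L + offset) %% k) + 1L
    offset <- offset + length(ids)
  }
  n_val <- max(1L, round(fractions[2] * n))
  folds <- lapply(seq_len(k), function(f) {
    test <- triad_ids[test_group == f]
    rest <- which(test_group != f)
    # stratified validation pick from the non-test triads
    val_idx <- integer(0)
    for (lab in c(0, 1)) {
      pool <- sample(rest[labels[rest] == lab])
      take <- max(1L, round(n_val * sum(labels[rest] == lab) /
                              length(rest)))
      val_idx <- c(val_idx, pool[seq_len(min(take, length(pool) - 1L))])
    }
    list(train = triad_ids[setdiff(rest, val_idx)],
         val = triad_ids[val_idx],
         test = test)
  })
  structure(folds, ids = triad_ids, labels = labels, k = k,
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("Cross-group fold plan: %d folds over %d triads\n",
              attr(x, "k"), length(attr(x, "ids"))))
  for (i in seq_along(x))
    cat(sprintf("  fold %d: train %d / val %d / test %d\n", i,
                length(x[[i]]$train), length(x[[i]]$val),
                length(x[[i]]$test)))
  invisible(x)
}

#' Matthews correlation coefficient of a 2x2 confusion
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`; when any
#' factor of the denominator is zero (a degenerate marginal, e.g. all
#' predictions in one class) the value is 0 by convention, with a
#' warning.
#'
#' @param tp,fp,tn,fn confusion counts; alternatively `tp` may be a 2x2
#'   matrix with true classes in rows (0 then 1) and predictions in
#'   columns.
#' @return MCC in \[-1, 1\].
#' @examples
#' mcc(tp = 11, fp = 2, tn = 12, fn = 3)  # 0.6445
#' @export
mcc <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (is.matrix(tp)) {
    m <- tp
    stopifnot(all(dim(m) == 2), all(m >= 0), sum(m) > 0)
    tn <- m[1, 1]; fp <- m[1, 2]; fn <- m[2, 1]; tp <- m[2, 2]
  }
  denom2 <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) {
    warning("degenerate confusion marginal; MCC set to 0 by convention")
    return(0)
  }
  (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom2)
}

# rank-statistic AUC (mid-ranks for ties)
auc_rank <- function(probabilities, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong (U-statistics) variance and normal CI for the AUC
auc_delong_ci <- function(probabilities, labels, level = 0.95) {
  x <- probabilities[labels == 1]  # positives
  y <- probabilities[labels == 0]
  m <- length(x); n <- length(y)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  auc <- mean(outer(x, y, psi))
  v10 <- vapply(x, function(xi) mean(psi(xi, y)), numeric(1))
  v01 <- vapply(y, function(yj) mean(psi(x, yj)), numeric(1))
  s <- if (m > 1) var(v10) / m else 0
  s <- s + if (n > 1) var(v01) / n else 0
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(s)
  c(auc = auc, lo = max(0, auc - half), hi = min(1, auc + half))
}

#' Pooled classification metrics with confidence intervals
#'
#' Accuracy and MCC from pooled confusion counts; AUC by the rank
#' statistic over triad probabilities with a DeLong (U-statistics)
#' confidence interval.  When per-fold assignments are given, accuracy
#' and MCC also get an interval `point +/- 2.05 * SE`, clipped to the
#' metric's range, where SE is the standard error of the per-fold metric
#' across folds (the interval width is a between-fold dispersion
#' summary, not a binomial CI).
#'
#' @param confusion named vector `c(tp, fp, tn, fn)` or 2x2 matrix (rows
#'   = true 0/1, cols = predicted 0/1).
#' @param probabilities,labels optional per-triad probabilities and true
#'   labels for the AUC.
#' @param folds optional integer fold id per triad (same order as
#'   `probabilities`).
#' @param se_multiplier multiplier on the between-fold SE (default 2.05).
#' @return List of class `faudyn_metrics`: `accuracy` (proportion),
#'   `accuracy_pct`, `mcc`, `auc`, plus `*_ci` entries where computable.
#' @examples
#' m <- compute_metrics(c(tp = 11, fp = 2, tn = 12, fn = 3))
#' round(m$accuracy_pct, 2)  # 82.14
#' @export
compute_metrics <- function(confusion, probabilities = NULL, labels = NULL,
                            folds = NULL, se_multiplier = 2.05) {
  if (is.matrix(confusion)) {
    cm <- confusion
    confusion <- c(tp = cm[2, 2], fp = cm[1, 2], tn = cm[1, 1],
                   fn = cm[2, 1])
  }
  tp <- confusion[["tp"]]; fp <- confusion[["fp"]]
  tn <- confusion[["tn"]]; fn <- confusion[["fn"]]
  n <- tp + fp + tn + fn
  if (n == 0) stop("empty confusion")
  out <- list(confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
              n = n,
              accuracy = (tp + tn) / n,
              accuracy_pct = 100 * (tp + tn) / n,
              mcc = mcc(tp = tp, fp = fp, tn = tn, fn = fn))
  if (!is.null(probabilities) && !is.null(labels) &&
      length(unique(labels)) == 2) {
    out$auc <- auc_rank(probabilities, labels)
    ci <- auc_delong_ci(probabilities, labels)
    out$auc_ci <- unname(ci[c("lo", "hi")])
  }
  if (!is.null(folds) && length(unique(folds)) > 1 &&
      !is.null(probabilities) && !is.null(labels)) {
    pred <- as.integer(probabilities >= 0.5)
    fold_acc <- tapply(pred == labels, folds, mean)
    fold_mcc <- vapply(split(seq_along(labels), folds), function(i) {
      suppressWarnings(mcc(tp = sum(pred[i] == 1 & labels[i] == 1),
                           fp = sum(pred[i] == 1 & labels[i] == 0),
                           tn = sum(pred[i] == 0 & labels[i] == 0),
                           fn = sum(pred[i] == 0 & labels[i] == 1)))
    }, numeric(1))
    k <- length(fold_acc)
    out$accuracy_ci <- pmin(1, pmax(0, out$accuracy +
      c(-1, 1) * se_multiplier * sd(fold_acc) / sqrt(k)))
    out$mcc_ci <- pmin(1, pmax(-1, out$mcc +
      c(-1, 1) * se_multiplier * sd(fold_mcc) / sqrt(k)))
  }
  structure(out, class = "faudyn_metrics")
}

#' @export
print.faudyn_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%% (n = %d)", x$accuracy_pct, x$n))
  if (!is.null(x$accuracy_ci))
    cat(sprintf(" [%.2f%%, %.2f%%]", 100 * x$accuracy_ci[1],
                100 * x$accuracy_ci[2]))
  cat(sprintf("\nMCC %.2f", x$mcc))
  if (!is.null(x$mcc_ci))
    cat(sprintf(" [%.2f, %.2f]", x$mcc_ci[1], x$mcc_ci[2]))
  if (!is.null(x$auc))
    cat(sprintf("\nAUC %.2f [%.2f, %.2f]", x$auc, x$auc_ci[1],
                x$auc_ci[2]))
  cat("\n")
  invisible(x)
}

#' Train and evaluate the CNN across cross-group folds
#'
#' For each fold, trains the classifier on the training triads'
#' participant images with early stopping on the validation triads, then
#' predicts the held-out test participants.  A triad's probability is
#' the mean of its participants' probabilities (or a majority vote,
#' per `config$aggregate`); predicted label is probability >= 0.5
#' (ties to the positive class).  Metrics are pooled over all folds'
#' test predictions.
#'
#' @param images list of `gaf_image` keyed by participant id (each
#'   carrying `triad_id` and `condition` attributes), as produced by
#'   [encode_dataset()].
#' @param labels named 0/1 vector per triad.
#' @param plan a [make_folds()] plan over the same triads.
#' @param config a [classifier_config()].
#' @return An object of class `faudyn_cv` (see [decode_topics()]).
#' @export
train_and_evaluate <- function(images, labels, plan, config) {
  stopifnot(inherits(plan, "fold_plan"),
            inherits(config, "classifier_config"))
  img_triad <- vapply(images, function(im) attr(im, "triad_id"),
                      character(1))
  rows <- list()
  for (f in seq_along(plan)) {
    fold <- plan[[f]]
    pick <- function(ids) images[img_triad %in% ids]
    lab_of <- function(imgs) labels[vapply(imgs, attr, character(1),
                                           "triad_id")]
    tr_imgs <- pick(fold$train); va_imgs <- pick(fold$val)
    if (length(unique(lab_of(tr_imgs))) < 2)
      stop("fold ", f, " has single-class training labels")
    cfg <- config
    cfg$seed <- sub_seed(config$seed, f, salt = 3L)
    fit <- cnn_fit(tr_imgs, lab_of(tr_imgs), va_imgs, lab_of(va_imgs), cfg)
    te_imgs <- pick(fold$test)
    p <- predict(fit, te_imgs)
    for (tid in fold$test) {
      pp <- p[img_triad[names(p)] == tid]
      prob <- if (config$aggregate == "mean") mean(pp) else
        mean(pp >= 0.5)
      rows[[tid]] <- data.frame(triad_id = tid,
                                condition = unname(labels[tid]),
                                prob = unname(prob),
                                pred = as.integer(prob >= 0.5),
                                fold = f)
    }
  }
  res <- do.call(rbind, rows[attr(plan, "ids")])
  metrics <- compute_metrics(
    c(tp = sum(res$pred == 1 & res$condition == 1),
      fp = sum(res$pred == 1 & res$condition == 0),
      tn = sum(res$pred == 0 & res$condition == 0),
      fn = sum(res$pred == 0 & res$condition == 1)),
    probabilities = res$prob, labels = res$condition, folds = res$fold)
  structure(list(triads = res, metrics = metrics, plan = plan,
                 config = config),
            class = "faudyn_cv")
}

#' @export
print.faudyn_cv <- function(x, ...) {
  cat(sprintf("Cross-group CNN classification: %d triads, %d folds (%s backbone)\n",
              nrow(x$triads), attr(x$plan, "k"), x$config$backbone))
  print(x$metrics)
  invisible(x)
}

#' @export
summary.faudyn_cv <- function(object, ...) {
  print(object)
  cat("\nPer-fold test accuracy:\n")
  print(round(tapply(object$triads$pred == object$triads$condition,
                     object$triads$fold, mean), 3))
  invisible(object)
}

#' Decode conversation topic from AU dynamics
#'
#' The package's top-level fit: masks speech, encodes every participant
#' as a 3-channel GADF image, and runs leakage-free cross-group CNN
#' classification of the triad's conversation condition.
#'
#' @param dataset an `au_dataset`.
#' @param config a [classifier_config()].
#' @param input `"au"` (masked AU dynamics, the main analysis),
#'   `"au_unmasked"` (no speech masking), `"speech_binary"` (control:
#'   channels replaced by the speech-presence indicator) or `"permuted"`
#'   (control: speech-free AU values shuffled in time).
#' @param segment optional `list(length_min =, position =)` applied to
#'   every series before encoding (see [extract_segment()]).
#' @param k folds (default 5).
#' @param seed seed for the fold plan, training and any control
#'   permutation.
#' @return An object of class `faudyn_cv`: `triads` (per-triad
#'   probability, prediction, fold), `metrics` (accuracy/MCC/AUC with
#'   CIs), `plan`, `config`.
#' @examples
#' \donttest{
#' ds <- generate_dataset(generator_config(n_triads = 6, duration_s = 120))
#' cv <- decode_topics(ds, classifier_config(max_epochs = 20), seed = 1)
#' cv$metrics$accuracy
#' }
#' @export
decode_topics <- function(dataset, config = classifier_config(),
                          input = c("au", "au_unmasked", "speech_binary",
                                    "permuted"),
                          segment = NULL, k = 5, seed = 1L) {
  input <- match.arg(input)
  stopifnot(inherits(dataset, "au_dataset"))
  labels <- dataset_labels(dataset)
  transform <- switch(input,
    au = NULL,
    au_unmasked = NULL,
    speech_binary = binarize_speech,
    permuted = local({
      cnt <- 0L
      function(s) {
        cnt <<- cnt + 1L
        permute_series(s, seed = sub_seed(seed, cnt, salt = 11L))
      }
    }))
  if (!is.null(segment)) {
    pre <- transform
    transform <- function(s) {
      s <- extract_segment(s, segment$length_min, segment$position)
      if (is.null(pre)) s else pre(s)
    }
  }
  images <- encode_dataset(dataset, side = config$side,
                           work_len = config$work_len,
                           mask = input != "au_unmasked",
                           transform = transform)
  plan <- make_folds(names(labels), unname(labels), k = k,
                     seed = sub_seed(seed, 1L, salt = 7L))
  cfg <- config
  cfg$seed <- seed
  train_and_evaluate(images, labels, plan, cfg)
}
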