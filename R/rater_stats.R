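#' Accuracy of human ratings at rating, video, or rater level
#'
#' Rating level: overall proportion of correct ratings.  Video level:
#' per-video proportion correct (plus the count of videos all of whose
#' raters were correct; a majority-vote variant is available).  Rater
#' level: per-rater proportion correct.
#'
#' @param records a `rating_table` data frame.
#' @param level `"rating"`, `"video"` or `"rater"`.
#' @param majority_vote at video level, also report the accuracy of the
#'   per-video majority prediction.
#' @return For `"rating"`: list with `accuracy` (proportion) and
#'   `accuracy_pct` (2 dp).  For `"video"`/`"rater"`: list with the
#'   per-unit proportions and summaries.
#' @examples
#' rt <- generate_rating_table(19, 28, 5, p_correct = 0.9, seed = 1)
#' rating_accuracy(rt, "rating")$accuracy_pct
#' @export
rating_accuracy <- function(records, level = c("rating", "video", "rater"),
                            majority_vote = FALSE) {
  level <- match.arg(level)
  stopifnot(nrow(records) > 0)
  correct <- records$true_topic == records$predicted_topic
  if (level == "rating") {
    return(list(accuracy = mean(correct),
                accuracy_pct = round(100 * mean(correct), 2)))
  }
  if (level == "video") {
    per <- tapply(correct, records$video_id, mean)
    out <- list(per_video = per,
                n_all_correct = sum(per == 1),
                mean_accuracy_pct = round(100 * mean(per), 2))
    if (majority_vote) {
      maj <- tapply(seq_len(nrow(records)), records$video_id, function(i) {
        p <- mean(records$predicted_topic[i])
        as.integer(p >= 0.5) == records$true_topic[i][1]
      })
      out$majority_accuracy_pct <- round(100 * mean(maj), 2)
    }
    return(out)
  }
  per <- tapply(correct, records$rater_id, mean)
  list(per_rater = per,
       n_perfect = sum(per == 1),
       mean_accuracy_pct = round(100 * mean(per), 2))
}

#' 2x2 confusion table of a rating study
#'
#' Rows: true topic (0 then 1); columns: predicted topic (0 then 1).
#'
#' @param records a `rating_table`.
#' @return Integer 2x2 matrix.
#' @export
rating_confusion <- function(records) {
  m <- table(factor(records$true_topic, levels = c(0, 1)),
             factor(records$predicted_topic, levels = c(0, 1)))
  matrix(as.integer(m), 2, 2,
         dimnames = list(true = c("0", "1"), predicted = c("0", "1")))
}

#' Fleiss' kappa for a fixed number of raters per item
#'
#' Chance-corrected agreement `kappa = (Pbar - Pe) / (1 - Pe)` for
#' `n` raters classifying each item into one of several categories; the
#' caller stratifies by raters-per-item when that number varies (as with
#' videos rated by three vs four raters).  Significance is the standard
#' large-sample z approximation.
#'
#' @param counts items x categories matrix of rating counts; every row
#'   must sum to the same number of raters.
#' @return List with `kappa`, `z`, `p`, `n_raters`, `n_items`.
#' @examples
#' fleiss_kappa(rbind(c(3, 0), c(2, 1)))$kappa  # -0.2
#' @export
fleiss_kappa <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("at least two items required")
  n_r <- unique(rowSums(counts))
  if (length(n_r) != 1)
    stop("unequal raters per item; stratify before calling")
  if (n_r < 2) stop("at least two raters per item required")
  N <- nrow(counts)
  p_j <- colSums(counts) / (N * n_r)
  P_i <- (rowSums(counts^2) - n_r) / (n_r * (n_r - 1))
  Pbar <- mean(P_i)
  Pe <- sum(p_j^2)
  if (1 - Pe < .Machine$double.eps)
    stop("degenerate: all ratings in one category (Pe = 1)")
  kappa <- (Pbar - Pe) / (1 - Pe)
  # large-sample variance (Fleiss 1971)
  var_k <- 2 * (Pe - (2 * n_r - 3) * Pe^2 +
                  2 * (n_r - 2) * sum(p_j^3)) /
    (N * n_r * (n_r - 1) * (1 - Pe)^2)
  z <- kappa / sqrt(var_k)
  list(kappa = kappa, z = z, p = 2 * pnorm(-abs(z)),
       n_raters = n_r, n_items = N)
}

#' Pooled-variance t-test from printed group summaries
#'
#' Student (pooled, not Welch) two-sample t from group means, SDs and
#' sizes: `df = n1 + n2 - 2`.  Cohen's d is `(mean2 - mean1) /
#' s_pooled`, its sign following the same group ordering as t.
#'
#' @param n1,m1,sd1 first group size, mean, SD.
#' @param n2,m2,sd2 second group.
#' @return List with `t`, `df`, `p` (two-sided), `d`.
#' @examples
#' # decision timing, correct vs incorrect ratings
#' r <- pooled_t_from_summary(78, 17.53, 16.98, 17, 27.59, 21.02)
#' round(c(r$t, r$d), 2)  # 2.12 0.57
#' @export
pooled_t_from_summary <- function(n1, m1, sd1, n2, m2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (m1 == m2) stop("zero variance in both groups with equal means")
    return(list(t = Inf * sign(m2 - m1), df = n1 + n2 - 2, p = 0,
                d = Inf * sign(m2 - m1)))
  }
  sp <- sqrt(sp2)
  tval <- (m2 - m1) / (sp * sqrt(1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df),
       d = (m2 - m1) / sp)
}

#' Pearson correlation with two-sided t-based p-value
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with `r` and `p`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Pearson chi-square test of a 2x2 table
#'
#' @param table 2x2 non-negative counts.
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return List with `chisq`, `df`, `p`.
#' @examples
#' chi_square_2x2(rbind(c(30, 10), c(10, 30)))$chisq  # 20
#' @export
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal")
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Full report of a human-rating study
#'
#' Computes the statistics of the rater analysis from a rating table:
#' accuracies at the three levels, confusion and MCC, a chi-square test
#' of accuracy by topic, Fleiss' kappa stratified by raters-per-video,
#' t-tests of confidence and decision time for correct vs incorrect
#' ratings, and the confidence–decision-time correlation.
#'
#' @param records a `rating_table`.
#' @return List of class `rater_report`.
#' @export
rater_report <- function(records) {
  correct <- records$true_topic == records$predicted_topic
  conf <- rating_confusion(records)
  by_topic <- rbind(c(sum(correct[records$true_topic == 0]),
                      sum(!correct[records$true_topic == 0])),
                    c(sum(correct[records$true_topic == 1]),
                      sum(!correct[records$true_topic == 1])))
  raters_per_video <- table(records$video_id)
  kappa <- lapply(sort(unique(as.integer(raters_per_video))), function(nr) {
    vids <- names(raters_per_video)[raters_per_video == nr]
    sub <- records[records$video_id %in% vids, ]
    counts <- t(vapply(split(sub$predicted_topic, sub$video_id),
                       function(p) c(sum(p == 0), sum(p == 1)),
                       numeric(2)))
    if (nrow(counts) < 2) return(NULL)
    c(list(raters_per_video = nr), fleiss_kappa(counts))
  })
  summarise <- function(v, g) pooled_t_from_summary(
    sum(g), mean(v[g]), sd(v[g]), sum(!g), mean(v[!g]), sd(v[!g]))
  structure(list(
    n_ratings = nrow(records),
    accuracy = rating_accuracy(records, "rating"),
    video = rating_accuracy(records, "video"),
    rater = rating_accuracy(records, "rater"),
    confusion = conf,
    mcc = suppressWarnings(mcc(conf)),
    chisq_by_topic = chi_square_2x2(by_topic),
    fleiss = Filter(Negate(is.null), kappa),
    confidence_t = summarise(records$confidence, correct),
    decision_time_t = summarise(records$decision_time, correct),
    conf_time_cor = pearson_r(records$confidence, records$decision_time)),
    class = "rater_report")
}

#' @export
print.rater_report <- function(x, ...) {
  cat(sprintf("Human rating study: %d ratings\n", x$n_ratings))
  cat(sprintf("  overall accuracy %.2f%%, MCC %.2f\n",
              x$accuracy$accuracy_pct, x$mcc))
  cat(sprintf("  chi-square by topic: X2(%d) = %.3f, p = %.3f\n",
              x$chisq_by_topic$df, x$chisq_by_topic$chisq,
              x$chisq_by_topic$p))
  for (k in x$fleiss)
    cat(sprintf("  Fleiss kappa (%d raters/video): %.3f (p = %.3g)\n",
                k$raters_per_video, k$kappa, k$p))
  cat(sprintf("  confidence, correct vs not: t(%d) = %.3f, d = %.2f\n",
              x$confidence_t$df, x$confidence_t$t, x$confidence_t$d))
  cat(sprintf("  decision time, correct vs not: t(%d) = %.3f, d = %.2f\n",
              x$decision_time_t$df, x$decision_time_t$t,
              x$decision_time_t$d))
  cat(sprintf("  confidence vs decision time: r = %.3f (p = %.3g)\n",
              x$conf_time_cor$r, x$conf_time_cor$p))
  invisible(x)
}
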