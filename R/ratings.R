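#' Generate a synthetic human-rating table
#'
#' Emulates a rating study in which each rater judges a fixed number of
#' randomly assigned conversation videos (binary topic judgment plus a
#' 1–6 confidence and a 1–100 decision-time report), under the constraint
#' that every video is rated at least three times.  Correctness is
#' Bernoulli(`p_correct`); correct ratings draw higher confidence and
#' earlier decision times than incorrect ones (defaults follow typical
#' observed summaries: confidence means ~4.8 vs ~3.5, decision-time means
#' ~17.5 vs ~27.6).
#'
#' @param n_raters number of raters.
#' @param videos character vector of video ids (one per conversation)
#'   or a single count.
#' @param ratings_per_rater videos rated by each rater (distinct).
#' @param p_correct probability a rating is correct.
#' @param seed integer seed.
#' @param true_topics optional named 0/1 vector of true topics per video;
#'   defaults to balanced alternation.
#' @param conf_means,time_means length-2 numeric: (correct, incorrect)
#'   means of confidence and decision time.
#' @return Data frame of class `rating_table` with columns `rater_id`,
#'   `video_id`, `true_topic`, `predicted_topic`, `correct`,
#'   `confidence` (integer 1–6), `decision_time` (1–100).
#' @examples
#' rt <- generate_rating_table(19, 28, 5, p_correct = 0.82, seed = 1)
#' nrow(rt)            # 95
#' min(table(rt$video_id))  # >= 3
#' @export
generate_rating_table <- function(n_raters, videos, ratings_per_rater,
                                  p_correct, seed,
                                  true_topics = NULL,
                                  conf_means = c(4.8, 3.5),
                                  time_means = c(17.5, 27.6)) {
  if (length(videos) == 1 && is.numeric(videos))
    videos <- sprintf("video%02d", seq_len(videos))
  n_videos <- length(videos)
  stopifnot(n_raters >= 1, ratings_per_rater >= 1,
            p_correct >= 0, p_correct <= 1)
  if (n_raters * ratings_per_rater < 3 * n_videos)
    stop("infeasible assignment: need n_raters * ratings_per_rater >= ",
         "3 * n_videos")
  if (ratings_per_rater > n_videos)
    stop("infeasible assignment: a rater cannot rate more distinct ",
         "videos than exist")
  if (is.null(true_topics))
    true_topics <- stats::setNames(rep(c(0L, 1L), length.out = n_videos),
                                   videos)
  set.seed(seed)

  n_ratings <- n_raters * ratings_per_rater
  # video slot multiset: >= 3 each, extras spread round-robin over a
  # shuffled video order; then each rater greedily takes the videos with
  # the most remaining slots (random tie-break), which keeps the degree
  # sequence feasible while staying random
  base <- rep(3L, n_videos)
  extra <- n_ratings - 3L * n_videos
  ord <- sample.int(n_videos)
  remaining <- base + tabulate(rep(ord, length.out = extra), n_videos)
  assign <- matrix(0L, nrow = ratings_per_rater, ncol = n_raters)
  for (r in seq_len(n_raters)) {
    pick <- order(remaining, runif(n_videos),
                  decreasing = TRUE)[seq_len(ratings_per_rater)]
    if (any(remaining[pick] <= 0))
      stop("could not build a duplicate-free assignment")
    remaining[pick] <- remaining[pick] - 1L
    assign[, r] <- pick
  }

  rater_id <- rep(sprintf("rater%02d", seq_len(n_raters)),
                  each = ratings_per_rater)
  video_id <- videos[as.vector(assign)]
  true_topic <- as.integer(true_topics[video_id])
  correct <- runif(n_ratings) < p_correct
  predicted <- ifelse(correct, true_topic, 1L - true_topic)
  conf_mu <- ifelse(correct, conf_means[1], conf_means[2])
  confidence <- pmin(6L, pmax(1L, as.integer(round(rnorm(n_ratings,
                                                         conf_mu, 1.1)))))
  time_mu <- ifelse(correct, time_means[1], time_means[2])
  decision_time <- pmin(100, pmax(1, rnorm(n_ratings, time_mu, 17)))

  structure(data.frame(rater_id = rater_id, video_id = video_id,
                       true_topic = true_topic,
                       predicted_topic = as.integer(predicted),
                       correct = correct,
                       confidence = confidence,
                       decision_time = decision_time),
            class = c("rating_table", "data.frame"))
}
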