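#' Temporally permute an AU series (control analysis)
#'
#' Destroys temporal structure while preserving the overall value
#' distribution: within each AU channel, the values at speech-free
#' frames are permuted uniformly at random; masked (zeroed) frames stay
#' in place.  The multiset of values per channel is unchanged.
#'
#' @param series an `au_series` (typically masked).
#' @param seed integer seed.
#' @param scope `"speech_free"` (default: shuffle only speech-free
#'   frames) or `"all"` (shuffle every frame).
#' @return The permuted series.
#' @export
permute_series <- function(series, seed,
                           scope = c("speech_free", "all")) {
  stopifnot(inherits(series, "au_series"))
  scope <- match.arg(scope)
  idx <- if (scope == "speech_free") which(!series$speech_mask) else
    seq_len(nrow(series$values))
  if (length(idx) < 2) return(series)
  set.seed(seed)
  for (j in 1:3)
    series$values[idx, j] <- series$values[sample(idx), j]
  series
}

#' Replace AU channels by a binary speech indicator (control analysis)
#'
#' Every AU channel becomes 0 where the participant speaks and 1 where
#' they are silent, so only speech timing can inform the classifier.
#'
#' @param series an `au_series` with a speech mask.
#' @return The series with all three channels equal to the indicator.
#' @export
binarize_speech <- function(series) {
  stopifnot(inherits(series, "au_series"))
  ind <- as.numeric(!series$speech_mask)
  series$values <- matrix(ind, nrow = length(ind), ncol = 3,
                          dimnames = list(NULL, c("au4", "au6", "au12")))
  series
}

#' Static descriptive features of an AU series
#'
#' Eight statistics per AU channel (24 in total): maximum intensity,
#' mean activity, standard deviation (sample, n-1), maximum / mean /
#' minimum episode duration in frames, number of episodes, and total
#' activated frames.  An *episode* is a maximal run of frames with AU
#' value >= `activation_threshold`.  Channels with no episode report
#' zero durations and set the `no_episodes_<au>` attribute flag.
#'
#' @param series an `au_series`.
#' @param activation_threshold threshold in (0,1), default 0.5.
#' @param masked_only if `TRUE`, compute over speech-free frames only
#'   (default `FALSE`: the entire recording).
#' @return Named numeric vector of 24 features
#'   (`<au>_<feature>` naming), with attribute `no_episodes`.
#' @examples
#' s <- new_au_series(cbind(c(0, .8, .9, 0, .7, 0),
#'                          matrix(0.01, 6, 2)), fps = 25)
#' static_features(s)[["au4_n_episodes"]]  # 2
#' @export
static_features <- function(series, activation_threshold = 0.5,
                            masked_only = FALSE) {
  stopifnot(inherits(series, "au_series"),
            activation_threshold > 0, activation_threshold < 1)
  vals <- series$values
  if (masked_only) vals <- vals[!series$speech_mask, , drop = FALSE]
  if (nrow(vals) == 0) stop("empty series")
  feats <- c()
  no_ep <- logical(3)
  for (j in 1:3) {
    x <- vals[, j]
    act <- x >= activation_threshold
    r <- rle(act)
    durs <- r$lengths[r$values]
    if (length(durs) == 0) {
      durs_stats <- c(0, 0, 0)
      no_ep[j] <- TRUE
    } else {
      durs_stats <- c(max(durs), mean(durs), min(durs))
    }
    f <- c(max(x), mean(x), sd(x), durs_stats, length(durs), sum(act))
    names(f) <- paste0(colnames(vals)[j], "_",
                       c("max", "mean", "sd", "max_dur", "mean_dur",
                         "min_dur", "n_episodes", "total_active"))
    feats <- c(feats, f)
  }
  attr(feats, "no_episodes") <- stats::setNames(no_ep, colnames(vals))
  feats
}

#' Static feature table of a dataset, aggregated to triad level
#'
#' Participant features are averaged within each triad so the table fits
#' the triad-level cross-group validation.
#'
#' @param dataset an `au_dataset`.
#' @inheritParams static_features
#' @return Data frame: one row per triad, 24 feature columns plus
#'   `triad_id` and `condition`.
#' @export
dataset_static_features <- function(dataset, activation_threshold = 0.5,
                                    masked_only = FALSE) {
  rows <- lapply(dataset, function(tr) {
    f <- rowMeans(vapply(tr$participants, static_features,
                         numeric(24),
                         activation_threshold = activation_threshold,
                         masked_only = masked_only))
    cbind(data.frame(triad_id = tr$triad_id, condition = tr$condition),
          as.data.frame(as.list(f)))
  })
  do.call(rbind, rows)
}

#' Baseline classification from static features
#'
#' Logistic regression or random forest on the 24 static features (not
#' normalized), trained and tested on the same cross-group fold plan as
#' the image pipeline and pooled with [compute_metrics()].
#'
#' @param features data frame from [dataset_static_features()].
#' @param plan a [make_folds()] plan over the same triad ids.
#' @param model `"logistic"` or `"random_forest"`.
#' @param seed integer seed (random forest).
#' @return An object of class `faudyn_cv` (without a CNN config).
#' @export
baseline_classify <- function(features, plan,
                              model = c("logistic", "random_forest"),
                              seed = 1L) {
  model <- match.arg(model)
  stopifnot(inherits(plan, "fold_plan"))
  fcols <- setdiff(names(features), c("triad_id", "condition"))
  rows <- list()
  for (f in seq_along(plan)) {
    fold <- plan[[f]]
    tr <- features[features$triad_id %in% c(fold$train, fold$val), ]
    te <- features[features$triad_id %in% fold$test, ]
    if (length(unique(tr$condition)) < 2)
      stop("fold ", f, " has single-class training labels")
    if (model == "logistic") {
      fit <- suppressWarnings(glm(condition ~ ., family = binomial(),
                                  data = tr[, c("condition", fcols)]))
      p <- suppressWarnings(predict(fit, te, type = "response"))
    } else {
      set.seed(sub_seed(seed, f, salt = 5L))
      fit <- randomForest::randomForest(
        x = tr[, fcols], y = factor(tr$condition, levels = c(0, 1)))
      p <- predict(fit, te[, fcols], type = "prob")[, "1"]
    }
    rows[[f]] <- data.frame(triad_id = te$triad_id,
                            condition = te$condition,
                            prob = as.numeric(p),
                            pred = as.integer(p >= 0.5), fold = f)
  }
  res <- do.call(rbind, rows)
  res <- res[match(attr(plan, "ids"), res$triad_id), ]
  metrics <- compute_metrics(
    c(tp = sum(res$pred == 1 & res$condition == 1),
      fp = sum(res$pred == 1 & res$condition == 0),
      tn = sum(res$pred == 0 & res$condition == 0),
      fn = sum(res$pred == 0 & res$condition == 1)),
    probabilities = res$prob, labels = res$condition, folds = res$fold)
  structure(list(triads = res, metrics = metrics, plan = plan,
                 config = list(backbone = model)),
            class = "faudyn_cv")
}

#' Accuracy grid over segment length and position
#'
#' Re-runs the full pipeline (mask, optional segment crop, GADF
#' encoding, cross-group CNN) for every combination of segment length
#' and position, with identical fold plans and seeds across cells.
#'
#' @param dataset an `au_dataset`.
#' @param lengths_min numeric vector of segment lengths in minutes.
#' @param positions subset of `c("first", "middle", "last")`.
#' @param config a [classifier_config()].
#' @param seed seed shared by all cells.
#' @return A `segment_grid` data frame: `length_min`, `position`,
#'   `accuracy_pct`.
#' @export
segment_accuracy_grid <- function(dataset, lengths_min = 2:7,
                                  positions = c("first", "middle", "last"),
                                  config = classifier_config(),
                                  seed = 1L) {
  grid <- expand.grid(length_min = lengths_min, position = positions,
                      stringsAsFactors = FALSE)
  grid$accuracy_pct <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cv <- decode_topics(dataset, config,
                        segment = list(length_min = grid$length_min[i],
                                       position = grid$position[i]),
                        seed = seed)
    grid$accuracy_pct[i] <- cv$metrics$accuracy_pct
  }
  structure(grid, class = c("segment_grid", "data.frame"))
}
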