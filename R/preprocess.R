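#' Extract a fixed-length segment from an AU series
#'
#' Positions follow the convention: `first` takes frames `[0, L)`,
#' `middle` takes `[floor(T/2) - floor(L/2), +L)` (centered on the
#' midpoint frame, left-biased on odd remainders), `last` takes
#' `[T - L, T)`, with `L = length_min * 60 * fps`.  The speech mask is
#' cropped identically.
#'
#' @param series an `au_series`.
#' @param length_min segment length in minutes (positive).
#' @param position one of `"first"`, `"middle"`, `"last"`.
#' @return The cropped `au_series`.
#' @examples
#' s <- new_au_series(matrix(runif(22500 * 3), ncol = 3), fps = 25)
#' seg <- extract_segment(s, 2, "first")   # frames 1..3000
#' @export
extract_segment <- function(series, length_min,
                            position = c("first", "middle", "last")) {
  stopifnot(inherits(series, "au_series"), length_min > 0)
  position <- match.arg(position)
  n <- nrow(series$values)
  L <- as.integer(round(length_min * 60 * series$fps))
  if (L > n) stop("segment length exceeds conversation duration")
  start0 <- switch(position,                      # 0-based start frame
                   first = 0L,
                   middle = n %/% 2L - L %/% 2L,
                   last = n - L)
  idx <- (start0 + 1L):(start0 + L)
  series$values <- series$values[idx, , drop = FALSE]
  series$speech_mask <- series$speech_mask[idx]
  series$segments <- NULL  # millisecond bookkeeping no longer aligned
  series
}

#' Frame quality-control report
#'
#' Counts frames flagged invalid by an upstream face-detection QC step
#' and removes them from the series (positions closed up; no
#' interpolation).
#'
#' @param valid_flags logical per frame, `TRUE` = frame kept.
#' @param series optional `au_series` to filter.
#' @return A list of class `qc_report`: `total_frames`, `removed_frames`,
#'   `removed_percent` (2 dp), and `series` (filtered, if given).
#' @examples
#' qc_report(c(TRUE, TRUE, TRUE, FALSE))$removed_percent  # 25
#' @export
qc_report <- function(valid_flags, series = NULL) {
  if (length(valid_flags) == 0) stop("empty flags")
  stopifnot(is.logical(valid_flags))
  if (!any(valid_flags)) stop("all frames invalid")
  total <- length(valid_flags)
  removed <- sum(!valid_flags)
  if (!is.null(series)) {
    stopifnot(inherits(series, "au_series"),
              length(valid_flags) == nrow(series$values))
    series$values <- series$values[valid_flags, , drop = FALSE]
    series$speech_mask <- series$speech_mask[valid_flags]
  }
  structure(list(total_frames = total, removed_frames = removed,
                 removed_percent = round(100 * removed / total, 2),
                 series = series),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: removed %d of %d frames (%.2f%%)\n",
              x$removed_frames, x$total_frames, x$removed_percent))
  invisible(x)
}

#' Two-sample Kolmogorov–Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs; the p-value
#' uses the standard asymptotic two-sample approximation.  Used, e.g., to
#' compare per-triad speech-free proportions between conditions.
#'
#' @param x,y numeric samples (nonempty).
#' @return List with `D` and `p`.
#' @examples
#' ks_two_sample(c(1, 3), c(2, 4))$D  # 0.5
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Speech-free fractions of a dataset, by triad or participant
#'
#' @param dataset an `au_dataset`.
#' @param by `"triad"` (mean over the triad's participants; default) or
#'   `"participant"`.
#' @return Data frame with `triad_id`, `condition`, `fraction` (and
#'   `participant_id` when `by = "participant"`).
#' @export
dataset_speech_free <- function(dataset, by = c("triad", "participant")) {
  by <- match.arg(by)
  rows <- lapply(dataset, function(tr) {
    f <- vapply(tr$participants,
                function(p) speech_free_fraction(p$speech_mask), numeric(1))
    if (by == "triad")
      data.frame(triad_id = tr$triad_id, condition = tr$condition,
                 fraction = mean(f))
    else
      data.frame(triad_id = tr$triad_id, condition = tr$condition,
                 participant_id = vapply(tr$participants,
                                         `[[`, character(1),
                                         "participant_id"),
                 fraction = f)
  })
  do.call(rbind, rows)
}
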