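#' Generate turn-taking speech segments for one triad
#'
#' Simulates an alternating-speaker process: silent gaps shared by the
#' whole triad alternate with single-speaker turns, the next speaker drawn
#' uniformly among the two participants who did not just speak.  Turn and
#' gap lengths are exponential; the gap mean is chosen so that each
#' participant's *expected* speech-free fraction equals
#' `target_speech_free_fraction` (each participant takes one third of the
#' turns, so their speaking fraction is one third of the triad's total
#' speaking fraction).
#'
#' @param config a [generator_config()].
#' @param triad_seed integer seed for this triad's turn sequence.
#' @return A list of three `speech_segments` data frames (columns
#'   `participant_id`, `start_ms`, `end_ms`; half-open millisecond
#'   intervals, sorted, non-overlapping within a participant).
#' @examples
#' cfg <- generator_config(n_triads = 2, duration_s = 120, seed = 1)
#' segs <- generate_speech_segments(cfg, triad_seed = 5)
#' sapply(segs, nrow)
#' @export
generate_speech_segments <- function(config, triad_seed) {
  stopifnot(inherits(config, "generator_config"))
  dur_ms <- config$duration_s * 1000
  ids <- paste0("p", 1:3)
  empty <- lapply(ids, function(id)
    structure(data.frame(participant_id = character(0),
                         start_ms = numeric(0), end_ms = numeric(0)),
              class = c("speech_segments", "data.frame")))
  names(empty) <- ids

  # speaking fraction of the whole triad; each participant speaks 1/3 of it
  speak_frac <- 3 * (1 - config$target_speech_free_fraction)
  if (speak_frac >= 1)
    stop("target_speech_free_fraction below 2/3 is not reachable with ",
         "one speaker at a time")
  if (speak_frac <= 0) return(empty)  # fraction 1: nobody speaks
  mean_turn_ms <- config$mean_turn_s * 1000
  mean_gap_ms <- mean_turn_ms * (1 - speak_frac) / speak_frac

  set.seed(triad_seed)
  t <- rexp(1, 1 / mean_gap_ms)   # leading gap
  if (t >= dur_ms) {
    warning("duration too short to place any speaking turn")
    return(empty)
  }
  starts <- list(numeric(0), numeric(0), numeric(0))
  ends <- list(numeric(0), numeric(0), numeric(0))
  current <- 0L
  while (t < dur_ms) {
    speaker <- if (current == 0L) sample.int(3L, 1L) else
      sample(setdiff(1:3, current), 1L)
    len <- rexp(1, 1 / mean_turn_ms)
    end <- min(t + len, dur_ms)
    starts[[speaker]] <- c(starts[[speaker]], t)
    ends[[speaker]] <- c(ends[[speaker]], end)
    current <- speaker
    t <- end + rexp(1, 1 / mean_gap_ms)
  }
  out <- lapply(1:3, function(i)
    structure(data.frame(participant_id = rep(ids[i], length(starts[[i]])),
                         start_ms = starts[[i]], end_ms = ends[[i]]),
              class = c("speech_segments", "data.frame")))
  names(out) <- ids
  out
}

# frames whose [i*1000/fps, (i+1)*1000/fps) window intersects any interval;
# a frame counts as speech if any part of it overlaps speech (strict rule)
speech_mask_from_segments <- function(segments, n_frames, fps) {
  mask <- logical(n_frames)
  if (nrow(segments) == 0) return(mask)
  frame_ms <- 1000 / fps
  if (any(segments$start_ms < 0) ||
      any(segments$end_ms > n_frames * frame_ms + 1e-9))
    stop("speech segment outside conversation duration")
  for (r in seq_len(nrow(segments))) {
    i0 <- max(0L, as.integer(floor(segments$start_ms[r] / frame_ms)))
    i1 <- min(n_frames - 1L,
              as.integer(ceiling(segments$end_ms[r] / frame_ms)) - 1L)
    if (i1 >= i0) mask[(i0 + 1L):(i1 + 1L)] <- TRUE
  }
  mask
}

#' Zero AU signals during a participant's own speech
#'
#' Speech periods are masked in the AU signals by setting all three AU
#' channels to zero, so that only speech-free facial activity feeds the
#' downstream image encoding.  A frame counts as speech if its
#' `[i/fps, (i+1)/fps)` window overlaps any speech interval.
#'
#' @param series an `au_series` object.
#' @param segments a `speech_segments` data frame for the same
#'   participant (millisecond half-open intervals).
#' @return The series with masked frames zeroed and `speech_mask` set.
#' @examples
#' s <- new_au_series(matrix(runif(75), 25, 3), fps = 25)
#' seg <- data.frame(participant_id = "p1", start_ms = 100, end_ms = 300)
#' m <- mask_speech(s, seg)
#' sum(m$speech_mask)  # 6 frames
#' @export
mask_speech <- function(series, segments) {
  stopifnot(inherits(series, "au_series"))
  n <- nrow(series$values)
  add <- speech_mask_from_segments(segments, n, series$fps)
  series$speech_mask <- series$speech_mask | add
  series$values[series$speech_mask, ] <- 0
  series
}

#' Fraction of frames that are speech-free
#'
#' @param mask logical vector, `TRUE` where the participant is speaking.
#' @return `count(FALSE) / length(mask)`.
#' @export
speech_free_fraction <- function(mask) {
  if (length(mask) == 0) stop("empty mask")
  stopifnot(is.logical(mask))
  sum(!mask) / length(mask)
}
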