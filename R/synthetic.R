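#' Construct an AU time-series object
#'
#' One participant's facial action-unit intensity matrix over frames:
#' columns AU4 (brow lowerer), AU6 (cheek raiser), AU12 (lip-corner
#' puller), each in \[0, 1\], plus a per-frame speech mask (`TRUE` =
#' speaking).
#'
#' @param values numeric frames x 3 matrix in \[0, 1\].
#' @param fps frames per second.
#' @param participant_id,triad_id identifiers.
#' @param condition 0 (get-to-know-each-other), 1 (moral dilemma) or NA.
#' @param speech_mask logical per frame; defaults to all `FALSE`.
#' @param segments optional `speech_segments` data frame for this
#'   participant, kept alongside the series.
#' @return An object of class `au_series`.
#' @export
new_au_series <- function(values, fps, participant_id = "p1",
                          triad_id = NA_character_, condition = NA_integer_,
                          speech_mask = NULL, segments = NULL) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == 3, nrow(values) >= 1, fps > 0,
            all(values >= 0), all(values <= 1))
  if (!is.na(condition) && !condition %in% c(0L, 1L))
    stop("condition must be 0, 1 or NA")
  colnames(values) <- c("au4", "au6", "au12")
  if (is.null(speech_mask)) speech_mask <- logical(nrow(values))
  stopifnot(is.logical(speech_mask), length(speech_mask) == nrow(values))
  structure(list(participant_id = participant_id, triad_id = triad_id,
                 condition = if (is.na(condition)) NA_integer_
                             else as.integer(condition),
                 values = values, speech_mask = speech_mask,
                 fps = fps, segments = segments),
            class = "au_series")
}

#' @export
print.au_series <- function(x, ...) {
  cat(sprintf("AU time series: %s (triad %s, condition %s)\n",
              x$participant_id, x$triad_id, x$condition))
  cat(sprintf("  %d frames at %g fps (%.1f s), speech-free %.1f%%\n",
              nrow(x$values), x$fps, nrow(x$values) / x$fps,
              100 * speech_free_fraction(x$speech_mask)))
  invisible(x)
}

# gamma parameterized by mean/sd
rdur <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  rgamma(n, shape = shape, rate = shape / mean)
}

# draw episode onsets/durations/amplitudes for one channel
draw_episodes <- function(n_ep, ce, duration_s) {
  data.frame(onset_s = rbeta(n_ep, ce$onset_beta[1], ce$onset_beta[2]) *
               duration_s,
             dur_s = rdur(n_ep, ce$dur_mean, ce$dur_sd),
             amp = runif(n_ep, ce$amp_range[1], ce$amp_range[2]))
}

# render episodes as a rise-plateau-fall (trapezoid) profile, max-combined
render_episodes <- function(ep, n_frames, fps) {
  x <- numeric(n_frames)
  if (nrow(ep) == 0) return(x)
  for (r in seq_len(nrow(ep))) {
    i0 <- floor(ep$onset_s[r] * fps) + 1
    i1 <- min(n_frames, ceiling((ep$onset_s[r] + ep$dur_s[r]) * fps))
    if (i1 < i0) next
    len <- i1 - i0 + 1
    ramp <- max(1L, round(0.25 * len))
    prof <- rep(1, len)
    prof[seq_len(ramp)] <- seq_len(ramp) / ramp
    prof[(len - ramp + 1):len] <- pmin(prof[(len - ramp + 1):len],
                                       rev(seq_len(ramp) / ramp))
    seg <- i0:i1
    x[seg] <- pmax(x[seg], ep$amp[r] * prof)
  }
  x
}

#' Generate one synthetic triadic conversation
#'
#' Places burst-like AU episodes as a Poisson point process with the
#' condition's rates, durations, amplitudes and AU6–AU12 co-activation
#' (see [condition_effect()]), on top of low-level baseline noise, and
#' attaches a turn-taking speech mask.  Values are *not* masked here;
#' apply [mask_speech()] downstream.
#'
#' @param config a [generator_config()].
#' @param triad_id identifier for the triad.
#' @param condition 0 or 1.
#' @param seed integer seed; output is bitwise-reproducible given the
#'   seed.
#' @return An object of class `au_triad`: list with `triad_id`,
#'   `condition`, `participants` (three `au_series` of equal length).
#' @examples
#' cfg <- generator_config(n_triads = 2, duration_s = 60, seed = 1)
#' tri <- generate_triad(cfg, "t1", condition = 1, seed = 42)
#' @export
generate_triad <- function(config, triad_id, condition, seed) {
  stopifnot(inherits(config, "generator_config"))
  if (!condition %in% c(0, 1)) stop("invalid condition label")
  ce <- config$condition_effect[[as.character(condition)]]
  n <- as.integer(round(config$duration_s * config$fps))
  segs <- generate_speech_segments(config, sub_seed(seed, 1L, salt = 1L))

  set.seed(seed)
  dur_min <- config$duration_s / 60
  participants <- vector("list", 3)
  for (p in 1:3) {
    n6 <- rpois(1, ce$rates["au6"] * dur_min)
    ep6 <- draw_episodes(n6, ce, config$duration_s)
    co <- if (n6 > 0) runif(n6) < ce$coactivation else logical(0)
    n12i <- rpois(1, max(0, ce$rates["au12"] - ce$coactivation *
                              ce$rates["au6"]) * dur_min)
    ep12 <- rbind(ep6[co, , drop = FALSE],
                  draw_episodes(n12i, ce, config$duration_s))
    n4 <- rpois(1, ce$rates["au4"] * dur_min)
    ep4 <- draw_episodes(n4, ce, config$duration_s)

    vals <- cbind(au4 = render_episodes(ep4, n, config$fps),
                  au6 = render_episodes(ep6, n, config$fps),
                  au12 = render_episodes(ep12, n, config$fps))
    baseline <- matrix(runif(3 * n, 0, config$baseline_max), n, 3)
    vals <- pmin(pmax(vals, baseline), 1)
    pid <- paste0(triad_id, "_p", p)
    seg <- segs[[p]]
    seg$participant_id <- rep(pid, nrow(seg))
    participants[[p]] <- new_au_series(
      vals, config$fps, participant_id = pid, triad_id = triad_id,
      condition = condition,
      speech_mask = speech_mask_from_segments(seg, n, config$fps),
      segments = seg)
  }
  structure(list(triad_id = triad_id, condition = as.integer(condition),
                 participants = participants),
            class = "au_triad")
}

#' @export
print.au_triad <- function(x, ...) {
  cat(sprintf("Triad %s (condition %d): 3 participants, %d frames\n",
              x$triad_id, x$condition, nrow(x$participants[[1]]$values)))
  invisible(x)
}

#' Generate a dataset of synthetic triads
#'
#' Conditions are assigned in balanced alternation (0, 1, 0, 1, ...), so
#' an even `n_triads` yields exactly n/2 triads per condition.  A
#' manifest (attribute `"manifest"`) records per-triad ids, conditions
#' and seeds.
#'
#' @param config a [generator_config()]; `n_triads >= 2`.
#' @return An object of class `au_dataset`: list of `au_triad`.
#' @examples
#' ds <- generate_dataset(generator_config(n_triads = 4, duration_s = 30))
#' table(dataset_labels(ds))
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_triads < 2) stop("n_triads must be at least 2")
  n <- config$n_triads
  conditions <- rep(c(0L, 1L), length.out = n)
  ids <- sprintf("triad%02d", seq_len(n))
  seeds <- vapply(seq_len(n), function(i) sub_seed(config$seed, i),
                  integer(1))
  triads <- lapply(seq_len(n), function(i)
    generate_triad(config, ids[i], conditions[i], seeds[i]))
  manifest <- data.frame(triad_id = ids, condition = conditions,
                         seed = seeds)
  structure(triads, manifest = manifest, fps = config$fps,
            class = "au_dataset")
}

#' Per-triad condition labels of a dataset
#' @param dataset an `au_dataset`.
#' @return Named integer vector of 0/1 labels, names = triad ids.
#' @export
dataset_labels <- function(dataset) {
  stats::setNames(vapply(dataset, function(t) t$condition, integer(1)),
                  vapply(dataset, function(t) t$triad_id, character(1)))
}

#' @export
print.au_dataset <- function(x, ...) {
  lab <- dataset_labels(x)
  cat(sprintf("AU dataset: %d triads (%d / %d per condition), %d frames each\n",
              length(x), sum(lab == 0), sum(lab == 1),
              nrow(x[[1]]$participants[[1]]$values)))
  invisible(x)
}
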