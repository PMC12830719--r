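#' Per-condition episode dynamics for the synthetic generator
#'
#' Describes, for one conversation condition, how burst-like AU episodes
#' are placed in time.  Episode *rates* are per minute and per AU channel
#' (AU4, AU6, AU12); durations are gamma-distributed with the given mean
#' and SD (seconds); amplitudes are uniform on `amp_range`; `coactivation`
#' is the probability that an AU6 episode is accompanied by a synchronous
#' AU12 episode (shared onset, duration and amplitude); `onset_beta` are
#' the two shape parameters of the beta distribution that places episode
#' onsets within the conversation (c(1, 1) = uniform; shape1 < shape2
#' concentrates episodes early).
#'
#' The default *pair* of effects (see [generator_config()]) keeps rates,
#' durations and amplitudes identical across conditions and lets only the
#' AU6–AU12 co-activation probability differ.  That makes the pooled
#' per-AU value distributions — and hence every per-AU static summary —
#' identical across conditions by construction, while the joint temporal
#' structure (which the GADF image encoding exposes as channel alignment)
#' still separates them.
#'
#' @param rates named numeric, episodes/min for au4, au6, au12.
#' @param dur_mean,dur_sd mean and SD of episode duration, seconds.
#' @param coactivation probability in \[0,1\] that an AU6 episode recruits
#'   a synchronous AU12 episode.
#' @param amp_range length-2 numeric in (0,1), episode amplitude bounds.
#' @param onset_beta length-2 positive numeric, beta shapes for onset
#'   placement.
#' @return An object of class `condition_effect`.
#' @export
condition_effect <- function(rates = c(au4 = 2, au6 = 3, au12 = 3),
                             dur_mean = 2, dur_sd = 1,
                             coactivation = 0.5,
                             amp_range = c(0.5, 0.95),
                             onset_beta = c(1, 1)) {
  stopifnot(length(rates) == 3, all(rates >= 0),
            dur_mean > 0, dur_sd > 0,
            coactivation >= 0, coactivation <= 1,
            length(amp_range) == 2, amp_range[1] > 0, amp_range[2] <= 1,
            amp_range[1] <= amp_range[2],
            length(onset_beta) == 2, all(onset_beta > 0))
  names(rates) <- c("au4", "au6", "au12")
  if (rates["au12"] < coactivation * rates["au6"])
    stop("au12 rate must be >= coactivation * au6 rate ",
         "(co-activated episodes count towards the au12 rate)")
  structure(list(rates = rates, dur_mean = dur_mean, dur_sd = dur_sd,
                 coactivation = coactivation, amp_range = amp_range,
                 onset_beta = onset_beta),
            class = "condition_effect")
}

#' Configuration of the synthetic triad generator
#'
#' Bundles every knob of the synthetic-data module.  Defaults emulate the
#' study design the package targets: triads of three participants, about
#' 15-minute conversations sampled at 25 frames/s, roughly 77% of each
#' participant's time speech-free, and two conditions whose AU dynamics
#' differ in temporal structure (AU6–AU12 co-activation) but not in
#' marginal value distributions.
#'
#' @param n_triads number of triads to generate.
#' @param duration_s conversation length in seconds (default 900).
#' @param fps sampling rate in frames/s (default 25).
#' @param target_speech_free_fraction expected speech-free fraction of
#'   each participant's timeline, in (0,1\] (default 0.77; 1 means a
#'   fully silent conversation).
#' @param mean_turn_s mean speaking-turn length in seconds; the
#'   inter-turn gap mean is derived from it and
#'   `target_speech_free_fraction`.
#' @param condition_effect list of two [condition_effect()] objects named
#'   `"0"` (get-to-know-each-other) and `"1"` (moral dilemma).
#' @param marginals_matched logical; if `TRUE` (default) the two
#'   condition effects must share rates, durations and amplitude ranges so
#'   pooled per-AU value distributions are equal by construction and only
#'   timing statistics (co-activation, onset placement) may differ.
#' @param baseline_max upper bound of the per-frame baseline noise
#'   (uniform on \[0, baseline_max\]); must stay below 0.1.
#' @param seed integer seed controlling all generation.
#' @return An object of class `generator_config`.
#' @examples
#' cfg <- generator_config(n_triads = 4, duration_s = 60, seed = 1)
#' ds <- generate_dataset(cfg)
#' @export
generator_config <- function(n_triads = 28,
                             duration_s = 900,
                             fps = 25,
                             target_speech_free_fraction = 0.77,
                             mean_turn_s = 6,
                             condition_effect = list(
                               "0" = faudyn::condition_effect(coactivation = 0.15),
                               "1" = faudyn::condition_effect(coactivation = 0.85)),
                             marginals_matched = TRUE,
                             baseline_max = 0.08,
                             seed = 1L) {
  stopifnot(n_triads >= 1, duration_s > 0, fps > 0,
            target_speech_free_fraction > 0,
            target_speech_free_fraction <= 1,
            mean_turn_s > 0,
            is.list(condition_effect),
            all(c("0", "1") %in% names(condition_effect)),
            baseline_max > 0, baseline_max < 0.1)
  for (ce in condition_effect[c("0", "1")])
    if (!inherits(ce, "condition_effect"))
      stop("condition_effect entries must be condition_effect objects")
  if (marginals_matched) {
    a <- condition_effect[["0"]]; b <- condition_effect[["1"]]
    same <- isTRUE(all.equal(a$rates, b$rates)) &&
      isTRUE(all.equal(c(a$dur_mean, a$dur_sd), c(b$dur_mean, b$dur_sd))) &&
      isTRUE(all.equal(a$amp_range, b$amp_range))
    if (!same)
      stop("marginals_matched = TRUE requires equal rates, durations and ",
           "amplitude ranges across conditions")
  }
  structure(list(n_triads = as.integer(n_triads),
                 duration_s = duration_s, fps = fps,
                 target_speech_free_fraction = target_speech_free_fraction,
                 mean_turn_s = mean_turn_s,
                 condition_effect = condition_effect,
                 marginals_matched = marginals_matched,
                 baseline_max = baseline_max,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic triad generator configuration\n")
  cat(sprintf("  %d triads, %.0f s at %g fps (%d frames)\n",
              x$n_triads, x$duration_s, x$fps,
              as.integer(round(x$duration_s * x$fps))))
  cat(sprintf("  target speech-free fraction: %.2f (mean turn %.1f s)\n",
              x$target_speech_free_fraction, x$mean_turn_s))
  cat(sprintf("  marginals matched: %s\n", x$marginals_matched))
  for (k in c("0", "1")) {
    ce <- x$condition_effect[[k]]
    cat(sprintf("  condition %s: rates %s /min, dur %.1f±%.1f s, coact %.2f\n",
                k, paste(ce$rates, collapse = "/"),
                ce$dur_mean, ce$dur_sd, ce$coactivation))
  }
  invisible(x)
}

# derive a reproducible 32-bit sub-seed from a base seed and an index
sub_seed <- function(seed, index, salt = 0L) {
  s <- (as.double(seed) * 2654435.0 + index * 97003.0 + salt * 7919.0)
  as.integer(s %% 2147483647)
}
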