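# small configs and cached heavyweight results shared across test files

tiny_config <- function(n_triads = 4, duration_s = 60, seed = 1, ...) {
  generator_config(n_triads = n_triads, duration_s = duration_s,
                   seed = seed, ...)
}

# classifier settings used by the CNN-based acceptance experiments
accept_classifier <- function(seed = 1L) {
  classifier_config(backbone = "tiny", side = 64, work_len = 256,
                    seed = seed)
}

# The dynamics-recovery experiment (main pipeline + baselines + controls
# on the same data/folds) is expensive; compute once per test run and
# share between test blocks.
.accept_cache <- new.env(parent = emptyenv())

accept_experiments <- function(seeds = 1:5) {
  key <- paste0("exp_", paste(seeds, collapse = "_"))
  if (!is.null(.accept_cache[[key]])) return(.accept_cache[[key]])
  rows <- lapply(seeds, function(seed) {
    ds <- generate_dataset(generator_config(n_triads = 28, seed = seed))
    cv <- decode_topics(ds, accept_classifier(), input = "au",
                        seed = seed)
    cvp <- decode_topics(ds, accept_classifier(), input = "permuted",
                         seed = seed)
    cvb <- decode_topics(ds, accept_classifier(),
                         input = "speech_binary", seed = seed)
    bl <- baseline_classify(dataset_static_features(ds), cv$plan,
                            "logistic", seed = seed)
    data.frame(seed = seed,
               cnn = cv$metrics$accuracy,
               permuted = cvp$metrics$accuracy,
               speech_binary = cvb$metrics$accuracy,
               logistic = bl$metrics$accuracy)
  })
  .accept_cache[[key]] <- do.call(rbind, rows)
  .accept_cache[[key]]
}
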