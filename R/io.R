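#' Write a dataset to CSV files plus a JSON manifest
#'
#' One CSV per participant (`frame`, `au4`, `au6`, `au12`, `speech`), one
#' CSV per participant for speech segments (`participant_id`,
#' `start_ms`, `end_ms`), and `manifest.json` recording triad ids,
#' conditions, seeds and fps.
#'
#' @param dataset an `au_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "au_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tr in dataset) {
    for (p in tr$participants) {
      df <- data.frame(frame = seq_len(nrow(p$values)) - 1L,
                       au4 = p$values[, "au4"], au6 = p$values[, "au6"],
                       au12 = p$values[, "au12"],
                       speech = as.integer(p$speech_mask))
      write.csv(df, file.path(dir, paste0(p$participant_id, ".csv")),
                row.names = FALSE)
      if (!is.null(p$segments))
        write.csv(p$segments,
                  file.path(dir, paste0(p$participant_id, "_speech.csv")),
                  row.names = FALSE)
    }
  }
  manifest <- attr(dataset, "manifest")
  jsonlite::write_json(list(fps = attr(dataset, "fps"),
                            triads = manifest),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing the CSVs and `manifest.json`.
#' @return An `au_dataset`.
#' @export
read_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  fps <- man$fps
  triads <- lapply(seq_len(nrow(man$triads)), function(i) {
    tid <- man$triads$triad_id[i]
    cond <- as.integer(man$triads$condition[i])
    participants <- lapply(1:3, function(p) {
      pid <- paste0(tid, "_p", p)
      df <- read.csv(file.path(dir, paste0(pid, ".csv")))
      segf <- file.path(dir, paste0(pid, "_speech.csv"))
      segs <- if (file.exists(segf)) {
        s <- read.csv(segf)
        structure(s, class = c("speech_segments", "data.frame"))
      } else NULL
      new_au_series(as.matrix(df[, c("au4", "au6", "au12")]), fps,
                    participant_id = pid, triad_id = tid,
                    condition = cond,
                    speech_mask = df$speech == 1L, segments = segs)
    })
    structure(list(triad_id = tid, condition = cond,
                   participants = participants), class = "au_triad")
  })
  structure(triads, manifest = man$triads, fps = fps,
            class = "au_dataset")
}

#' Read a ratings CSV
#'
#' Expects columns `rater_id`, `video_id`, `true_topic`,
#' `predicted_topic`, `confidence`, `decision_time` (a `correct` column
#' is recomputed).
#'
#' @param path CSV file path.
#' @return A `rating_table` data frame.
#' @export
read_rating_table <- function(path) {
  df <- read.csv(path)
  need <- c("rater_id", "video_id", "true_topic", "predicted_topic",
            "confidence", "decision_time")
  if (!all(need %in% names(df)))
    stop("ratings CSV must have columns: ", paste(need, collapse = ", "))
  df$correct <- df$true_topic == df$predicted_topic
  structure(df, class = c("rating_table", "data.frame"))
}
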