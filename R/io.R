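# Plain-text on-disk formats: event tables as TSV, signals as one CSV per
# subject-session with a JSON sidecar holding the acquisition metadata.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read an event table as TSV
#'
#' Column names follow the event-table contract (`subject_id`, `phase`,
#' `trial_index`, `statement_id`, `repetition_status`, `veridicality`,
#' `stimulus_onset`, `response_onset`, `rt_ms`, `judgment`, `confidence`,
#' `latent_corrugator`).
#'
#' @param events event table data.frame.
#' @param path file path.
#' @return the path (write) or the table with design attributes restored
#'   from the companion manifest when present (read).
#' @export
write_events_tsv <- function(events, path) {
  write_tsv(as.data.frame(events), path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  ev <- read_tsv(path)
  manifest <- file.path(dirname(path), "manifest.json")
  if (file.exists(manifest)) {
    mf <- jsonlite::read_json(manifest, simplifyVector = TRUE)
    if (!is.null(mf$config$design)) {
      attr(ev, "config") <- do.call(design_config, mf$config$design)
    }
  }
  ev
}

#' Write / read one subject-session signal file
#'
#' Signals are stored as CSV with columns `sample_index`, `corrugator_uV`,
#' `zygomaticus_uV`, `frontalis_uV`, plus a JSON sidecar
#' (`<path>.json`) carrying `sampling_rate`, `subject` and `phase`.
#'
#' @param rec an `emg_recording`.
#' @param path CSV file path.
#' @return the path (write) or an `emg_recording` (read).
#' @export
write_signal_csv <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  df <- data.frame(sample_index = seq_len(nrow(rec$signal)),
                   corrugator_uV = rec$signal[, "corrugator"],
                   zygomaticus_uV = rec$signal[, "zygomaticus"],
                   frontalis_uV = rec$signal[, "frontalis"])
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(sampling_rate = rec$sampling_rate,
                            subject = rec$subject_id, phase = rec$phase,
                            channels = rec$channels),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_signal_csv
#' @export
read_signal_csv <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop2("missing JSON sidecar for %s", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  df <- utils::read.csv(path)
  need <- c("corrugator_uV", "zygomaticus_uV", "frontalis_uV")
  if (!all(need %in% names(df)) || anyNA(df[need])) {
    stop2("corrupted signal file %s (subject %s, phase %s)",
          path, meta$subject, meta$phase)
  }
  sig <- as.matrix(df[, need])
  colnames(sig) <- MUSCLES
  structure(list(subject_id = meta$subject, phase = meta$phase,
                 channels = MUSCLES, signal = sig,
                 sampling_rate = meta$sampling_rate),
            class = "emg_recording")
}
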