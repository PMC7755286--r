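# Plain-text persistence: trial tables as TSV, ground truth as JSON, and a
# documented two-file recording container (meta JSON + signal TSV).

#' Write a trial table to TSV
#'
#' Columns: trial, condition, direction, cue1_onset_s, delay_ms, cue2_onset_s,
#' saccade_latency_ms, included. Onsets are written in seconds.
#'
#' @param trials trial table
#' @param path output file path
#' @return the path, invisibly
#' @export
write_trial_table <- function(trials, path) {
  fs <- attr(trials, "sampling_rate")
  .assert(!is.null(fs), "trial table lacks a sampling_rate attribute")
  out <- data.frame(trial = trials$trial,
                    condition = trials$condition,
                    direction = trials$direction,
                    cue1_onset_s = (trials$cue1_onset - 1) / fs,
                    delay_ms = trials$delay_ms,
                    cue2_onset_s = (trials$cue2_onset - 1) / fs,
                    saccade_latency_ms = trials$saccade_latency_ms,
                    included = trials$included)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trial table written by [write_trial_table()]
#'
#' @param path TSV path
#' @param sampling_rate sampling rate used to restore sample indices
#' @return an `fs_trials` tibble
#' @export
read_trial_table <- function(path, sampling_rate = 1024) {
  d <- read.delim(path)
  out <- tibble::tibble(trial = d$trial,
                        condition = d$condition,
                        direction = d$direction,
                        cue1_onset = as.integer(round(d$cue1_onset_s * sampling_rate)) + 1L,
                        delay_ms = d$delay_ms,
                        cue2_onset = as.integer(round(d$cue2_onset_s * sampling_rate)) + 1L,
                        saccade_latency_ms = d$saccade_latency_ms,
                        included = d$included)
  attr(out, "sampling_rate") <- sampling_rate
  class(out) <- c("fs_trials", class(out))
  out
}

#' Write a recording to a plain-text container
#'
#' Two files: `<prefix>_meta.json` (participant, channel labels, sampling
#' rate, sample count) and `<prefix>_signal.tsv` (samples x channels).
#'
#' @param recording an `fs_recording`
#' @param prefix output path prefix
#' @return the prefix, invisibly
#' @export
write_recording <- function(recording, prefix) {
  meta <- list(participant_id = recording$participant_id,
               channel_labels = recording$channel_labels,
               sampling_rate = recording$sampling_rate,
               n_samples = ncol(recording$signal))
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"), auto_unbox = TRUE,
                       digits = NA)
  sig <- t(recording$signal)
  colnames(sig) <- recording$channel_labels
  write.table(sig, paste0(prefix, "_signal.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(prefix)
}

#' Read a recording written by [write_recording()]
#'
#' @param prefix path prefix used at write time
#' @return an `fs_recording`
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  sig <- as.matrix(read.delim(paste0(prefix, "_signal.tsv"), check.names = FALSE))
  new_recording(t(sig), meta$sampling_rate, meta$channel_labels,
                meta$participant_id)
}

#' Write ground truth to JSON
#'
#' @param ground_truth an `fs_ground_truth`
#' @param path output JSON path
#' @return the path, invisibly
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(unclass(ground_truth), path, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}
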