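#' Construct a raw EEG recording
#'
#' @param samples channels x time numeric matrix, microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector aligned to the rows of `samples`.
#' @param subject_id,trial_id identifiers carried through the pipeline.
#' @param label optional 0-based class index.
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(samples, fs, channel_names,
                          subject_id = NA_character_, trial_id = NA_character_,
                          label = NA_integer_) {
  samples <- as.matrix(samples)
  if (fs <= 0) abort("sampling rate must be positive", "invalid_data")
  if (length(channel_names) != nrow(samples)) {
    abort("channel_names length must match the number of rows", "invalid_data")
  }
  if (anyNA(samples)) abort("recording contains NaN/NA samples", "invalid_data")
  structure(list(
    samples = samples, fs = fs, channel_names = as.character(channel_names),
    subject_id = subject_id, trial_id = trial_id,
    label = if (is.na(label)) NA_integer_ else as.integer(label),
    window_index = NA_integer_
  ), class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d ch x %d samples @ %g Hz, subject %s, trial %s, label %s\n",
              nrow(x$samples), ncol(x$samples), x$fs, x$subject_id, x$trial_id,
              ifelse(is.na(x$label), "-", x$label)))
  invisible(x)
}

#' Write / read a recording as a delimited matrix plus JSON sidecar
#'
#' The on-disk raw format is a plain TSV (channels x samples, row names are
#' channel labels) next to a `<stem>.json` sidecar holding `fs`, `subject_id`,
#' `trial_id` and `label`.
#'
#' @param rec a [raw_recording()].
#' @param stem path without extension; writes `<stem>.tsv` and `<stem>.json`.
#' @return `write_recording` returns `stem` invisibly; `read_recording`
#'   returns a [raw_recording()].
#' @export
write_recording <- function(rec, stem) {
  utils::write.table(rec$samples, paste0(stem, ".tsv"),
                     sep = "\t", quote = FALSE, col.names = FALSE,
                     row.names = rec$channel_names)
  meta <- list(fs = rec$fs, subject_id = rec$subject_id,
               trial_id = rec$trial_id, label = rec$label)
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE, null = "null")
  invisible(stem)
}

#' @rdname write_recording
#' @export
read_recording <- function(stem) {
  tsv <- paste0(stem, ".tsv")
  if (!file.exists(tsv)) abort(paste0("missing recording file: ", tsv), "missing_input")
  tab <- utils::read.delim(tsv, header = FALSE, row.names = 1)
  meta <- jsonlite::read_json(paste0(stem, ".json"))
  m <- as.matrix(tab)
  dimnames(m) <- NULL
  raw_recording(m, fs = meta$fs, channel_names = rownames(tab),
                subject_id = meta$subject_id %||% NA_character_,
                trial_id = meta$trial_id %||% NA_character_,
                label = if (is.null(meta$label) || is.na(meta$label)) NA_integer_ else meta$label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
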