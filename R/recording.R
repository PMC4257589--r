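#' EEG recordings
#'
#' A `recording` is the package's container for one multichannel EEG
#' recording: a channels x samples matrix of potentials (microvolts), the
#' channel labels, the sampling rate, subject/session identity, and the
#' epoch structure (start index and length of each retained epoch).
#'
#' Epochs exist so that downstream operations that must not look across a
#' temporal discontinuity (filtering after artifact rejection, GFP peak
#' detection, segment building) can respect epoch boundaries. A freshly
#' constructed recording holds a single epoch spanning all samples.
#'
#' @param data Numeric matrix, channels x samples.
#' @param channel_labels Character vector of unique channel names, one per
#'   row of `data`.
#' @param sampling_rate Sampling rate in Hz.
#' @param subject_id,session_id Identifiers carried through the pipeline.
#' @param epochs Optional data.frame with columns `start` (1-based sample
#'   index) and `n` (epoch length in samples); defaults to one epoch
#'   covering the whole recording.
#' @return An object of class `recording`.
#' @export
recording <- function(data, channel_labels, sampling_rate,
                      subject_id = NA_character_, session_id = NA_character_,
                      epochs = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be a numeric matrix")
  if (length(channel_labels) != nrow(data))
    stop("channel_labels must have one entry per row of data")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be positive")
  if (is.null(epochs)) {
    epochs <- data.frame(start = 1L, n = ncol(data))
  }
  stopifnot(all(c("start", "n") %in% names(epochs)))
  if (nrow(epochs) > 0) {
    if (any(epochs$start < 1L) || any(epochs$start + epochs$n - 1L > ncol(data)))
      stop("epoch boundaries outside data range")
    if (is.unsorted(epochs$start, strictly = TRUE) && nrow(epochs) > 1)
      stop("epochs must be ordered by start index")
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, channel_labels = as.character(channel_labels),
         sampling_rate = sampling_rate, subject_id = subject_id,
         session_id = session_id, epochs = epochs),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%0.1f s, %d epoch%s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate, nrow(x$epochs),
              if (nrow(x$epochs) == 1) "" else "s"))
  if (!is.na(x$subject_id))
    cat(sprintf("  subject %s, session %s\n", x$subject_id, x$session_id))
  invisible(x)
}

#' @export
dim.recording <- function(x) dim(x$data)

# Total retained duration in seconds (sum of epoch lengths)
#' @rdname recording
#' @param x A `recording`.
#' @export
recording_duration <- function(x) sum(x$epochs$n) / x$sampling_rate

# identifier used in tables: "<subject>_<session>"
recording_id <- function(x) paste(x$subject_id, x$session_id, sep = "_")

# Apply a per-channel function within each epoch, preserving shape.
# f receives a channels x n matrix and must return one of the same shape.
.map_epochs <- function(rec, f) {
  out <- rec$data
  for (i in seq_len(nrow(rec$epochs))) {
    idx <- rec$epochs$start[i] + seq_len(rec$epochs$n[i]) - 1L
    out[, idx] <- f(rec$data[, idx, drop = FALSE])
  }
  rec$data <- out
  rec
}

#' Read / write recordings as delimited text
#'
#' The delimited layout is a tab-separated table with a header line of
#' channel labels; each subsequent line is one sample (columns = channels,
#' microvolts). The sampling rate is stored in a `# sampling_rate_hz:`
#' comment on the first line.
#'
#' @param path File path.
#' @param rec A `recording`.
#' @return `read_recording_tsv()` returns a `recording`;
#'   `write_recording_tsv()` returns `path` invisibly.
#' @export
write_recording_tsv <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz: %.10g", rec$sampling_rate), con)
  writeLines(paste(rec$channel_labels, collapse = "\t"), con)
  utils::write.table(t(rec$data), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording_tsv
#' @param subject_id,session_id Identity attached to the recording read.
#' @export
read_recording_tsv <- function(path, subject_id = NA_character_,
                               session_id = NA_character_) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("# *sampling_rate_hz: *([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2)
    stop("missing '# sampling_rate_hz:' header in ", path)
  fs <- as.numeric(m[2])
  tab <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                           check.names = FALSE)
  recording(t(as.matrix(tab)), colnames(tab), fs,
            subject_id = subject_id, session_id = session_id)
}
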