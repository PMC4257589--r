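#' Read and write EDF (European Data Format) recordings
#'
#' Minimal EDF support for continuous multichannel EEG: an ASCII header
#' followed by 16-bit little-endian integer data records. Recordings are
#' written with one-second data records, so the sampling rate must be a
#' whole number; a trailing partial second is dropped on write. Amplitudes
#' are scaled linearly between the per-channel physical range and the full
#' digital range, which quantizes the signal (relative error on the order
#' of range / 65536).
#'
#' @param rec A `recording`; potentials interpreted as microvolts.
#' @param path File path.
#' @return `read_edf()` returns a `recording`; `write_edf()` returns
#'   `path` invisibly.
#' @export
write_edf <- function(rec, path) {
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop("write_edf requires an integer sampling rate")
  nch <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  data <- rec$data[, seq_len(n_rec * fs), drop = FALSE]

  pmin <- apply(data, 1, min)
  pmax <- apply(data, 1, max)
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767

  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * nch
  writeChar(paste0(
    pad("0", 8),
    pad(substr(paste0("subject ", rec$subject_id), 1, 80), 80),
    pad(substr(paste0("session ", rec$session_id), 1, 80), 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(hdr_bytes, 8), pad("", 44), pad(n_rec, 8), pad("1", 8), pad(nch, 4)),
    con, eos = NULL)
  field <- function(vals, w) writeChar(paste(pad(vals, w), collapse = ""),
                                       con, eos = NULL)
  field(substr(rec$channel_labels, 1, 16), 16)
  field(rep("", nch), 80)                       # transducer
  field(rep("uV", nch), 8)                      # physical dimension
  field(sprintf("%.6g", pmin), 8)
  field(sprintf("%.6g", pmax), 8)
  field(rep(dmin, nch), 8)
  field(rep(dmax, nch), 8)
  field(rep("", nch), 80)                       # prefiltering
  field(rep(fs, nch), 8)                        # samples per record
  field(rep("", nch), 32)

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(n_rec)) {
    idx <- (r - 1L) * fs + seq_len(fs)
    for (ch in seq_len(nch)) {
      dig <- round((data[ch, idx] - pmin[ch]) * scale[ch] + dmin)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_edf
#' @param subject_id,session_id Identity attached to the recording read;
#'   defaults parse the free-text EDF identification fields written by
#'   `write_edf()`.
#' @export
read_edf <- function(path, subject_id = NULL, session_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ver <- rd(8)
  patient <- rd(80); rec_field <- rd(80)
  rd(8); rd(8)                                   # date, time
  rd(8)                                          # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  per <- function(w) vapply(seq_len(nch), function(i) rd(w), "")
  labels <- per(16)
  per(80); per(8)
  pmin <- as.numeric(per(8)); pmax <- as.numeric(per(8))
  dmin <- as.numeric(per(8)); dmax <- as.numeric(per(8))
  per(80)
  spr <- as.integer(per(8))
  per(32)
  if (length(unique(spr)) != 1L)
    stop("read_edf supports only uniform samples-per-record across channels")
  fs <- spr[1] / rec_dur
  out <- matrix(0, nch, n_rec * spr[1])
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nch)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2L,
                     endian = "little", signed = TRUE)
      out[ch, (r - 1L) * spr[1] + seq_len(spr[1])] <-
        (dig - dmin[ch]) * scale[ch] + pmin[ch]
    }
  }
  if (is.null(subject_id))
    subject_id <- sub("^subject ", "", patient)
  if (is.null(session_id))
    session_id <- sub("^session ", "", rec_field)
  recording(out, labels, fs, subject_id = subject_id, session_id = session_id)
}
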