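#' Zero-phase Butterworth filtering
#'
#' Band-pass and band-stop (notch) filters applied per channel with a
#' second-order IIR Butterworth design and forward-backward filtering
#' (zero phase shift). Filtering is applied within each epoch
#' independently, never across epoch boundaries.
#'
#' @param rec A `recording`.
#' @param low_hz,high_hz Pass-band (band-pass) or stop-band (notch) edges
#'   in Hz; both must lie strictly below the Nyquist frequency.
#' @param order Filter order (of the prototype; forward-backward doubles
#'   the effective order).
#' @return Filtered `recording`.
#' @export
bandpass_filter <- function(rec, low_hz, high_hz, order = 2) {
  .butter_apply(rec, low_hz, high_hz, order, type = "pass")
}

#' @rdname bandpass_filter
#' @param stop_low,stop_high Stop-band edges in Hz (default 55-65, the
#'   60 Hz mains band).
#' @export
notch_filter <- function(rec, stop_low = 55, stop_high = 65, order = 2) {
  .butter_apply(rec, stop_low, stop_high, order, type = "stop")
}

.butter_apply <- function(rec, lo, hi, order, type) {
  nyq <- rec$sampling_rate / 2
  if (!(0 < lo && lo < hi && hi < nyq))
    stop(sprintf("cutoffs must satisfy 0 < %g < %g < Nyquist (%g Hz)",
                 lo, hi, nyq))
  flt <- signal::butter(order, c(lo, hi) / nyq,
                        type = if (type == "pass") "pass" else "stop")
  .map_epochs(rec, function(x) {
    t(apply(x, 1, function(ch) signal::filtfilt(flt, ch)))
  })
}

#' Cut a recording into fixed-length epochs
#'
#' Divides each existing epoch into consecutive segments of `epoch_s`
#' seconds; a trailing partial segment is discarded. Epoch bookkeeping is
#' what keeps later stages (GFP peaks, microstate segments) from spanning
#' temporal discontinuities.
#'
#' @param rec A `recording`.
#' @param epoch_s Epoch length in seconds (default 2).
#' @return `recording` whose data holds only the complete epochs.
#' @export
epoch_recording <- function(rec, epoch_s = 2) {
  n_ep_samp <- round(epoch_s * rec$sampling_rate)
  pieces <- list()
  for (i in seq_len(nrow(rec$epochs))) {
    k <- as.integer(rec$epochs$n[i] %/% n_ep_samp)
    if (k < 1) next
    s0 <- rec$epochs$start[i]
    idx <- s0 + seq_len(k * n_ep_samp) - 1L
    pieces[[length(pieces) + 1L]] <- list(data = rec$data[, idx, drop = FALSE],
                                          k = k)
  }
  if (length(pieces) == 0)
    stop("no complete epoch of ", epoch_s, " s fits in the recording")
  data <- do.call(cbind, lapply(pieces, `[[`, "data"))
  k_tot <- sum(vapply(pieces, `[[`, 0L, "k"))
  recording(data, rec$channel_labels, rec$sampling_rate,
            subject_id = rec$subject_id, session_id = rec$session_id,
            epochs = data.frame(start = (seq_len(k_tot) - 1L) * n_ep_samp + 1L,
                                n = n_ep_samp))
}

#' Amplitude-threshold epoch rejection
#'
#' Deterministic artifact rule standing in for manual review: any epoch in
#' which any channel exceeds `abs_amplitude_uv` in absolute potential is
#' dropped. The number of dropped epochs is reported via `message()` and
#' attached as attribute `n_rejected`.
#'
#' @param rec An epoched `recording`.
#' @param abs_amplitude_uv Rejection threshold in microvolts (default 100).
#' @return `recording` containing the retained epochs only.
#' @export
reject_epochs <- function(rec, abs_amplitude_uv = 100) {
  keep <- logical(nrow(rec$epochs))
  for (i in seq_len(nrow(rec$epochs))) {
    idx <- rec$epochs$start[i] + seq_len(rec$epochs$n[i]) - 1L
    keep[i] <- max(abs(rec$data[, idx])) <= abs_amplitude_uv
  }
  n_drop <- sum(!keep)
  if (all(!keep)) stop("no data remaining after epoch rejection")
  if (n_drop > 0)
    message(sprintf("reject_epochs: dropped %d of %d epochs", n_drop, length(keep)))
  idx_keep <- unlist(lapply(which(keep), function(i)
    rec$epochs$start[i] + seq_len(rec$epochs$n[i]) - 1L))
  ep_n <- rec$epochs$n[keep]
  out <- recording(rec$data[, idx_keep, drop = FALSE], rec$channel_labels,
                   rec$sampling_rate, subject_id = rec$subject_id,
                   session_id = rec$session_id,
                   epochs = data.frame(start = cumsum(c(1L, ep_n[-length(ep_n)])),
                                       n = ep_n))
  attr(out, "n_rejected") <- n_drop
  out
}

#' Average re-referencing
#'
#' Subtracts the instantaneous mean across channels from every sample, so
#' the per-sample channel mean is zero. Idempotent.
#'
#' @param rec A `recording`.
#' @return Average-referenced `recording`.
#' @export
average_reference <- function(rec) {
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec
}

#' Downsample a recording
#'
#' Integer-factor decimation preceded by a zero-phase anti-alias low-pass
#' (4th-order Butterworth at 90% of the new Nyquist), applied per epoch.
#'
#' @param rec A `recording`.
#' @param target_hz New sampling rate; must divide the current rate.
#' @return Downsampled `recording`.
#' @export
downsample_recording <- function(rec, target_hz) {
  if (target_hz == rec$sampling_rate) return(rec)
  if (target_hz > rec$sampling_rate)
    stop("cannot upsample: target rate above current rate")
  fac <- rec$sampling_rate / target_hz
  if (abs(fac - round(fac)) > 1e-9)
    stop("target_hz must divide the sampling rate")
  fac <- round(fac)
  flt <- signal::butter(4, 0.9 / fac, type = "low")
  pieces <- list(); ep_n <- integer(0)
  for (i in seq_len(nrow(rec$epochs))) {
    idx <- rec$epochs$start[i] + seq_len(rec$epochs$n[i]) - 1L
    x <- t(apply(rec$data[, idx, drop = FALSE], 1,
                 function(ch) signal::filtfilt(flt, ch)))
    sel <- seq(1, ncol(x), by = fac)
    pieces[[i]] <- x[, sel, drop = FALSE]
    ep_n <- c(ep_n, length(sel))
  }
  recording(do.call(cbind, pieces), rec$channel_labels, target_hz,
            subject_id = rec$subject_id, session_id = rec$session_id,
            epochs = data.frame(start = cumsum(c(1L, ep_n[-length(ep_n)])),
                                n = ep_n))
}

#' Subset a recording to a smaller montage
#'
#' Keeps exactly the named channels (e.g. the standard 19- or 8-electrode
#' arrays) and re-average-references the result, since the average
#' reference is montage-dependent.
#'
#' @param rec A `recording`.
#' @param montage Montage name (`"ch30"`, `"ch19"`, `"ch8"`) or character
#'   vector of labels; all must be present in the recording.
#' @return Subsetted, re-referenced `recording`.
#' @export
subset_channels <- function(rec, montage) {
  labels <- montage_channels(montage)
  missing <- setdiff(labels, rec$channel_labels)
  if (length(missing) > 0)
    stop("channel(s) not in recording: ", paste(missing, collapse = ", "))
  rec$data <- rec$data[match(labels, rec$channel_labels), , drop = FALSE]
  rec$channel_labels <- labels
  average_reference(rec)
}

#' Band power of a recording
#'
#' Welch-style spectral estimate: a Hann-windowed periodogram per epoch
#' and channel, averaged over epochs and channels, then integrated over
#' the classical bands delta (1-3.5 Hz), theta (4-7 Hz), alpha (8-12 Hz)
#' and beta (12-30 Hz). Relative power uses total 1-30 Hz power as the
#' denominator.
#'
#' @param rec An epoched `recording`.
#' @param bands Named list of `c(low, high)` band edges in Hz.
#' @return data.frame with columns `band`, `low_hz`, `high_hz`,
#'   `absolute_power` (uV^2) and `relative_power`.
#' @export
band_power <- function(rec, bands = list(delta = c(1, 3.5), theta = c(4, 7),
                                         alpha = c(8, 12), beta = c(12, 30))) {
  n <- rec$epochs$n[1]
  if (length(unique(rec$epochs$n)) != 1)
    stop("band_power expects equal-length epochs; run epoch_recording() first")
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))  # Hann
  wnorm <- sum(w^2)
  freqs <- (seq_len(n %/% 2 + 1) - 1) * rec$sampling_rate / n
  psd <- numeric(length(freqs))
  for (i in seq_len(nrow(rec$epochs))) {
    idx <- rec$epochs$start[i] + seq_len(n) - 1L
    x <- rec$data[, idx, drop = FALSE]
    x <- x - rowMeans(x)
    spec <- Mod(t(stats::mvfft(t(x * rep(w, each = nrow(x))))))^2
    p <- colMeans(spec)[seq_along(freqs)] / (wnorm * rec$sampling_rate)
    p[-1] <- 2 * p[-1]
    psd <- psd + p
  }
  psd <- psd / nrow(rec$epochs)
  df <- rec$sampling_rate / n
  integrate_band <- function(b) sum(psd[freqs >= b[1] & freqs <= b[2]]) * df
  absol <- vapply(bands, integrate_band, 0)
  total <- integrate_band(c(1, 30))
  data.frame(band = names(bands),
             low_hz = vapply(bands, `[`, 0, 1),
             high_hz = vapply(bands, `[`, 0, 2),
             absolute_power = unname(absol),
             relative_power = unname(if (total > 0) absol / total else absol * 0))
}

#' Full preprocessing chain
#'
#' Applies, in order: notch (55-65 Hz), 1-50 Hz band-pass, epoching,
#' amplitude-threshold epoch rejection, average re-referencing, optional
#' downsampling, and a final 1-30 Hz band-pass — the conditioning chain a
#' microstate analysis expects. Band powers, when requested, are computed
#' on the 1-50 Hz data before the final 1-30 Hz filter.
#'
#' @param rec Raw `recording`.
#' @param epoch_s Epoch length, s.
#' @param reject_uv Epoch rejection threshold, uV (NULL disables).
#' @param target_hz Analysis sampling rate (NULL keeps the input rate).
#' @param notch Length-2 stop band in Hz, or NULL to skip (e.g. for data
#'   sampled too low to contain mains noise).
#' @param final_band Length-2 pass band for the final filter.
#' @param compute_band_power Also return the band-power table?
#' @return A `recording`, with attribute `band_power` if requested.
#' @export
preprocess_recording <- function(rec, epoch_s = 2, reject_uv = 100,
                                 target_hz = 200, notch = c(55, 65),
                                 final_band = c(1, 30),
                                 compute_band_power = FALSE) {
  if (!is.null(notch) && notch[2] < rec$sampling_rate / 2)
    rec <- notch_filter(rec, notch[1], notch[2])
  if (rec$sampling_rate / 2 > 50) rec <- bandpass_filter(rec, 1, 50)
  rec <- epoch_recording(rec, epoch_s)
  if (!is.null(reject_uv)) rec <- reject_epochs(rec, reject_uv)
  rec <- average_reference(rec)
  bp <- if (compute_band_power) band_power(rec) else NULL
  if (!is.null(target_hz) && target_hz != rec$sampling_rate)
    rec <- downsample_recording(rec, target_hz)
  rec <- bandpass_filter(rec, final_band[1], final_band[2])
  rec <- average_reference(rec)
  if (!is.null(bp)) attr(rec, "band_power") <- bp
  rec
}
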