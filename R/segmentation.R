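#' Back-fit microstate maps onto GFP-peak maps
#'
#' Labels every original map (GFP-peak topography) with the class of the
#' template it correlates with most strongly in absolute value (polarity
#' never matters at rest). Ties break in label order.
#'
#' @param ps A `peakset`.
#' @param ms A `mapset` on the same montage.
#' @return A `microstate_sequence`: data.frame with one row per peak
#'   (`time_ms`, `epoch`, `class`, `correlation`) carrying the peakset's
#'   timing metadata as attributes.
#' @export
backfit <- function(ps, ms) {
  if (nrow(ps$maps) == 0) stop("empty peak set")
  if (!identical(ps$channel_labels, ms$channel_labels) &&
      ncol(ps$maps) != ncol(ms$maps))
    stop("peakset and mapset montages differ")
  C <- abs(.gfp_normalize_rows(ps$maps) %*% t(ms$maps)) / ncol(ps$maps)
  win <- max.col(C, ties.method = "first")   # label order A < B < C < D
  seq_df <- data.frame(time_ms = ps$time_ms, epoch = ps$epoch,
                       class = ms$labels[win],
                       correlation = C[cbind(seq_len(nrow(C)), win)],
                       stringsAsFactors = FALSE)
  attr(seq_df, "epoch_durations_ms") <- ps$epoch_durations_ms
  attr(seq_df, "total_time_s") <- ps$total_time_s
  attr(seq_df, "subject_id") <- ps$subject_id
  attr(seq_df, "session_id") <- ps$session_id
  attr(seq_df, "classes") <- ms$labels
  class(seq_df) <- c("microstate_sequence", "data.frame")
  seq_df
}

#' Build microstate segments from a labeled peak sequence
#'
#' Within each epoch, runs of consecutive same-class peaks become
#' segments. Interior boundaries sit at the temporal midpoint between the
#' last peak of one run and the first peak of the next; the first segment
#' starts at the epoch start and the last ends at the epoch end, both
#' flagged `truncated` (they are cut by the epoch boundary, so their
#' observed lifespan underestimates the underlying dwell).
#'
#' @param seq_df A `microstate_sequence` from [backfit()].
#' @return data.frame with `epoch`, `class`, `onset_ms`, `offset_ms`,
#'   `lifespan_ms`, `truncated`; attribute `total_time_s` retained.
#' @export
build_segments <- function(seq_df) {
  ep_dur <- attr(seq_df, "epoch_durations_ms")
  ep_end <- cumsum(ep_dur)
  ep_start <- c(0, ep_end[-length(ep_end)])
  out <- list()
  for (e in unique(seq_df$epoch)) {
    d <- seq_df[seq_df$epoch == e, ]
    if (nrow(d) == 0) next
    r <- rle(d$class)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1
    n_run <- length(r$values)
    onset <- numeric(n_run); offset <- numeric(n_run)
    for (i in seq_len(n_run)) {
      onset[i] <- if (i == 1) ep_start[e] else
        (d$time_ms[ends_idx[i - 1]] + d$time_ms[starts_idx[i]]) / 2
      offset[i] <- if (i == n_run) ep_end[e] else
        (d$time_ms[ends_idx[i]] + d$time_ms[starts_idx[i + 1]]) / 2
    }
    out[[length(out) + 1]] <- data.frame(
      epoch = e, class = r$values, onset_ms = onset, offset_ms = offset,
      lifespan_ms = offset - onset,
      truncated = seq_len(n_run) %in% c(1L, n_run),
      stringsAsFactors = FALSE)
  }
  segs <- do.call(rbind, out)
  attr(segs, "total_time_s") <- attr(seq_df, "total_time_s")
  attr(segs, "classes") <- attr(seq_df, "classes")
  attr(segs, "subject_id") <- attr(seq_df, "subject_id")
  attr(segs, "session_id") <- attr(seq_df, "session_id")
  segs
}

#' Extract microstate features from segments
#'
#' Per class: mean lifespan (ms) over that class's segments, frequency of
#' appearance (segments per second of retained recording), and coverage
#' (summed lifespans over total time). The `All` row gives the mean
#' lifespan over all segments, the total appearance rate, and coverage 1.
#' Epoch-truncated segments are included, which keeps the identity
#' coverage = frequency x mean lifespan(s) exact. A class that never
#' appears gets lifespan `NA` and frequency/coverage 0.
#'
#' @param segs Segment table from [build_segments()].
#' @param classes Class labels to report (defaults to the mapset's).
#' @param total_time_s Total retained recording time in seconds (defaults
#'   to the value carried by `segs`).
#' @return data.frame with `class`, `mean_lifespan` (ms), `frequency`
#'   (1/s), `coverage`.
#' @export
extract_features <- function(segs, classes = attr(segs, "classes"),
                             total_time_s = attr(segs, "total_time_s")) {
  if (is.null(classes)) classes <- sort(unique(segs$class))
  total_ms <- total_time_s * 1000
  rows <- lapply(classes, function(k) {
    d <- segs[segs$class == k, ]
    if (nrow(d) == 0)
      return(data.frame(class = k, mean_lifespan = NA_real_,
                        frequency = 0, coverage = 0))
    data.frame(class = k, mean_lifespan = mean(d$lifespan_ms),
               frequency = nrow(d) / total_time_s,
               coverage = sum(d$lifespan_ms) / total_ms)
  })
  all_row <- data.frame(class = "All",
                        mean_lifespan = mean(segs$lifespan_ms),
                        frequency = nrow(segs) / total_time_s,
                        coverage = sum(segs$lifespan_ms) / total_ms)
  do.call(rbind, c(rows, list(all_row)))
}

#' Features of one recording under one map set
#'
#' Convenience wrapper: back-fit, build segments, extract features, and
#' prepend identity columns.
#'
#' @param ps A `peakset`.
#' @param ms A `mapset`.
#' @return Feature data.frame with `subject`, `session`, `class`,
#'   `mean_lifespan`, `frequency`, `coverage`, `gev` (GEV of the back-fit
#'   on this recording's peaks).
#' @export
microstate_features <- function(ps, ms) {
  seq_df <- backfit(ps, ms)
  feats <- extract_features(build_segments(seq_df))
  cbind(data.frame(subject = ps$subject_id, session = ps$session_id),
        feats, gev = gev(ps, ms))
}
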