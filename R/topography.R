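#' Global field power
#'
#' The global field power (GFP) of a scalp topography is the root mean
#' square of the average-referenced potentials — equivalently the spatial
#' standard deviation (population form, divisor n) across electrodes:
#' \deqn{GFP = \sqrt{\frac{1}{n}\sum_i (v_i - \bar v)^2}}
#' Moments of high GFP carry the highest topographic signal-to-noise ratio,
#' which is why microstate analysis samples topographies at GFP peaks.
#'
#' @param v Numeric vector: potential at each electrode (one topography).
#' @return Non-negative scalar.
#' @examples
#' gfp(c(1, -1))        # 1
#' gfp(c(3, -1, -1, -1))  # sqrt(3)
#' @export
gfp <- function(v) {
  if (length(v) < 2) stop("a topography needs at least 2 electrodes")
  v <- v - mean(v)
  sqrt(sum(v^2) / length(v))
}

#' GFP time series of a recording
#'
#' @param rec A `recording`.
#' @return Numeric vector, one GFP value per sample.
#' @export
gfp_series <- function(rec) {
  x <- rec$data
  x <- sweep(x, 2, colMeans(x))
  sqrt(colMeans(x^2))
}

#' Extract topographies at GFP peaks ("original maps")
#'
#' Finds local maxima of the GFP curve — samples with GFP strictly higher
#' than both the preceding and the following sample — independently within
#' each epoch, and collects the topography at each peak. Epoch-edge samples
#' are never peaks, and plateaus (ties) emit none.
#'
#' @param rec A `recording` (average-referenced).
#' @return A `peakset`: list with `maps` (peaks x channels matrix),
#'   `sample_index`, `time_ms`, `gfp`, `epoch`, plus montage and provenance
#'   fields. `time_ms` is relative to the concatenated retained data (epoch
#'   durations accumulate), so segment durations can be computed on it.
#' @export
find_gfp_peaks <- function(rec) {
  g <- gfp_series(rec)
  idx <- integer(0); ep <- integer(0)
  offset_ms <- 0
  time_ms <- numeric(0)
  dt_ms <- 1000 / rec$sampling_rate
  for (i in seq_len(nrow(rec$epochs))) {
    s <- rec$epochs$start[i]; n <- rec$epochs$n[i]
    if (n < 3) next
    ge <- g[s + seq_len(n) - 1L]
    core <- 2:(n - 1)
    is_peak <- ge[core] > ge[core - 1] & ge[core] > ge[core + 1]
    pk <- core[is_peak]
    idx <- c(idx, s + pk - 1L)
    ep <- c(ep, rep.int(i, length(pk)))
    time_ms <- c(time_ms, offset_ms + (pk - 1) * dt_ms)
    offset_ms <- offset_ms + n * dt_ms
  }
  structure(
    list(maps = t(rec$data[, idx, drop = FALSE]),
         sample_index = idx, time_ms = time_ms, gfp = g[idx],
         epoch = ep,
         epoch_durations_ms = rec$epochs$n * dt_ms,
         channel_labels = rec$channel_labels,
         sampling_rate = rec$sampling_rate,
         subject_id = rec$subject_id, session_id = rec$session_id,
         total_time_s = recording_duration(rec)),
    class = "peakset")
}

#' @export
print.peakset <- function(x, ...) {
  cat(sprintf("<peakset> %d GFP-peak maps, %d channels, %.1f s of data\n",
              nrow(x$maps), ncol(x$maps), x$total_time_s))
  invisible(x)
}

#' Export a peakset as a data.frame
#'
#' One row per GFP peak: identity, sample index, time, GFP, then one column
#' per electrode.
#'
#' @param ps A `peakset`.
#' @return data.frame.
#' @export
peakset_table <- function(ps) {
  cbind(data.frame(recording_id = paste(ps$subject_id, ps$session_id, sep = "_"),
                   sample_index = ps$sample_index,
                   time_ms = ps$time_ms, gfp = ps$gfp, epoch = ps$epoch),
        as.data.frame(ps$maps))
}

#' Spatial correlation between two topographies
#'
#' Pearson product-moment correlation across electrodes. For
#' average-referenced maps this equals the cosine between the two potential
#' vectors. `abs_correlation()` is its absolute value, the
#' polarity-invariant similarity used for all resting-state clustering and
#' back-fitting (maps of opposite polarity are the same microstate).
#'
#' @param u,v Numeric vectors over the same montage.
#' @return Scalar in `[-1, 1]` (`[0, 1]` for `abs_correlation`).
#' @export
spatial_correlation <- function(u, v) {
  if (length(u) != length(v)) stop("topographies are on different montages")
  u <- u - mean(u); v <- v - mean(v)
  du <- sqrt(sum(u^2)); dv <- sqrt(sum(v^2))
  if (du == 0 || dv == 0) stop("spatial correlation undefined for a constant map")
  sum(u * v) / (du * dv)
}

#' @rdname spatial_correlation
#' @export
abs_correlation <- function(u, v) abs(spatial_correlation(u, v))

#' Normalize a topography to unit GFP
#'
#' Centers the map across electrodes and scales it so its GFP is 1.
#'
#' @param v Numeric vector (one topography).
#' @return Zero-mean map with GFP 1.
#' @export
gfp_normalize <- function(v) {
  v <- v - mean(v)
  g <- sqrt(sum(v^2) / length(v))
  if (g == 0) stop("cannot GFP-normalize a constant map")
  v / g
}

#' Global map dissimilarity
#'
#' Root-mean-square difference between two GFP-normalized maps:
#' 0 for identical maps, 2 for antipodal ones. Satisfies
#' \eqn{GMD = \sqrt{2(1 - C)}} with \eqn{C} the spatial correlation.
#'
#' @param u,v GFP-normalized topographies (checked to tolerance `tol`).
#' @param tol Tolerance on the unit-GFP check.
#' @return Scalar in `[0, 2]`.
#' @export
gmd <- function(u, v, tol = 1e-6) {
  if (length(u) != length(v)) stop("topographies are on different montages")
  gu <- gfp(u); gv <- gfp(v)
  if (abs(gu - 1) > tol || abs(gv - 1) > tol)
    stop("gmd() expects GFP-normalized maps; call gfp_normalize() first")
  u <- u - mean(u); v <- v - mean(v)
  sqrt(sum((u - v)^2) / length(u))
}

# --- internal matrix helpers used by clustering/backfitting ---------------

# Row-center then L2-normalize each row of a maps matrix (rows = maps).
# For centered rows, the dot product of normalized rows is the spatial
# correlation, which lets correlation batches run as one matrix product.
.normalize_rows <- function(m) {
  m <- m - rowMeans(m)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("constant map encountered")
  m / nrm
}

# correlation matrix between rows of a (maps) and rows of b (templates)
.corr_matrix <- function(a, b) {
  .normalize_rows(a) %*% t(.normalize_rows(b))
}
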