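# Independent oracles and fixtures shared across the test files.

# All partitions of 1..m into exactly K unlabeled non-empty blocks.
all_partitions <- function(m, K) {
  out <- list()
  rec <- function(i, blocks) {
    if (i > m) {
      if (length(blocks) == K) out[[length(out) + 1]] <<- blocks
      return(invisible())
    }
    for (b in seq_along(blocks)) {
      nb <- blocks
      nb[[b]] <- c(nb[[b]], i)
      rec(i + 1, nb)
    }
    if (length(blocks) < K) rec(i + 1, c(blocks, list(i)))
  }
  rec(2, list(1L))
  out
}

# Brute-force best GEV over every partition into K clusters, with the
# cluster template defined as the normalized sign-aligned average of the
# members (signs enumerated exhaustively). Independent of the clustering
# code path.
gev_exhaustive <- function(X, K) {
  w <- apply(X, 1, function(v) stats::sd(v) * sqrt((length(v) - 1) / length(v)))
  Xc <- X - rowMeans(X)
  Xn <- Xc / sqrt(rowSums(Xc^2))
  best <- -Inf
  for (p in all_partitions(nrow(X), K)) {
    tot <- 0
    for (blk in p) {
      r <- length(blk)
      signs_grid <- as.matrix(expand.grid(rep(list(c(1, -1)), r)))
      bbest <- -Inf
      for (si in seq_len(nrow(signs_grid))) {
        tm <- colMeans(Xn[blk, , drop = FALSE] * signs_grid[si, ])
        if (sum(tm^2) < 1e-18) next
        cs <- abs(Xn[blk, , drop = FALSE] %*% tm) / sqrt(sum(tm^2))
        bbest <- max(bbest, sum((w[blk] * cs)^2))
      }
      tot <- tot + bbest
    }
    best <- max(best, tot)
  }
  best / sum(w^2)
}

# ICC(3,k) via an independent ANOVA decomposition (stats::aov)
icc3k_aov <- function(m) {
  d <- data.frame(y = as.numeric(m),
                  s = factor(rep(seq_len(nrow(m)), ncol(m))),
                  t = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  av <- stats::anova(stats::aov(y ~ s + t, data = d))
  (av["s", "Mean Sq"] - av["Residuals", "Mean Sq"]) / av["s", "Mean Sq"]
}

# Fixture: each of the four canonical templates duplicated with small
# perturbations -- clustering must recover the templates.
separated_maps_fixture <- function(n_per = 10, noise = 0.02, seed = 42,
                                   montage = "ch30") {
  tm <- make_template_maps(montage, seed = 1)
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(tm)), function(k) {
    t(replicate(n_per, tm[k, ] * sample(c(-1, 1), 1) +
                  noise * rnorm(ncol(tm))))
  }))
  list(maps = X, templates = tm,
       truth = rep(seq_len(nrow(tm)), each = n_per))
}

# A tiny peakset built directly (no signal chain) for segmentation tests
manual_peakset <- function(times_ms, classes, templates, epoch_ms = NULL,
                           epoch = rep(1L, length(times_ms))) {
  if (is.null(epoch_ms)) epoch_ms <- max(times_ms) + 10
  maps <- templates[match(classes, rownames(templates)), , drop = FALSE]
  structure(list(maps = maps, sample_index = seq_along(times_ms),
                 time_ms = times_ms, gfp = rep(1, length(times_ms)),
                 epoch = epoch, epoch_durations_ms = epoch_ms,
                 channel_labels = colnames(templates), sampling_rate = 1000,
                 subject_id = "S1", session_id = "T1",
                 total_time_s = sum(epoch_ms) / 1000),
            class = "peakset")
}

# Sine-wave recording helper
sine_recording <- function(freq_hz, fs = 1000, dur_s = 4, n_ch = 4,
                           amplitude = 10) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  base <- amplitude * sin(2 * pi * freq_hz * t)
  data <- t(sapply(seq_len(n_ch), function(i) base * (1 + 0.1 * i)))
  recording(data, paste0("ch", seq_len(n_ch)), fs)
}

rms <- function(x) sqrt(mean(x^2))
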