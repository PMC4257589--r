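#' Configuration for the synthetic microstate study
#'
#' Bundles every knob of the synthetic-EEG generator. The defaults emulate
#' the resting-state eyes-closed design the package is validated against:
#' 10 subjects x 3 sessions, 30 channels, 120 s per recording at 200 Hz, an
#' alpha-band (10 Hz) oscillatory carrier, mean microstate dwell time
#' 100 ms (centre of the canonical 80-120 ms range) with 10 ms
#' between-subject SD, and a signal-to-noise power ratio of 2.
#'
#' @param n_subjects,n_sessions Study dimensions.
#' @param montage `"ch30"`, `"ch19"` or `"ch8"`.
#' @param sampling_rate Hz.
#' @param record_length Seconds per recording.
#' @param mean_duration Population mean microstate dwell time, ms.
#' @param duration_bs_sd Between-subject SD of the subject-level mean dwell
#'   time, ms. Subjects receive a multiplicative duration factor shared
#'   across their sessions; this is what gives microstate features genuine
#'   test-retest reliability.
#' @param duration_shape Gamma shape of the dwell-time distribution.
#' @param min_duration Truncation floor on dwell times, ms.
#' @param carrier_frequency Oscillatory carrier frequency, Hz.
#' @param snr Ratio of template signal power to noise power (may be `Inf`
#'   for noiseless data).
#' @param amplitude Carrier amplitude in microvolts (scale only).
#' @param syntax_matrix 4x4 class transition probability matrix; rows must
#'   sum to 1 with a zero diagonal. Default: uniform off-diagonal.
#' @param noise_smoothness Length scale (head-radius units) of the Gaussian
#'   spatial kernel applied to channel noise.
#' @param seed Integer master seed.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 10, n_sessions = 3, montage = "ch30",
                         sampling_rate = 200, record_length = 120,
                         mean_duration = 100, duration_bs_sd = 10,
                         duration_shape = 4, min_duration = 30,
                         carrier_frequency = 10, snr = 2, amplitude = 10,
                         syntax_matrix = NULL, noise_smoothness = 0.45,
                         seed = 1) {
  if (is.null(syntax_matrix)) {
    syntax_matrix <- matrix(1 / 3, 4, 4)
    diag(syntax_matrix) <- 0
  }
  if (any(diag(syntax_matrix) != 0) ||
      any(abs(rowSums(syntax_matrix) - 1) > 1e-9))
    stop("syntax_matrix rows must sum to 1 with zero diagonal")
  if (snr <= 0) stop("snr must be positive")
  if (record_length * 1000 < min_duration)
    stop("record_length too short for a single dwell segment")
  structure(as.list(environment()), class = "synth_config")
}

#' Generate four synthetic microstate template topographies
#'
#' Builds four smooth, zero-mean, unit-GFP scalp maps qualitatively
#' matching the four canonical resting-state microstate classes: A
#' (left-posterior to right-anterior gradient), B (right-posterior to
#' left-anterior), C (posterior-anterior), D (fronto-central focal). A
#' small seeded spatially-smooth perturbation makes distinct seeds give
#' distinct (but still canonical) maps; pairwise absolute spatial
#' correlations stay below 0.7.
#'
#' @param montage Montage name or channel-label vector.
#' @param seed Integer seed for the perturbation.
#' @param jitter Relative amplitude of the smooth perturbation.
#' @return 4 x channels matrix with rownames `A`-`D` and channel colnames.
#' @export
make_template_maps <- function(montage = "ch30", seed = 1, jitter = 0.15) {
  coords <- montage_coordinates(montage)
  x <- coords$x; y <- coords$y
  base <- rbind(
    A = 0.8 * x + 0.6 * y,
    B = -0.8 * x + 0.6 * y,
    C = y,
    D = exp(-((x^2 + (y - 0.25)^2) / 0.35))
  )
  rng <- .new_rng(seed)
  K <- exp(-(.montage_distances(coords$label)^2) / (2 * 0.3^2))
  maps <- base
  for (k in 1:4) {
    noise <- as.numeric(K %*% rng$norm(length(x)))
    noise <- noise / max(stats::sd(noise), 1e-12)
    maps[k, ] <- gfp_normalize(gfp_normalize(base[k, ]) + jitter *
                                 (noise - mean(noise)))
  }
  maps <- .decorrelate(maps)
  colnames(maps) <- coords$label
  maps
}

# Cap pairwise |spatial correlation| of template maps. On sparse montages
# the canonical gradients can overlap strongly (the posterior-anterior and
# fronto-central patterns are barely distinguishable on 8 electrodes);
# partialling the shared component out of the later map restores
# separation while preserving smoothness. Deterministic.
.decorrelate <- function(maps, cmax = 0.6, target = 0.55, max_pass = 25) {
  n <- ncol(maps)
  for (pass in seq_len(max_pass)) {
    maps <- .gfp_normalize_rows(maps)
    C <- maps %*% t(maps) / n
    off <- abs(C); diag(off) <- 0
    if (max(off) <= cmax) break
    for (k in 2:nrow(maps)) for (j in seq_len(k - 1)) {
      c_kj <- sum(maps[k, ] * maps[j, ]) / n
      if (abs(c_kj) > cmax) {
        maps[k, ] <- gfp_normalize(maps[k, ] -
                                     (c_kj - sign(c_kj) * target) * maps[j, ])
      }
    }
  }
  maps
}

#' Generate one synthetic recording with microstate ground truth
#'
#' The generative model: a first-order Markov chain over the four classes
#' emits dwell segments whose durations follow a truncated Gamma
#' distribution with subject-specific mean; within a segment the class
#' template is amplitude-modulated by a sinusoidal carrier with random
#' phase (so polarity inverts every half-cycle); spatially smooth Gaussian
#' noise is added at the configured signal-to-noise power ratio; the result
#' is average-referenced.
#'
#' @param templates 4 x channels template matrix (e.g.
#'   [make_template_maps()]).
#' @param config A [synth_config()].
#' @param subject_id,session_id Identity strings.
#' @param duration_factor Subject-level multiplicative dwell-time factor.
#' @param seed Integer seed for this recording.
#' @return List with `recording` (a `recording`) and `truth` (a list:
#'   `segments` data.frame with `onset_ms`, `duration_ms`, `class`;
#'   `templates`; `duration_factor`; `seed`).
#' @export
generate_recording <- function(templates, config, subject_id = "S1",
                               session_id = "T1", duration_factor = 1,
                               seed = config$seed) {
  rng <- .new_rng(seed)
  fs <- config$sampling_rate
  n_samples <- round(config$record_length * fs)
  total_ms <- n_samples * 1000 / fs
  mean_dur <- config$mean_duration * duration_factor
  shape <- config$duration_shape

  # dwell segments: truncated Gamma durations, Markov class sequence
  durations <- numeric(0); classes <- integer(0)
  cls <- rng$sample_int(4)
  acc <- 0
  while (acc < total_ms) {
    d <- rng$gamma(shape, scale = mean_dur / shape)
    while (d < config$min_duration)
      d <- rng$gamma(shape, scale = mean_dur / shape)
    d <- min(d, total_ms - acc)
    durations <- c(durations, d); classes <- c(classes, cls)
    acc <- acc + d
    cls <- rng$sample_int(4, prob = config$syntax_matrix[cls, ])
  }
  onsets <- cumsum(c(0, durations[-length(durations)]))

  # carrier signal: template x sinusoid, random phase per segment
  nch <- ncol(templates)
  sig <- matrix(0, nch, n_samples)
  t_s <- (seq_len(n_samples) - 1) / fs
  seg_of_sample <- findInterval(t_s * 1000, onsets)
  phases <- rng$unif(length(durations), 0, 2 * pi)
  carrier <- config$amplitude *
    sin(2 * pi * config$carrier_frequency * t_s + phases[seg_of_sample])
  for (k in seq_len(nrow(templates))) {
    in_k <- classes[seg_of_sample] == k
    if (any(in_k)) sig[, in_k] <- outer(templates[k, ], carrier[in_k])
  }

  if (is.finite(config$snr)) {
    K <- exp(-(.montage_distances(colnames(templates))^2) /
               (2 * config$noise_smoothness^2))
    noise <- K %*% matrix(rng$norm(nch * n_samples), nch, n_samples)
    noise <- sweep(noise, 2, colMeans(noise))
    noise <- noise * sqrt(mean(sig^2) / (config$snr * mean(noise^2)))
    sig <- sig + noise
  }
  sig <- sweep(sig, 2, colMeans(sig))

  rec <- recording(sig, colnames(templates), fs,
                   subject_id = subject_id, session_id = session_id)
  truth <- list(
    segments = data.frame(onset_ms = onsets, duration_ms = durations,
                          class = rownames(templates)[classes]),
    templates = templates, duration_factor = duration_factor, seed = seed)
  list(recording = rec, truth = truth)
}

#' Generate a full synthetic study
#'
#' Draws one dwell-time factor per subject (shared across that subject's
#' sessions — the source of between-subject variance that test-retest
#' reliability measures) and generates every subject x session recording.
#' Deterministic under the config seed: each recording gets its own seed
#' derived from the master seed by a fixed counter scheme.
#'
#' @param config A [synth_config()].
#' @param templates Optional template matrix; defaults to
#'   [make_template_maps()] on the config montage and seed.
#' @return List of class `synth_study` with `recordings` (list of
#'   `recording`), `truths` (parallel list), `templates`, `config`,
#'   `subject_factors`.
#' @export
generate_study <- function(config = synth_config(), templates = NULL) {
  if (is.null(templates))
    templates <- make_template_maps(config$montage, seed = config$seed)
  rng <- .new_rng(config$seed * 7919 + 1)
  factors <- 1 + rng$norm(config$n_subjects) *
    config$duration_bs_sd / config$mean_duration
  factors <- pmax(factors, 0.3)
  recordings <- list(); truths <- list()
  i <- 0
  for (s in seq_len(config$n_subjects)) {
    for (ses in seq_len(config$n_sessions)) {
      i <- i + 1
      seed_i <- (config$seed %% 100000L) * 10000 + s * 100 + ses
      g <- generate_recording(templates, config,
                              subject_id = sprintf("S%02d", s),
                              session_id = sprintf("T%d", ses),
                              duration_factor = factors[s], seed = seed_i)
      recordings[[i]] <- g$recording
      truths[[i]] <- g$truth
    }
  }
  structure(list(recordings = recordings, truths = truths,
                 templates = templates, config = config,
                 subject_factors = factors),
            class = "synth_study")
}

#' @export
print.synth_study <- function(x, ...) {
  cat(sprintf("<synth_study> %d subjects x %d sessions, %s montage, %g s @ %g Hz\n",
              x$config$n_subjects, x$config$n_sessions, x$config$montage,
              x$config$record_length, x$config$sampling_rate))
  invisible(x)
}

#' Write a ground-truth segment table
#'
#' @param truth A `truth` element from [generate_recording()].
#' @param path File path for the tab-separated table
#'   (`onset_ms`, `duration_ms`, `class`).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth$segments, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# Self-contained RNG stream (local to the generator, never touches the
# global .Random.seed) so study generation composes deterministically.
.new_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  assign("state", local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed %% .Machine$integer.max))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  }), envir = env)
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", get("state", env), envir = globalenv())
    out <- f()
    assign("state", get(".Random.seed", globalenv()), envir = env)
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(
    norm = function(n) with_state(function() stats::rnorm(n)),
    unif = function(n, min = 0, max = 1)
      with_state(function() stats::runif(n, min, max)),
    gamma = function(shape, scale)
      with_state(function() stats::rgamma(1, shape = shape, scale = scale)),
    sample_int = function(n, prob = NULL)
      with_state(function() sample.int(n, 1L, prob = prob)),
    sample_k = function(n, k)
      with_state(function() sample.int(n, k))
  )
}
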