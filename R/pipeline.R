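#' Study configuration
#'
#' Collects every choice of a full microstate reliability analysis: the
#' data source (synthetic by default), the montage / derivation-strategy /
#' clustering-algorithm grid, clustering and TANOVA effort, preprocessing
#' parameters, and the master seed. The `"full"` profile uses 300 k-means
#' restarts and 5000 TANOVA permutations; the default `"desk"` profile
#' reduces them to 50 and 1000, which leaves results essentially unchanged
#' on the synthetic study while keeping a complete run at desk scale.
#'
#' @param synth A [synth_config()] describing the synthetic study (used
#'   when `recordings` is NULL).
#' @param recordings Optional list of `recording` objects to analyze
#'   instead of synthetic data.
#' @param montages Subset of `c("ch30", "ch19", "ch8")`.
#' @param strategies Subset of `c("global", "by_session", "by_recording")`.
#' @param algorithms Subset of `c("taahc", "kmeans")`.
#' @param K Number of microstate classes (fixed a priori at 4).
#' @param profile `"desk"` or `"full"`.
#' @param restarts,tanova_permutations Override the profile values.
#' @param reject_uv Epoch-rejection threshold, microvolts.
#' @param epoch_s Epoch length, seconds.
#' @param seed Master seed; per-stage seeds are derived from it by a fixed
#'   counter scheme so stages can be rerun independently.
#' @return List of class `study_config`.
#' @export
study_config <- function(synth = synth_config(), recordings = NULL,
                         montages = "ch30", strategies = "global",
                         algorithms = c("taahc", "kmeans"), K = 4,
                         profile = c("desk", "full"),
                         restarts = NULL, tanova_permutations = NULL,
                         reject_uv = 100, epoch_s = 2, seed = 1) {
  profile <- match.arg(profile)
  if (is.null(restarts)) restarts <- if (profile == "full") 300 else 50
  if (is.null(tanova_permutations))
    tanova_permutations <- if (profile == "full") 5000 else 1000
  stopifnot(length(montages) > 0, length(strategies) > 0,
            length(algorithms) > 0, K >= 2)
  structure(as.list(environment()), class = "study_config")
}

#' Load a study configuration from a YAML file
#'
#' Top-level keys map to [study_config()] arguments; the `synth` block
#' maps to [synth_config()]. Keys not present keep their defaults.
#'
#' @param path Path to a YAML configuration file.
#' @return A `study_config`.
#' @export
study_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  synth_args <- raw$synth
  raw$synth <- NULL
  args <- raw[names(raw) %in% names(formals(study_config))]
  if (!is.null(synth_args))
    args$synth <- do.call(synth_config,
                          synth_args[names(synth_args) %in%
                                       names(formals(synth_config))])
  do.call(study_config, args)
}

# stage seeds derived from the master seed (kept below 2^31)
.stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 131071 + stage * 8191) %% 2147483647
}

#' Run the full microstate reliability study
#'
#' Executes, for every montage x algorithm x strategy combination:
#' preprocessing, GFP-peak extraction, two-level map derivation,
#' back-fitting, feature extraction, and the test-retest reliability
#' report. When both algorithms are run with the global strategy it adds
#' the TAAHC-vs-k-means consistency table and per-class TANOVA tests;
#' when several montages are run it adds the cross-montage consistency
#' table. Per-recording band powers and the feature-vs-power regression
#' are computed on the primary montage. Deterministic under the config
#' seed.
#'
#' @param config A [study_config()].
#' @param verbose Emit progress messages?
#' @return List of class `study_report` with elements `features` (long
#'   table over all combinations), `reliability`, `consistency_algorithms`,
#'   `consistency_montages`, `tanova`, `feature_correlations`,
#'   `power_regression`, `band_power`, `mapsets`, `manifest`, `config`.
#' @export
run_study <- function(config = study_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  # ---- data ----
  if (is.null(config$recordings)) {
    say("generating synthetic study (seed %d)", config$synth$seed)
    study <- generate_study(config$synth)
    recs <- study$recordings
  } else {
    study <- NULL
    recs <- config$recordings
  }
  # ---- preprocessing ----
  say("preprocessing %d recordings", length(recs))
  band_rows <- list()
  pre <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    r <- preprocess_recording(recs[[i]], epoch_s = config$epoch_s,
                              reject_uv = config$reject_uv,
                              target_hz = NULL, compute_band_power = TRUE)
    bp <- attr(r, "band_power")
    band_rows[[i]] <- cbind(data.frame(subject = r$subject_id,
                                       session = r$session_id), bp)
    pre[[i]] <- r
  }
  band_power_tab <- do.call(rbind, band_rows)
  manifest <- data.frame(
    subject = vapply(pre, `[[`, "", "subject_id"),
    session = vapply(pre, `[[`, "", "session_id"),
    duration_s = vapply(pre, recording_duration, 0),
    n_epochs = vapply(pre, function(r) nrow(r$epochs), 0L))

  features <- list(); reliability <- list(); mapsets_out <- list()
  peaksets_by_montage <- list()
  references <- list()
  combo_features <- list()   # keyed by montage|algorithm|strategy

  for (mg in config$montages) {
    say("montage %s: extracting GFP peaks", mg)
    psets <- lapply(pre, function(r) find_gfp_peaks(subset_channels(r, mg)))
    peaksets_by_montage[[mg]] <- psets
    # global TAAHC first: its map set is the labeling reference for the
    # rest of this montage's runs
    ref_run <- derive_maps(psets, "global", "taahc", K = config$K,
                           seed = .stage_seed(config$seed, 1))
    references[[mg]] <- ref_run$mapsets$global
    for (alg in config$algorithms) {
      for (strat in config$strategies) {
        say("montage %s: %s / %s", mg, alg, strat)
        dm <- if (alg == "taahc" && strat == "global") ref_run else
          derive_maps(psets, strat, alg, K = config$K,
                      reference = references[[mg]],
                      restarts = config$restarts,
                      seed = .stage_seed(config$seed, 2))
        key <- paste(mg, alg, strat, sep = "|")
        mapsets_out[[key]] <- dm
        feat <- do.call(rbind, lapply(seq_along(psets), function(i) {
          ms <- .fitting_mapset(dm, psets[[i]])
          microstate_features(psets[[i]], ms)
        }))
        feat <- cbind(montage = mg, algorithm = alg, strategy = strat, feat)
        combo_features[[key]] <- feat
        features[[key]] <- feat
        rel <- reliability_report(feat)
        reliability[[key]] <- cbind(montage = mg, algorithm = alg,
                                    strategy = strat, rel)
      }
    }
  }
  features <- do.call(rbind, features)
  reliability <- do.call(rbind, reliability)
  rownames(features) <- rownames(reliability) <- NULL

  # ---- consistency: TAAHC vs k-means (global maps, first session) ----
  consistency_alg <- NULL; tanova_res <- NULL
  if (all(c("taahc", "kmeans") %in% config$algorithms) &&
      "global" %in% config$strategies) {
    consistency_alg <- do.call(rbind, lapply(config$montages, function(mg) {
      tabs <- list(taahc = combo_features[[paste(mg, "taahc", "global", sep = "|")]],
                   kmeans = combo_features[[paste(mg, "kmeans", "global", sep = "|")]])
      ses1 <- sort(unique(tabs$taahc$session))[1]
      cbind(montage = mg, comparison = "taahc_vs_kmeans",
            consistency_alpha(tabs, session = ses1))
    }))
    say("TANOVA: TAAHC vs k-means class maps")
    mg <- config$montages[1]
    tanova_res <- .tanova_algorithms(
      peaksets_by_montage[[mg]],
      mapsets_out[[paste(mg, "taahc", "global", sep = "|")]]$mapsets$global,
      mapsets_out[[paste(mg, "kmeans", "global", sep = "|")]]$mapsets$global,
      permutations = config$tanova_permutations,
      seed = .stage_seed(config$seed, 3))
  }
  # ---- consistency across montages (TAAHC global) ----
  consistency_mont <- NULL
  if (length(config$montages) >= 2 && "global" %in% config$strategies &&
      "taahc" %in% config$algorithms) {
    tabs <- lapply(config$montages, function(mg)
      combo_features[[paste(mg, "taahc", "global", sep = "|")]])
    names(tabs) <- config$montages
    ses1 <- sort(unique(tabs[[1]]$session))[1]
    consistency_mont <- cbind(comparison = paste(config$montages, collapse = "_vs_"),
                              consistency_alpha(tabs, session = ses1))
  }
  # ---- feature correlations and power regression (primary combo) ----
  key1 <- paste(config$montages[1], config$algorithms[1],
                config$strategies[1], sep = "|")
  fc <- feature_correlations(combo_features[[key1]])
  n_rec <- length(recs)
  pr <- if (n_rec >= 8) power_regression(combo_features[[key1]], band_power_tab)
        else NULL   # fewer recordings than a 4-regressor fit can support

  structure(list(features = features, reliability = reliability,
                 consistency_algorithms = consistency_alg,
                 consistency_montages = consistency_mont,
                 tanova = tanova_res, feature_correlations = fc,
                 power_regression = pr, band_power = band_power_tab,
                 mapsets = mapsets_out, manifest = manifest,
                 references = references,
                 peaksets = peaksets_by_montage,
                 study = study, config = config),
            class = "study_report")
}

# pick the mapset a recording is fitted with, per strategy
.fitting_mapset <- function(dm, ps) {
  switch(dm$strategy,
    global = dm$mapsets$global,
    by_session = dm$mapsets[[ps$session_id]],
    by_recording = dm$mapsets[[paste(ps$subject_id, ps$session_id, sep = "_")]])
}

# subject-level class maps (sign-aligned mean of a subject's backfitted
# peak maps per class) for the TAAHC-vs-kmeans TANOVA
.subject_class_maps <- function(psets, ms) {
  subjects <- sort(unique(vapply(psets, `[[`, "", "subject_id")))
  lapply(stats::setNames(ms$labels, ms$labels), function(cls) {
    k <- match(cls, ms$labels)
    t(vapply(subjects, function(s) {
      maps <- do.call(rbind, lapply(psets, function(p) {
        if (p$subject_id != s) return(NULL)
        sq <- backfit(p, ms)
        p$maps[sq$class == cls, , drop = FALSE]
      }))
      .polarity_mean(.gfp_normalize_rows(maps), ms$maps[k, ])
    }, numeric(ncol(ms$maps))))
  })
}

.tanova_algorithms <- function(psets, ms_taahc, ms_kmeans, permutations,
                               seed) {
  maps_t <- .subject_class_maps(psets, ms_taahc)
  maps_k <- .subject_class_maps(psets, ms_kmeans)
  do.call(rbind, lapply(names(maps_t), function(cls) {
    res <- tanova(maps_t[[cls]], maps_k[[cls]],
                  permutations = permutations, seed = seed)
    data.frame(class = cls, observed_gmd = res$observed_gmd,
               p_value = res$p_value, permutations = permutations,
               seed = seed)
  }))
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d recordings, montages: %s\n",
              nrow(x$manifest), paste(x$config$montages, collapse = ", ")))
  cat(sprintf("  mean retained data %.2f s (range %.1f-%.1f)\n",
              mean(x$manifest$duration_s), min(x$manifest$duration_s),
              max(x$manifest$duration_s)))
  cat(sprintf("  reliability rows: %d; mean alpha %.3f\n",
              nrow(x$reliability), mean(x$reliability$alpha, na.rm = TRUE)))
  invisible(x)
}

#' Write a study report to delimited files
#'
#' Serializes every table of a `study_report` as tab-separated text in
#' `dir`, plus each derived map set (via [write_mapset()]) and a run
#' manifest.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(tab, name) {
    if (is.null(tab)) return()
    utils::write.table(tab, file.path(dir, paste0(name, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  wt(report$features, "features")
  wt(report$reliability, "reliability")
  wt(report$consistency_algorithms, "consistency_algorithms")
  wt(report$consistency_montages, "consistency_montages")
  wt(report$tanova, "tanova")
  wt(report$feature_correlations, "feature_correlations")
  wt(report$band_power, "band_power")
  wt(report$manifest, "manifest")
  for (key in names(report$mapsets)) {
    sets <- report$mapsets[[key]]$mapsets
    for (nm in names(sets)) {
      write_mapset(sets[[nm]],
                   file.path(dir, sprintf("maps_%s_%s.tsv",
                                          gsub("\\|", "_", key), nm)))
    }
  }
  invisible(dir)
}
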