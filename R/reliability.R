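#' Cronbach's alpha
#'
#' Raw-score Cronbach's alpha for a subjects x measurements matrix:
#' \deqn{\alpha = \frac{K}{K-1}\left(1 - \frac{\sum_i \sigma^2_i}{\sigma^2_Y}\right)}
#' with K the number of repeated measurements, \eqn{\sigma^2_i} the sample
#' variance (over subjects) of measurement i, and \eqn{\sigma^2_Y} the
#' variance of the per-subject total scores. Equivalent to the ICC(3,k)
#' intraclass correlation: a relative reliability coefficient, comparing
#' within-subject to between-subject variance.
#'
#' @param m Numeric matrix, subjects in rows, repeated measurements in
#'   columns; at least 2 of each, no missing cells.
#' @return Scalar alpha, or `NA` (with a warning) when the total-score
#'   variance is zero and alpha is undefined.
#' @examples
#' cronbach_alpha(rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))  # 1
#' @export
cronbach_alpha <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need >= 2 subjects and >= 2 measurements")
  if (anyNA(m)) stop("missing cells; apply listwise deletion first")
  K <- ncol(m)
  var_y <- stats::var(rowSums(m))
  if (var_y == 0) {
    warning("zero between-subject variance: Cronbach's alpha undefined")
    return(NA_real_)
  }
  (K / (K - 1)) * (1 - sum(apply(m, 2, stats::var)) / var_y)
}

#' Standard error of measurement
#'
#' Absolute-reliability companion to Cronbach's alpha:
#' \eqn{SEM = \sqrt{MS_{error}}} from the two-way (subject x measurement)
#' ANOVA decomposition, i.e. after removing the systematic
#' session/measurement effect. In feature units. The near-equivalent
#' \eqn{SD\sqrt{1 - ICC(3,1)}} is available as a cross-check via
#' `method = "icc"`.
#'
#' @param m Subjects x measurements matrix (as [cronbach_alpha()]).
#' @param method `"anova"` (default) or `"icc"` diagnostic variant.
#' @return SEM in the units of the measurements.
#' @export
sem_measurement <- function(m, method = c("anova", "icc")) {
  method <- match.arg(method)
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need >= 2 subjects and >= 2 measurements")
  if (anyNA(m)) stop("missing cells; apply listwise deletion first")
  n <- nrow(m); K <- ncol(m)
  grand <- mean(m)
  ss_subj <- K * sum((rowMeans(m) - grand)^2)
  ss_meas <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ms_err <- max(ss_tot - ss_subj - ss_meas, 0) / ((n - 1) * (K - 1))
  if (method == "anova") return(sqrt(ms_err))
  ms_subj <- ss_subj / (n - 1)
  icc31 <- (ms_subj - ms_err) / (ms_subj + (K - 1) * ms_err)
  stats::sd(as.numeric(m)) * sqrt(1 - icc31)
}

#' Smallest detectable change
#'
#' The change in a feature that exceeds measurement noise with the stated
#' confidence for repeated measurements in a single individual:
#' \eqn{SDC = z \sqrt{2}\, SEM} (z = 1.96 for 95%).
#'
#' @param sem Standard error of measurement (feature units).
#' @param z Two-sided critical value (default 1.96).
#' @return SDC in feature units.
#' @examples
#' smallest_detectable_change(6.41)  # 17.77 ms
#' @export
smallest_detectable_change <- function(sem, z = 1.96) {
  z * sqrt(2) * sem
}

#' Topographic analysis of variance (TANOVA)
#'
#' Randomization test for a topographic difference between two paired sets
#' of maps (one map per subject per condition). The test statistic is the
#' global map dissimilarity (GMD) between the GFP-normalized group-average
#' maps; members are sign-aligned to the grand-mean map before averaging
#' (unaligned averaging annihilates polarity-invariant topographies).
#' Under the null, each subject's pair is swapped at random; the p-value
#' is the fraction of permuted statistics at least as large as the
#' observed one (ties count toward p, which keeps the test valid and
#' makes identical groups yield p = 1; resolution 1/permutations).
#'
#' @param group1,group2 Subjects x channels matrices (paired by row).
#' @param permutations Number of random swaps (study default 5000).
#' @param seed Integer seed.
#' @return List of class `tanova_result`: `observed_gmd`, `p_value`,
#'   `permutations`, `seed`.
#' @export
tanova <- function(group1, group2, permutations = 5000, seed = 1) {
  g1 <- as.matrix(group1); g2 <- as.matrix(group2)
  if (!all(dim(g1) == dim(g2))) stop("groups must have identical dimensions")
  n <- nrow(g1)
  if (n < 2) stop("TANOVA needs at least 2 subjects")
  nch <- ncol(g1)
  g1 <- .gfp_normalize_rows(g1); g2 <- .gfp_normalize_rows(g2)
  # polarity alignment: to the grand mean (invariant under permutation)
  ref <- g1[1, ]
  align <- function(g, r) {
    s <- sign(g %*% r); s[s == 0] <- 1
    g * as.numeric(s)
  }
  g1 <- align(g1, ref); g2 <- align(g2, ref)
  grand <- colMeans(rbind(g1, g2))
  g1 <- align(g1, grand); g2 <- align(g2, grand)

  stat <- function(m1, m2) {
    m1 <- gfp_normalize(m1); m2 <- gfp_normalize(m2)
    sqrt(sum((m1 - m2)^2) / nch)
  }
  observed <- stat(colMeans(g1), colMeans(g2))

  rng <- .new_rng(seed)
  W <- matrix(rng$unif(permutations * n) < 0.5, permutations, n)
  M1 <- (W %*% g2 + (!W) %*% g1) / n
  M2 <- (W %*% g1 + (!W) %*% g2) / n
  M1 <- .gfp_normalize_rows(M1); M2 <- .gfp_normalize_rows(M2)
  perm_stats <- sqrt(rowSums((M1 - M2)^2) / nch)
  structure(list(observed_gmd = observed,
                 p_value = mean(perm_stats >= observed - 1e-12),
                 permutations = permutations, seed = seed),
            class = "tanova_result")
}

#' @export
print.tanova_result <- function(x, ...) {
  cat(sprintf("TANOVA: observed GMD %.4f, p = %.4f (%d permutations)\n",
              x$observed_gmd, x$p_value, x$permutations))
  invisible(x)
}

#' Test-retest reliability report
#'
#' Builds, for every feature x class combination, the subjects x sessions
#' measurement matrix from a long feature table and reports the mean, SD,
#' Cronbach's alpha, SEM (absolute and as percent of mean), and the 95%
#' smallest detectable change — the layout of a classical reliability
#' table. Subjects with a missing cell (e.g. a class absent from one
#' recording) are dropped listwise for that row, with the count recorded
#' in `n_dropped`.
#'
#' @param features Long data.frame with columns `subject`, `session`,
#'   `class`, and the feature columns named in `value_cols`.
#' @param value_cols Feature columns to analyze.
#' @return data.frame with one row per feature x class: `feature`,
#'   `class`, `n_subjects`, `n_sessions`, `n_dropped`, `mean`, `sd`,
#'   `alpha`, `sem`, `sem_pct`, `sdc95`.
#' @export
reliability_report <- function(features,
                               value_cols = c("mean_lifespan", "frequency",
                                              "coverage")) {
  out <- list()
  for (feat in value_cols) {
    for (cls in unique(features$class)) {
      d <- features[features$class == cls, c("subject", "session", feat)]
      if (feat == "coverage" && cls == "All") next  # identically 1
      wide <- stats::reshape(d, idvar = "subject", timevar = "session",
                             direction = "wide")
      m <- as.matrix(wide[, -1, drop = FALSE])
      complete <- stats::complete.cases(m)
      n_drop <- sum(!complete)
      m <- m[complete, , drop = FALSE]
      if (nrow(m) < 2 || ncol(m) < 2) next
      a <- suppressWarnings(cronbach_alpha(m))
      s <- sem_measurement(m)
      out[[length(out) + 1]] <- data.frame(
        feature = feat, class = cls, n_subjects = nrow(m),
        n_sessions = ncol(m), n_dropped = n_drop,
        mean = mean(m), sd = stats::sd(as.numeric(m)),
        alpha = a, sem = s,
        sem_pct = 100 * s / abs(mean(m)),
        sdc95 = smallest_detectable_change(s))
    }
  }
  do.call(rbind, out)
}

#' Cross-method consistency
#'
#' Cronbach's alpha with *methods* (clustering algorithms or montages) as
#' the repeated measurements, computed over recording units from a single
#' session (or all recordings, if preferred): the consistency analog of a
#' test-retest table.
#'
#' @param feature_tables Named list of long feature tables (one per
#'   method), each as in [reliability_report()]; rows are matched on
#'   `subject`, `session`, `class`.
#' @param value_cols Feature columns to analyze.
#' @param session Optional session id to restrict to (single-session
#'   consistency); `NULL` uses all recordings as units.
#' @return data.frame with `feature`, `class`, `n_units`, `alpha`.
#' @export
consistency_alpha <- function(feature_tables,
                              value_cols = c("mean_lifespan", "frequency",
                                             "coverage"),
                              session = NULL) {
  methods <- names(feature_tables)
  stopifnot(length(methods) >= 2)
  out <- list()
  classes <- unique(feature_tables[[1]]$class)
  for (feat in value_cols) {
    for (cls in classes) {
      if (feat == "coverage" && cls == "All") next
      cols <- lapply(feature_tables, function(tab) {
        d <- tab[tab$class == cls, ]
        if (!is.null(session)) d <- d[d$session == session, ]
        d <- d[order(d$subject, d$session), ]
        stats::setNames(d[[feat]], paste(d$subject, d$session))
      })
      units <- Reduce(intersect, lapply(cols, names))
      m <- vapply(cols, function(x) x[units], numeric(length(units)))
      keep <- stats::complete.cases(m)
      m <- m[keep, , drop = FALSE]
      if (nrow(m) < 2) next
      out[[length(out) + 1]] <- data.frame(
        feature = feat, class = cls, n_units = nrow(m),
        alpha = suppressWarnings(cronbach_alpha(m)))
    }
  }
  do.call(rbind, out)
}

#' Correlations among microstate features
#'
#' Pearson correlations across recordings: per class, mean lifespan vs
#' frequency; and across class pairs, lifespan-lifespan and
#' frequency-frequency.
#'
#' @param features Long feature table (see [reliability_report()]).
#' @return data.frame with `type`, `class_a`, `class_b`, `r`.
#' @export
feature_correlations <- function(features) {
  classes <- setdiff(unique(features$class), "All")
  wide <- function(feat) {
    sapply(classes, function(k) {
      d <- features[features$class == k, ]
      d <- d[order(d$subject, d$session), ]
      d[[feat]]
    })
  }
  ls <- wide("mean_lifespan"); fr <- wide("frequency")
  out <- list()
  for (k in classes)
    out[[length(out) + 1]] <- data.frame(
      type = "lifespan_vs_frequency", class_a = k, class_b = k,
      r = stats::cor(ls[, k], fr[, k], use = "complete.obs"))
  pairs <- utils::combn(classes, 2)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    out[[length(out) + 1]] <- data.frame(
      type = "lifespan_vs_lifespan", class_a = a, class_b = b,
      r = stats::cor(ls[, a], ls[, b], use = "complete.obs"))
    out[[length(out) + 1]] <- data.frame(
      type = "frequency_vs_frequency", class_a = a, class_b = b,
      r = stats::cor(fr[, a], fr[, b], use = "complete.obs"))
  }
  do.call(rbind, out)
}

#' Regression of overall microstate features on relative band power
#'
#' Ordinary least squares of the overall ("All") mean lifespan and
#' frequency on the relative power in the delta, theta, alpha and beta
#' bands, across recordings. Zero-variance regressors are dropped with a
#' warning; perfectly collinear ones are flagged (their coefficients come
#' back `NA` from the fit).
#'
#' @param features Long feature table (needs the `All` rows).
#' @param band_powers data.frame with columns `subject`, `session`,
#'   `band`, `relative_power` (one row per recording x band).
#' @return Named list of `lm` summaries, one per outcome
#'   (`mean_lifespan`, `frequency`).
#' @export
power_regression <- function(features, band_powers) {
  bp_wide <- stats::reshape(
    band_powers[, c("subject", "session", "band", "relative_power")],
    idvar = c("subject", "session"), timevar = "band", direction = "wide")
  names(bp_wide) <- sub("relative_power.", "rel_", names(bp_wide), fixed = TRUE)
  all_rows <- features[features$class == "All",
                       c("subject", "session", "mean_lifespan", "frequency")]
  d <- merge(all_rows, bp_wide, by = c("subject", "session"))
  regs <- grep("^rel_", names(d), value = TRUE)
  keep <- regs[vapply(regs, function(r) stats::var(d[[r]]) > 1e-12, TRUE)]
  if (length(keep) < length(regs))
    warning("dropped zero-variance regressor(s): ",
            paste(setdiff(regs, keep), collapse = ", "))
  fits <- lapply(c(mean_lifespan = "mean_lifespan", frequency = "frequency"),
                 function(y) {
    fit <- stats::lm(stats::reformulate(keep, response = y), data = d)
    if (anyNA(stats::coef(fit)))
      warning("collinear regressors in the ", y, " model (NA coefficients)")
    summary(fit)
  })
  fits
}
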