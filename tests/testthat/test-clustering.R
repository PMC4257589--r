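test_that("TAAHC recovers well-separated templates", {
  fx <- separated_maps_fixture(n_per = 10, noise = 0.02)
  res <- taahc(fx$maps, 4)
  matched <- match_labels(res$mapset, mapset(fx$templates))
  expect_true(all(attr(matched, "match_correlation") >= 0.99))
  expect_gt(res$mapset$gev_on_source, 0.99)
})

test_that("TAAHC degenerate partitions behave as defined", {
  fx <- separated_maps_fixture(n_per = 2, noise = 0.05)
  # K = number of maps: every map its own cluster, GEV = 1
  res <- taahc(fx$maps, nrow(fx$maps))
  expect_equal(res$mapset$gev_on_source, 1, tolerance = 1e-9)
  expect_equal(sort(unique(res$assignment)), seq_len(nrow(fx$maps)))
  # u and -u collapse into one polarity-invariant cluster
  u <- gfp_normalize(rnorm(19))
  res1 <- taahc(rbind(u, -u), 1)
  expect_equal(unname(abs(res1$mapset$maps %*% u) / 19), matrix(1),
               tolerance = 1e-9)
  expect_error(taahc(rbind(u, -u), 3), "K")
})

test_that("TAAHC is deterministic for a fixed input order", {
  fx <- separated_maps_fixture(n_per = 6, noise = 0.1, seed = 7)
  a <- taahc(fx$maps, 4)
  b <- taahc(fx$maps, 4)
  expect_identical(a$mapset$maps, b$mapset$maps)
  expect_identical(a$assignment, b$assignment)
})

test_that("modified k-means recovers templates, reproducibly under seed", {
  fx <- separated_maps_fixture(n_per = 10, noise = 0.02)
  km <- kmeans_microstates(fx$maps, 4, restarts = 20, seed = 3)
  matched <- match_labels(km$mapset, mapset(fx$templates))
  expect_true(all(attr(matched, "match_correlation") >= 0.99))
  km2 <- kmeans_microstates(fx$maps, 4, restarts = 20, seed = 3)
  expect_identical(km$mapset$maps, km2$mapset$maps)
  expect_identical(km$assignment, km2$assignment)
})

test_that("best-of-restarts GEV is monotone in the number of restarts", {
  fx <- separated_maps_fixture(n_per = 8, noise = 0.6, seed = 13)
  g1 <- kmeans_microstates(fx$maps, 4, restarts = 1, seed = 5)$gev
  g50 <- kmeans_microstates(fx$maps, 4, restarts = 50, seed = 5)$gev
  expect_gte(g50, g1)
})

test_that("k-means input validation catches degenerate map sets", {
  u <- gfp_normalize(rnorm(19))
  expect_error(kmeans_microstates(rbind(u, 2 * u, -u), 2, restarts = 5),
               "distinct")
  expect_error(kmeans_microstates(rbind(u, -u), 3), "K exceeds")
})

test_that("GEV equals 1 for exact fits and ignores orthogonal contributions", {
  tm <- make_template_maps("ch19", seed = 1)
  expect_equal(gev(tm, tm, seq_len(4)), 1, tolerance = 1e-12)
  # an orthogonal map assigned anywhere contributes zero to the numerator
  u <- c(1, -1, rep(0, 17))
  v <- c(0, 0, 1, -1, rep(0, 15))
  both <- rbind(u, v)
  g <- gev(both, matrix(u, 1), c(1, 1))
  expect_equal(g, sum(gfp(u)^2) / (gfp(u)^2 + gfp(v)^2), tolerance = 1e-12)
})

test_that("GEV on a 2-map toy case matches brute force over assignments", {
  set.seed(21)
  maps <- matrix(rnorm(2 * 10), 2)
  tmpl <- matrix(rnorm(2 * 10), 2)
  w <- apply(maps, 1, gfp)
  brute <- function(assign) {
    cs <- vapply(1:2, function(j) abs_correlation(maps[j, ], tmpl[assign[j], ]), 0)
    sum((w * cs)^2) / sum(w^2)
  }
  best <- max(brute(c(1, 1)), brute(c(1, 2)), brute(c(2, 1)), brute(c(2, 2)))
  expect_equal(gev(maps, tmpl), best, tolerance = 1e-12)
})

test_that("cross-validation criterion is zero for perfect fits and guarded", {
  tm <- make_template_maps("ch19", seed = 1)
  expect_equal(cv_criterion(tm, tm, seq_len(4)), 0, tolerance = 1e-12)
  set.seed(8)
  noisy <- tm + 0.1 * matrix(rnorm(length(tm)), nrow(tm))
  expect_gt(cv_criterion(noisy, tm, seq_len(4)), 0)
  expect_error(cv_criterion(tm[, 1:5], tm[, 1:5], seq_len(4)),
               "n_electrodes")
  # brute-force residual on a toy case
  maps <- rbind(c(2, -2, 0, 0, 1, -1), c(0, 1, -1, 2, -2, 0))
  tmpl <- .gfp_normalize_rows(matrix(c(1, -1, 0, 0, 0, 0), 1))
  a <- tmpl / sqrt(sum(tmpl^2))
  resid <- sum(vapply(1:2, function(j) {
    x <- maps[j, ] - mean(maps[j, ])
    sum(x^2) - sum(a * x)^2
  }, 0))
  n <- 6
  expect_equal(cv_criterion(maps, tmpl, c(1, 1)),
               resid / (2 * (n - 1)) * ((n - 1) / (n - 2))^2,
               tolerance = 1e-12)
})

test_that("label matching recovers permutations and ignores polarity", {
  tm <- make_template_maps("ch30", seed = 1)
  ref <- mapset(tm)
  expect_equal(match_labels(ref, ref)$labels, c("A", "B", "C", "D"))
  flipped <- mapset(-tm)
  mf <- match_labels(flipped, ref)
  expect_equal(unname(attr(mf, "match_correlation")), rep(1, 4),
               tolerance = 1e-9)
  perm <- c(3, 1, 4, 2)
  shuffled <- mapset(tm[perm, ], labels = c("w", "x", "y", "z"))
  ms <- match_labels(shuffled, ref)
  expect_equal(ms$labels, c("A", "B", "C", "D"))
  expect_equal(unname(ms$maps), unname(tm), tolerance = 1e-9)
})

test_that("derive_maps produces the expected map sets per strategy", {
  cfg <- synth_config(n_subjects = 2, n_sessions = 2, record_length = 20,
                      seed = 31)
  st <- generate_study(cfg)
  psets <- lapply(st$recordings, function(r)
    find_gfp_peaks(preprocess_recording(r, target_hz = NULL)))
  glob <- derive_maps(psets, "global", "taahc", K = 4)
  expect_named(glob$mapsets, "global")
  expect_length(glob$first_level, 4)
  # second-level input pools K maps per recording
  expect_equal(sum(vapply(glob$first_level, function(m) nrow(m$maps), 0L)),
               4 * length(psets))
  byrec <- derive_maps(psets, "by_recording", "taahc", K = 4,
                       reference = glob$mapsets$global)
  expect_length(byrec$mapsets, 4)
  expect_equal(names(byrec$mapsets)[1], "S01_T1")
  byses <- derive_maps(psets, "by_session", "taahc", K = 4,
                       reference = glob$mapsets$global)
  expect_equal(sort(names(byses$mapsets)), c("T1", "T2"))
  expect_true(all(vapply(byses$mapsets, function(m)
    identical(m$labels, c("A", "B", "C", "D")), TRUE)))
  empty <- psets[[1]]
  empty$maps <- empty$maps[0, , drop = FALSE]
  expect_error(derive_maps(c(list(empty), psets[-1]), "global", "taahc"),
               "S01_T1")
})

test_that("TAAHC and k-means agree on clean study data", {
  fx <- separated_maps_fixture(n_per = 15, noise = 0.3, seed = 3)
  mt <- taahc(fx$maps, 4)$mapset
  mk <- kmeans_microstates(fx$maps, 4, restarts = 30, seed = 4)$mapset
  matched <- match_labels(mk, mt)
  expect_true(all(attr(matched, "match_correlation") >= 0.95))
})

test_that("map sets serialize with metadata", {
  tm <- make_template_maps("ch8", seed = 1)
  ms <- mapset(tm, algorithm = "taahc", strategy = "global",
               gev_on_source = 0.75)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mapset(ms, path)
  lines <- readLines(path)
  expect_true(any(grepl("algorithm: taahc", lines)))
  tab <- read.delim(path, comment.char = "#", check.names = FALSE)
  expect_equal(tab$label, c("A", "B", "C", "D"))
  expect_equal(as.numeric(tab[1, -1]), unname(tm[1, ]), tolerance = 1e-6)
  back <- read_mapset(path)
  expect_equal(back$labels, ms$labels)
  expect_equal(back$algorithm, "taahc")
  expect_equal(back$gev_on_source, 0.75)
  expect_equal(unname(back$maps), unname(ms$maps), tolerance = 1e-5)
})
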