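test_that("Cronbach's alpha matches hand computation and its invariances", {
  m <- rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  expect_equal(cronbach_alpha(m), 1)
  # adding a constant to one session's column leaves alpha unchanged
  m2 <- m; m2[, 2] <- m2[, 2] + 10
  expect_equal(cronbach_alpha(m2), cronbach_alpha(m))
  # permutation of columns leaves alpha unchanged
  set.seed(31)
  r <- matrix(rnorm(24), 8, 3)
  expect_equal(cronbach_alpha(r[, c(3, 1, 2)]), cronbach_alpha(r))
  expect_warning(a0 <- cronbach_alpha(matrix(1, 4, 3)), "undefined")
  expect_true(is.na(a0))
  expect_error(cronbach_alpha(matrix(1, 1, 3)), ">= 2 subjects")
})

test_that("alpha is near zero for independent sessions and near one for strong subject effects", {
  set.seed(32)
  noise <- matrix(rnorm(200 * 3), 200, 3)
  expect_lt(abs(cronbach_alpha(noise)), 0.15)
  subj <- rnorm(200, sd = 5)
  strong <- subj + matrix(rnorm(200 * 3), 200, 3)
  expect_gt(cronbach_alpha(strong), 0.9)
})

test_that("alpha equals ICC(3,k) from an independent ANOVA decomposition", {
  set.seed(33)
  worst <- 0
  for (i in 1:25) {
    m <- matrix(rnorm(15, sd = runif(1, 0.5, 3)), 5, 3) + rnorm(5)
    worst <- max(worst, abs(cronbach_alpha(m) - icc3k_aov(m)))
  }
  expect_lt(worst, 1e-9)
})

test_that("SEM is the root error mean square of the two-way decomposition", {
  m <- rbind(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5))
  expect_equal(sem_measurement(m), 0)   # within-subject change is a session effect
  # invariant to a global constant
  set.seed(34)
  r <- matrix(rnorm(30), 10, 3)
  expect_equal(sem_measurement(r + 100), sem_measurement(r))
  # recovers a known measurement-noise SD
  sigma <- 2.5
  big <- rnorm(200, sd = 10) + matrix(rnorm(600, sd = sigma), 200, 3)
  expect_lt(abs(sem_measurement(big) - sigma) / sigma, 0.1)
  # ICC-based variant agrees to first order on reliable data
  expect_lt(abs(sem_measurement(big, "icc") - sem_measurement(big)) / sigma, 0.15)
})

test_that("smallest detectable change is z*sqrt(2)*SEM", {
  expect_equal(round(smallest_detectable_change(6.41), 2), 17.77)
  expect_equal(smallest_detectable_change(0), 0)
  expect_equal(smallest_detectable_change(5, z = 0), 0)
  expect_equal(smallest_detectable_change(3) / 3, 1.96 * sqrt(2))
})

test_that("TANOVA: identical groups give p = 1, real differences give small p", {
  set.seed(35)
  g1 <- t(replicate(10, gfp_normalize(rnorm(19))))
  res <- tanova(g1, g1, permutations = 500, seed = 2)
  expect_equal(res$observed_gmd, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  # strong difference: two distinct template directions
  a <- gfp_normalize(rnorm(19)); b <- gfp_normalize(rnorm(19))
  ga <- t(replicate(10, gfp_normalize(a + 0.1 * rnorm(19))))
  gb <- t(replicate(10, gfp_normalize(b + 0.1 * rnorm(19))))
  expect_lt(tanova(ga, gb, permutations = 500, seed = 2)$p_value, 0.05)
  # deterministic under seed
  r1 <- tanova(ga, gb, permutations = 200, seed = 7)
  r2 <- tanova(ga, gb, permutations = 200, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_error(tanova(ga[1, , drop = FALSE], gb[1, , drop = FALSE]),
               "2 subjects")
})

test_that("TANOVA is polarity-invariant in its inputs", {
  set.seed(36)
  g1 <- t(replicate(8, gfp_normalize(rnorm(19))))
  g2 <- g1 * rep(sample(c(-1, 1), 8, replace = TRUE), 19)
  res <- tanova(g1, g2, permutations = 300, seed = 3)
  expect_equal(res$observed_gmd, 0, tolerance = 1e-9)
  expect_equal(res$p_value, 1)
})

test_that("reliability_report builds the table layout of a reliability study", {
  set.seed(37)
  feats <- expand.grid(subject = paste0("S", 1:6), session = paste0("T", 1:3),
                       class = c("A", "B", "C", "D", "All"),
                       stringsAsFactors = FALSE)
  subj_eff <- rnorm(6, 100, 15)[match(feats$subject, paste0("S", 1:6))]
  feats$mean_lifespan <- subj_eff + rnorm(nrow(feats), sd = 3)
  feats$frequency <- 10 + rnorm(nrow(feats), sd = 0.5)
  feats$coverage <- ifelse(feats$class == "All", 1, 0.25 + rnorm(nrow(feats), sd = 0.02))
  rep <- reliability_report(feats)
  # 5 lifespan + 5 frequency + 4 coverage rows ("All" coverage constant)
  expect_equal(nrow(rep), 14)
  expect_true(all(c("alpha", "sem", "sem_pct", "sdc95") %in% names(rep)))
  expect_equal(rep$sdc95 / rep$sem, rep(1.96 * sqrt(2), 14))
  ls_rows <- rep[rep$feature == "mean_lifespan", ]
  expect_true(all(ls_rows$alpha > 0.7))   # strong subject effects by design
})

test_that("consistency alpha is 1 when a method is compared with itself", {
  set.seed(38)
  feats <- expand.grid(subject = paste0("S", 1:5), session = "T1",
                       class = c("A", "B"), stringsAsFactors = FALSE)
  feats$mean_lifespan <- rnorm(nrow(feats), 100, 10)
  feats$frequency <- rnorm(nrow(feats), 2.5, 0.3)
  feats$coverage <- rnorm(nrow(feats), 0.25, 0.03)
  ca <- consistency_alpha(list(m1 = feats, m2 = feats))
  expect_true(all(abs(ca$alpha - 1) < 1e-9))
})

test_that("feature correlations recover engineered relationships", {
  subj <- paste0("S", 1:20)
  set.seed(39)
  life_a <- rnorm(20, 100, 10)
  feats <- rbind(
    data.frame(subject = subj, session = "T1", class = "A",
               mean_lifespan = life_a, frequency = 300 / life_a,
               coverage = 0.5),
    data.frame(subject = subj, session = "T1", class = "B",
               mean_lifespan = life_a, frequency = rnorm(20, 2.5, 0.2),
               coverage = 0.5))
  fc <- feature_correlations(feats)
  r_af <- fc$r[fc$type == "lifespan_vs_frequency" & fc$class_a == "A"]
  expect_lt(r_af, -0.9)                       # mechanically inverse
  r_ll <- fc$r[fc$type == "lifespan_vs_lifespan"]
  expect_equal(r_ll, 1)                       # duplicated column
})

test_that("power regression recovers signs and flags degenerate designs", {
  set.seed(40)
  n <- 30
  rel_alpha <- runif(n, 0.3, 0.6)
  rel_beta <- runif(n, 0.1, 0.3)
  feats <- data.frame(subject = paste0("S", 1:n), session = "T1",
                      class = "All",
                      mean_lifespan = 50 + 100 * rel_alpha - 80 * rel_beta +
                        rnorm(n, sd = 1),
                      frequency = 5 + 10 * rel_beta + rnorm(n, sd = 0.1),
                      coverage = 1)
  bp <- rbind(
    data.frame(subject = paste0("S", 1:n), session = "T1", band = "alpha",
               relative_power = rel_alpha),
    data.frame(subject = paste0("S", 1:n), session = "T1", band = "beta",
               relative_power = rel_beta),
    data.frame(subject = paste0("S", 1:n), session = "T1", band = "delta",
               relative_power = 0.2))
  expect_warning(fits <- power_regression(feats, bp), "zero-variance")
  co <- stats::coef(fits$mean_lifespan)
  expect_gt(co["rel_alpha", "Estimate"], 0)
  expect_lt(co["rel_beta", "Estimate"], 0)
  expect_gt(fits$mean_lifespan$r.squared, 0.9)
})
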