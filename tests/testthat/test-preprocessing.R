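test_that("band-pass filter passes the passband and stops the stopband", {
  hi <- sine_recording(100, fs = 1000)
  lo <- sine_recording(10, fs = 1000)
  out_hi <- bandpass_filter(hi, 1, 30)
  out_lo <- bandpass_filter(lo, 1, 30)
  expect_lt(rms(out_hi$data), 0.05 * rms(hi$data))
  expect_equal(rms(out_lo$data), rms(lo$data), tolerance = 0.05)
  z <- recording(matrix(0, 3, 1000), c("a", "b", "c"), 1000)
  expect_equal(bandpass_filter(z, 1, 30)$data, z$data)
  expect_error(bandpass_filter(lo, 1, 600), "Nyquist")
})

test_that("notch filter removes 60 Hz and preserves 10 Hz", {
  tone60 <- sine_recording(60, fs = 1000)
  tone10 <- sine_recording(10, fs = 1000)
  expect_lt(rms(notch_filter(tone60)$data), 0.1 * rms(tone60$data))
  expect_equal(rms(notch_filter(tone10)$data), rms(tone10$data),
               tolerance = 0.05)
  z <- recording(matrix(0, 2, 500), c("a", "b"), 1000)
  expect_equal(notch_filter(z)$data, z$data)
})

test_that("epoching cuts complete 2-s epochs and drops the remainder", {
  mk <- function(dur_s) recording(matrix(rnorm(2 * 200 * dur_s), 2),
                                  c("a", "b"), 200)
  e5 <- epoch_recording(mk(5), 2)
  expect_equal(nrow(e5$epochs), 2)
  expect_equal(unique(e5$epochs$n), 400L)
  expect_equal(ncol(e5$data), 800)
  expect_equal(nrow(epoch_recording(mk(4), 2)$epochs), 2)
  expect_error(epoch_recording(mk(1.9), 2), "no complete epoch")
})

test_that("amplitude rejection drops exactly the spiked epochs", {
  set.seed(5)
  rec <- recording(matrix(rnorm(2 * 2000, sd = 10), 2), c("a", "b"), 200)
  rec <- epoch_recording(rec, 2)        # 5 epochs
  expect_equal(attr(reject_epochs(rec, 500), "n_rejected"), 0L)
  spiked <- rec
  spiked$data[1, 900] <- 1000           # epoch 3 (samples 801-1200)
  out <- suppressMessages(reject_epochs(spiked, 500))
  expect_equal(nrow(out$epochs), 4)
  expect_equal(attr(out, "n_rejected"), 1L)
  expect_false(any(abs(out$data) > 500))
  allspike <- rec
  allspike$data[1, seq(1, 2000, by = 100)] <- 1000
  expect_error(reject_epochs(allspike, 500), "no data remaining")
})

test_that("average reference zeroes channel means and is idempotent", {
  set.seed(6)
  rec <- recording(matrix(rnorm(300) + 5, 3), c("a", "b", "c"), 100)
  ar <- average_reference(rec)
  expect_lt(max(abs(colMeans(ar$data))), 1e-9)
  expect_equal(average_reference(ar)$data, ar$data)
  const <- recording(matrix(2, 3, 50), c("a", "b", "c"), 100)
  expect_equal(average_reference(const)$data, matrix(0, 3, 50),
               ignore_attr = TRUE)
})

test_that("downsampling preserves in-band content and rejects upsampling", {
  rec <- sine_recording(10, fs = 1000, dur_s = 6)
  down <- downsample_recording(rec, 200)
  expect_equal(down$sampling_rate, 200)
  expect_equal(ncol(down$data), ncol(rec$data) / 5)
  # compare steady-state RMS away from filter edges
  core <- 200:1000
  expect_equal(rms(down$data[, core]), rms(rec$data), tolerance = 0.02)
  expect_identical(downsample_recording(rec, 1000), rec)
  expect_error(downsample_recording(rec, 2000), "upsample")
  expect_error(downsample_recording(rec, 300), "divide")
})

test_that("montage subsetting keeps the named channels and re-references", {
  cfg <- synth_config(record_length = 5, seed = 1)
  g <- generate_recording(make_template_maps("ch30", 1), cfg, seed = 2)
  r19 <- subset_channels(g$recording, "ch19")
  expect_equal(r19$channel_labels, montage_channels("ch19"))
  expect_lt(max(abs(colMeans(r19$data))), 1e-9)
  r8 <- subset_channels(g$recording, "ch8")
  expect_equal(r8$channel_labels,
               c("F3", "F4", "C3", "Cz", "C4", "P3", "Pz", "P4"))
  expect_error(subset_channels(r8, "ch19"), "not in recording")
})

test_that("band power concentrates where the signal is", {
  alpha <- epoch_recording(sine_recording(10, fs = 200, dur_s = 8), 2)
  bp <- band_power(alpha)
  expect_gt(bp$relative_power[bp$band == "alpha"], 0.95)
  # equal-amplitude 2 Hz + 20 Hz: delta and beta absolute powers match
  t <- seq(0, 8 - 1 / 200, by = 1 / 200)
  x <- 10 * sin(2 * pi * 2 * t) + 10 * sin(2 * pi * 20 * t)
  rec <- epoch_recording(recording(rbind(x, -x), c("a", "b"), 200), 2)
  bp2 <- band_power(rec)
  d <- bp2$absolute_power[bp2$band == "delta"]
  b <- bp2$absolute_power[bp2$band == "beta"]
  expect_lt(abs(d - b) / max(d, b), 0.1)
  z <- epoch_recording(recording(matrix(0, 2, 800), c("a", "b"), 200), 2)
  expect_equal(band_power(z)$absolute_power, rep(0, 4))
})

test_that("the preprocessing chain is deterministic and keeps the average reference", {
  cfg <- synth_config(record_length = 10, seed = 8)
  g <- generate_recording(make_template_maps("ch30", 1), cfg, seed = 3)
  p1 <- preprocess_recording(g$recording, target_hz = NULL)
  p2 <- preprocess_recording(g$recording, target_hz = NULL)
  expect_identical(p1$data, p2$data)
  expect_lt(max(abs(colMeans(p1$data))), 1e-6)
})
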