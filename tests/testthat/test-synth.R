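test_that("ground truth validates its invariants", {
  expect_error(ground_truth(lf_peak_hz = 2), "lf_peak_hz")
  expect_error(ground_truth(lf_peak_hz = 13), "lf_peak_hz")
  expect_error(ground_truth(beta_peak_hz = 40), "beta_peak_hz")
  expect_error(ground_truth(coupling_lag_ms = 0), "coupling_lag_ms")
  expect_error(ground_truth(lf_power_gain = c(STR = -1, GPe = 1, GPi = 1)),
               "gains")
  expect_s3_class(ground_truth(), "bg_truth")
})

test_that("a three-minute 1 kHz hemisphere has 180000 samples on 8 contacts", {
  rec <- generate_hemisphere(ground_truth(), duration_s = 180, fs = 1000,
                             seed = 1)
  expect_equal(dim(rec$samples), c(8, 180000))
  expect_length(assign_structures(derive_bipolar(rec)), 3)
})

test_that("generation rejects impossible durations, rates and lags", {
  expect_error(generate_hemisphere(ground_truth(), duration_s = 0), "duration")
  expect_error(generate_hemisphere(ground_truth(beta_peak_hz = 30),
                                   duration_s = 10, fs = 100), "4x")
  expect_error(generate_hemisphere(ground_truth(coupling_lag_ms = 0.5),
                                   duration_s = 10, fs = 1000),
               "shorter than one sample")
})

test_that("generation is deterministic given a seed", {
  r1 <- generate_hemisphere(ground_truth(), 10, 500, seed = 99)
  r2 <- generate_hemisphere(ground_truth(), 10, 500, seed = 99)
  expect_identical(r1$samples, r2$samples)
  r3 <- generate_hemisphere(ground_truth(), 10, 500, seed = 100)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("low-frequency band power scales monotonically with the gain", {
  gains <- c(0.3, 0.8, 1.6, 3)
  band_power <- vapply(gains, function(g) {
    tr <- ground_truth(lf_power_gain = c(STR = g, GPe = 1, GPi = 1),
                       coupling_gain = c(str_gpi = 0, str_gpe = 0,
                                         gpe_gpi = 0),
                       common_source_gain = 0, line_noise_amp = 0)
    rec <- generate_hemisphere(tr, 30, 400, seed = 7)
    ch <- assign_structures(derive_bipolar(rec))
    x <- ch$STR$samples
    # raw (unnormalized) spectral mass in 3-12 Hz via direct periodogram
    w <- welch_spectra(x, x, 400, seg_s = 2)
    mean(w$Sxx[w$freqs >= 3 & w$freqs <= 12])
  }, numeric(1))
  expect_true(all(diff(band_power) > 0))
})

test_that("lagged coupling peaks the cross-correlation at the configured lag", {
  lag_ms <- 25
  fs <- 1000
  tr <- ground_truth(coupling_gain = c(str_gpi = 2, str_gpe = 0, gpe_gpi = 0),
                     coupling_lag_ms = lag_ms, common_source_gain = 0,
                     line_noise_amp = 0, bg_gain = 0.2)
  rec <- generate_hemisphere(tr, 60, fs, seed = 3, contact_noise_sd = 0.05)
  ch <- assign_structures(derive_bipolar(rec))
  cc <- stats::ccf(ch$STR$samples, ch$GPi$samples, lag.max = 100, plot = FALSE)
  best_lag <- cc$lag[which.max(abs(cc$acf))]
  # STR leads GPi by lag_ms
  expect_lte(abs(abs(best_lag) - lag_ms / 1000 * fs), 1)
})

test_that("cohort generation honors size, drops and severity model", {
  cfg <- cohort_config()
  coh <- generate_cohort(10, 2, cfg, seed = 5, duration_s = 2, fs = 400)
  expect_length(coh$recordings, 19)   # one hemisphere dropped by default
  expect_length(coh$truths, 19)
  expect_equal(nrow(coh$subjects), 10)
  expect_true(all(coh$subjects$severity >= 0))
  ids <- vapply(coh$recordings, `[[`, character(1), "subject_id")
  expect_equal(sum(ids == "s07"), 1)  # unilateral subject remains
  # alignment of recordings and truths
  for (i in seq_along(coh$truths)) {
    expect_equal(coh$recordings[[i]]$subject_id, coh$truths[[i]]$subject_id)
    expect_equal(coh$recordings[[i]]$hemisphere, coh$truths[[i]]$hemisphere)
  }
})

test_that("cohorts regenerate bit-for-bit from the same seed", {
  cfg <- cohort_config()
  c1 <- generate_cohort(3, 2, cfg, seed = 11, duration_s = 2, fs = 400)
  c2 <- generate_cohort(3, 2, cfg, seed = 11, duration_s = 2, fs = 400)
  expect_identical(c1$subjects, c2$subjects)
  for (i in seq_along(c1$recordings)) {
    expect_identical(c1$recordings[[i]]$samples, c2$recordings[[i]]$samples)
  }
})

test_that("noise-free severity with one covariate is an exact affine function", {
  cfg <- cohort_config(severity_noise_sd = 0, severity_w_coupling = 0,
                       gpi_gain_slope = 1.5,
                       drop_hemispheres = data.frame(subject = integer(),
                                                     hemisphere = character()))
  coh <- generate_cohort(8, 2, cfg, seed = 2, duration_s = 2, fs = 400)
  g <- vapply(coh$truths, function(tr) tr$lf_power_gain[["GPi"]], numeric(1))
  ids <- vapply(coh$truths, `[[`, character(1), "subject_id")
  mean_g <- tapply(g, ids, mean)[coh$subjects$subject_id]
  expect_equal(unname(stats::cor(mean_g, coh$subjects$severity)), 1,
               tolerance = 1e-10)
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(severity_noise_sd = -1), "severity_noise_sd")
  expect_error(cohort_config(lf_peak_sd = -2), "sd")
  expect_error(generate_cohort(0), "n_subjects")
})

test_that("cohort provenance round-trips through write_cohort", {
  coh <- generate_cohort(2, 2, cohort_config(
    drop_hemispheres = data.frame(subject = integer(),
                                  hemisphere = character())),
    seed = 4, duration_s = 2, fs = 400)
  dir <- file.path(tempdir(), "cohort_out")
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  expect_true(file.exists(file.path(dir, "generator_config.json")))
  gt <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(gt), 4)
  back <- read_recording(file.path(dir, "s01_left.bin"))
  expect_identical(unname(back$samples), unname(coh$recordings[[1]]$samples))
})
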