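# fake cross-spectrum object from analytic spectra, for factorization tests
cs_from_spectra <- function(freqs, s11, s22, s12, fs = 200) {
  structure(list(pair = c("a", "b"), freqs = freqs, S_ab = s12,
                 S_aa = s11, S_bb = s22, per_epoch_S_ab = NULL,
                 n_epochs = NA_integer_, fs = fs),
            class = "bg_cross_spectrum")
}

test_that("Wilson factorization reproduces the causality of a known VAR", {
  fs <- 200
  A <- matrix(c(0.5, 0, 0.4, 0.7), 2, 2, byrow = TRUE)
  Sig <- diag(2)
  f <- seq(0, fs / 2, by = 0.5)
  tv <- var1_true_spectrum(A, Sig, fs, f)
  g <- granger_nonparametric(cs_from_spectra(f, tv$s11, tv$s22, tv$s12))
  sel <- f >= 3 & f <= 35
  expect_equal(g$fwd[sel], tv$fwd[sel], tolerance = 0.02)
  expect_lt(max(abs(g$rev[sel])), 0.01)
})

test_that("swapping the channel order exchanges forward and reverse exactly", {
  fs <- 200
  A <- matrix(c(0.5, 0, 0.4, 0.7), 2, 2, byrow = TRUE)
  f <- seq(0, fs / 2, by = 0.5)
  tv <- var1_true_spectrum(A, diag(2), fs, f)
  g_ab <- granger_nonparametric(cs_from_spectra(f, tv$s11, tv$s22, tv$s12))
  g_ba <- granger_nonparametric(cs_from_spectra(f, tv$s22, tv$s11, Conj(tv$s12)))
  expect_equal(g_ab$fwd, g_ba$rev, tolerance = 1e-6)
  expect_equal(g_ab$rev, g_ba$fwd, tolerance = 1e-6)
})

test_that("independent channels show near-zero causality in both directions", {
  set.seed(17)
  a <- quick_tfr(rnorm(200 * 200), 200)
  b <- quick_tfr(rnorm(200 * 200), 200)
  g <- granger_nonparametric(cross_spectrum(a, b))
  # interior bins; the extreme grid edge has the fewest effective
  # observations per wavelet and is the noisiest
  sel <- g$freqs >= 2
  expect_lt(max(g$fwd[sel]), 0.02)
  expect_lt(max(g$rev[sel]), 0.02)
})

test_that("nonparametric estimates track a fitted VAR oracle on long data", {
  fs <- 200
  A <- matrix(c(0.5, 0, 0.4, 0.7), 2, 2, byrow = TRUE)
  X <- simulate_var1(A, 6e4, seed = 18)
  tfx <- quick_tfr(X[1, ], fs)
  tfy <- quick_tfr(X[2, ], fs)
  cs <- cross_spectrum(tfx, tfy)
  g <- granger_nonparametric(cs)
  or <- var1_granger_oracle(X, fs, cs$freqs)
  bm <- function(v) band_mean(v, cs$freqs, "lf")
  expect_equal(bm(g$fwd), bm(or$fwd), tolerance = 0.1)
  expect_lt(bm(g$rev), 0.02)
})

test_that("granger input validation catches bad grids", {
  f_bad <- c(seq(1, 10, 0.5), seq(11, 30, 1))
  expect_error(granger_nonparametric(
    cs_from_spectra(f_bad, rep(1, length(f_bad)), rep(1, length(f_bad)),
                    complex(real = rep(0.1, length(f_bad)))),
    ), "uniform")
  expect_error(time_reversed_correction(1:5, 1:5, 1:4, 1:5), "grid")
})

test_that("time reversal moves drive to the opposite direction and cancels symmetric data", {
  fs <- 200
  A <- matrix(c(0.5, 0, 0.4, 0.7), 2, 2, byrow = TRUE)
  f <- seq(0, fs / 2, by = 0.5)
  tv <- var1_true_spectrum(A, diag(2), fs, f)
  g <- granger_time_reversed(cs_from_spectra(f, tv$s11, tv$s22, tv$s12))
  sel <- f >= 3 & f <= 12
  # genuine lagged drive survives the correction
  expect_gt(mean(g$fwd_corrected[sel]), 0.1)
  expect_lt(mean(g$rev_corrected[sel]), 0)
  # reversed-data estimates put the drive in the opposite direction
  expect_gt(mean(g$rev_tr[sel]), mean(g$fwd_tr[sel]))
  # an exactly real cross-spectrum equals its own time reversal ->
  # corrected spectra are identically zero
  s12_real <- complex(real = 0.5 * sqrt(tv$s11 * tv$s22))
  g0 <- granger_time_reversed(cs_from_spectra(f, tv$s11, tv$s11, s12_real))
  expect_equal(max(abs(g0$fwd_corrected)), 0, tolerance = 1e-9)
  expect_equal(max(abs(g0$rev_corrected)), 0, tolerance = 1e-9)
})

test_that("bin-count directionality follows the strict-majority and tie rules", {
  f <- seq(1, 45, 0.5)
  n_lf <- sum(f >= 3 & f <= 12)
  up <- rep(1, length(f)); dn <- rep(0, length(f))
  d <- directionality_designation(up, dn, f)
  expect_true(d$striatal_driving)
  expect_false(d$pallidal_driving)
  expect_equal(d$n_bins_str, n_lf)
  expect_equal(d$n_bins_gpi, 0)
  # equal spectra tie everywhere: designated neither, ties logged
  d2 <- directionality_designation(up, up, f)
  expect_false(d2$striatal_driving)
  expect_false(d2$pallidal_driving)
  expect_equal(d2$n_ties, n_lf)
  # the significance gate suppresses designation entirely
  d3 <- directionality_designation(up, dn, f, coupling_significant = FALSE)
  expect_false(d3$striatal_driving)
  expect_false(d3$pallidal_driving)
})

test_that("direction is recovered end-to-end on a coupled generator pair", {
  tr <- ground_truth(lf_peak_hz = 8,
                     coupling_gain = c(str_gpi = 0.6, str_gpe = 0, gpe_gpi = 0))
  tfrs <- generator_pair(tr, 90, 400, seed = 19)
  cs <- cross_spectrum(tfrs$STR, tfrs$GPi)
  g <- granger_time_reversed(cs)
  d <- directionality_designation(g$fwd_corrected, g$rev_corrected, g$freqs)
  expect_true(d$striatal_driving)
  expect_gt(band_mean(g$fwd_corrected, g$freqs, "lf"),
            band_mean(g$rev_corrected, g$freqs, "lf"))
})
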