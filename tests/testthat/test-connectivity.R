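make_pair <- function(n_s = 40, fs = 200, f0 = 10, delay = 0, noise = 0.3,
                      seed = 1, freqs = default_freqs()) {
  # narrowband source plus independent noise on both channels; channel b
  # is a delayed copy of the source
  withr::with_seed(seed, {
    n <- n_s * fs
    src <- bgosc:::narrowband_noise(n + fs, fs, f0, 2)
    a <- src[(fs + 1):(fs + n)] + noise * rnorm(n)
    b <- src[(fs + 1 - delay):(fs + n - delay)] + noise * rnorm(n)
    list(a = quick_tfr(a, fs, freqs), b = quick_tfr(b, fs, freqs))
  })
}

test_that("the cross-spectrum of a channel with itself is its auto-spectrum", {
  set.seed(6)
  tfr <- quick_tfr(rnorm(5000), 200, freqs = seq(3, 12, 0.5))
  cs <- cross_spectrum(tfr, tfr)
  expect_equal(max(abs(Im(cs$S_ab))), 0, tolerance = 1e-12)
  expect_equal(Re(cs$S_ab), cs$S_aa, tolerance = 1e-10)
})

test_that("a pure delay shows up as the matching cross-spectral phase", {
  fs <- 200
  delay <- 5   # samples -> 25 ms
  p <- make_pair(delay = delay, noise = 0.05, seed = 7)
  cs <- cross_spectrum(p$a, p$b)
  at <- which.min(abs(cs$freqs - 10))
  expect_equal(Arg(cs$S_ab[at]), 2 * pi * 10 * delay / fs, tolerance = 0.1)
})

test_that("independent channels have vanishing cross-spectra and a Cauchy-Schwarz bound", {
  set.seed(8)
  a <- quick_tfr(rnorm(120 * 200), 200, freqs = seq(3, 35, 1))
  b <- quick_tfr(rnorm(120 * 200), 200, freqs = seq(3, 35, 1))
  cs <- cross_spectrum(a, b)
  coh <- Mod(cs$S_ab)^2 / (cs$S_aa * cs$S_bb)
  expect_lt(max(coh), 0.2)
  # coherency magnitude never exceeds 1, on any input
  p <- make_pair(seed = 9, noise = 0.01)
  cs2 <- cross_spectrum(p$a, p$b)
  expect_true(all(Mod(cs2$S_ab)^2 <= cs2$S_aa * cs2$S_bb + 1e-12))
  expect_true(all(abs(imaginary_coherence(cs2)) <= 1))
})

test_that("zero-lag copies have zero imaginary coherence; iCOH is antisymmetric", {
  p <- make_pair(n_s = 120, delay = 0, noise = 0.2, seed = 10,
                 freqs = seq(8, 12, 0.5))
  cs <- cross_spectrum(p$a, p$b)
  # common source with zero lag: iCOH vanishes despite strong coupling
  expect_lt(max(abs(imaginary_coherence(cs))), 0.1)
  expect_gt(max(magnitude_coherence(cs)), 0.8)
  # antisymmetry under channel exchange
  p2 <- make_pair(delay = 5, noise = 0.3, seed = 11, freqs = seq(3, 12, 0.5))
  ic_ab <- imaginary_coherence(cross_spectrum(p2$a, p2$b))
  ic_ba <- imaginary_coherence(cross_spectrum(p2$b, p2$a))
  expect_equal(ic_ab, -ic_ba, tolerance = 1e-10)
})

test_that("iCOH at the coupling peak matches a DFT-segment oracle", {
  tr <- ground_truth(lf_peak_hz = 8,
                     coupling_gain = c(str_gpi = 2, str_gpe = 0, gpe_gpi = 0),
                     common_source_gain = 0, osc_bandwidth_hz = 4)
  rec <- generate_hemisphere(tr, 120, 1000, seed = 13)
  ch <- assign_structures(derive_bipolar(rec))
  xs <- as.numeric(condition(ch$STR))
  xg <- as.numeric(condition(ch$GPi))
  cs <- cross_spectrum(quick_tfr(xs, 200), quick_tfr(xg, 200))
  ic <- abs(imaginary_coherence(cs))
  wo <- welch_icoh(xs, xg, 200)
  peak_m <- max(ic[cs$freqs >= 3 & cs$freqs <= 12])
  peak_w <- max(abs(wo$icoh[wo$freqs >= 3 & wo$freqs <= 12]))
  expect_equal(peak_m, peak_w, tolerance = 0.08)
})

test_that("debiased wPLI approaches 1 for consistent lag and 0 degenerately", {
  p <- make_pair(delay = 5, noise = 0.05, seed = 12, freqs = seq(8, 12, 0.5))
  cs <- cross_spectrum(p$a, p$b)
  expect_gt(max(wpli(cs)), 0.9)
  # b = a exactly: all per-epoch imaginary parts vanish -> 0 with warning
  tfr <- quick_tfr(rnorm(4000), 200, freqs = seq(3, 12, 0.5))
  cs_self <- cross_spectrum(tfr, tfr)
  expect_warning(w <- wpli(cs_self), "imaginary")
  expect_equal(w, rep(0, length(cs_self$freqs)))
  expect_error(wpli(structure(list(n_epochs = 1), class = "bg_cross_spectrum")),
               "2 epochs")
})

test_that("the debiased wPLI null is centered at zero and can be negative", {
  set.seed(14)
  vals <- replicate(40, {
    a <- quick_tfr(rnorm(60 * 200), 200, freqs = seq(8, 10, 0.5))
    b <- quick_tfr(rnorm(60 * 200), 200, freqs = seq(8, 10, 0.5))
    mean(wpli(cross_spectrum(a, b)))
  })
  expect_lt(abs(mean(vals)), 0.06)
  expect_gt(sum(vals < 0), 2)
})

test_that("epoch-shuffle surrogates are seeded, and separate coupling from null", {
  p <- make_pair(delay = 5, noise = 0.4, seed = 15, freqs = seq(3, 12, 0.5))
  s1 <- shuffle_surrogate(p$a, p$b, n_surrogates = 50, seed = 42)
  s2 <- shuffle_surrogate(p$a, p$b, n_surrogates = 50, seed = 42)
  expect_identical(s1$icoh, s2$icoh)
  cs <- cross_spectrum(p$a, p$b)
  obs <- band_mean(imaginary_coherence(cs), cs$freqs, "lf", abs = TRUE)
  null_bm <- apply(s1$icoh, 1, band_mean, freqs = s1$freqs, band = "lf",
                   abs = TRUE)
  expect_gt(obs, quantile(null_bm, 0.95))
  # uncoupled channels stay inside the null distribution
  set.seed(16)
  a0 <- quick_tfr(rnorm(40 * 200), 200, freqs = seq(3, 12, 0.5))
  b0 <- quick_tfr(rnorm(40 * 200), 200, freqs = seq(3, 12, 0.5))
  cs0 <- cross_spectrum(a0, b0)
  s0 <- shuffle_surrogate(a0, b0, n_surrogates = 100, seed = 3)
  obs0 <- band_mean(imaginary_coherence(cs0), cs0$freqs, "lf", abs = TRUE)
  null0 <- apply(s0$icoh, 1, band_mean, freqs = s0$freqs, band = "lf",
                 abs = TRUE)
  expect_lt(obs0, quantile(null0, 0.975))
  expect_error(shuffle_surrogate(a0, b0, n_surrogates = 0), "n_surrogates")
})
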