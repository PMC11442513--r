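#' Ground truth for one synthetic hemisphere
#'
#' Collects every generative parameter of a simulated hemisphere: spectral
#' peak locations, per-structure oscillation gains, directed coupling gains
#' and lag, the zero-lag common-source (volume conduction) gain, and line
#' noise amplitude. Downstream stages are tested by recovering these
#' values.
#'
#' @param subject_id,hemisphere identity fields.
#' @param lf_peak_hz low-frequency oscillation peak, within 3-12 Hz.
#' @param beta_peak_hz beta peak within 13-35 Hz, or `NA` when the
#'   hemisphere carries no beta rhythm.
#' @param lf_power_gain named vector (`STR`, `GPe`, `GPi`) of low-frequency
#'   oscillation amplitudes (a.u., >= 0).
#' @param beta_power_gain named vector of beta amplitudes (a.u., >= 0).
#' @param coupling_gain named vector with elements `str_gpi`, `str_gpe`,
#'   `gpe_gpi` (all >= 0): amplitude of the lag-delayed copy of the source
#'   oscillation mixed into the target.
#' @param coupling_lag_ms transmission delay in ms (> 0; must be at least
#'   one sample at the generation rate).
#' @param common_source_gain amplitude of a zero-lag component shared by
#'   all three structures (volume-conduction surrogate, >= 0).
#' @param line_noise_amp 50 Hz line-noise amplitude (>= 0).
#' @param bg_gain 1/f background amplitude.
#' @param osc_bandwidth_hz full width at half maximum of the narrowband
#'   oscillations (Hz).
#' @return object of class `bg_truth` (a validated list).
#' @export
ground_truth <- function(subject_id = "s01", hemisphere = "left",
                         lf_peak_hz = 8.5, beta_peak_hz = NA_real_,
                         lf_power_gain = c(STR = 1, GPe = 1, GPi = 1),
                         beta_power_gain = c(STR = 0.3, GPe = 0.3, GPi = 0.3),
                         coupling_gain = c(str_gpi = 0.6, str_gpe = 0.3,
                                           gpe_gpi = 0.2),
                         coupling_lag_ms = 25,
                         common_source_gain = 0.4,
                         line_noise_amp = 0.5,
                         bg_gain = 1,
                         osc_bandwidth_hz = 2) {
  if (!is.na(lf_peak_hz) && (lf_peak_hz < 3 || lf_peak_hz > 12)) {
    stopf("lf_peak_hz must lie in [3, 12] (got %g)", lf_peak_hz)
  }
  if (!is.na(beta_peak_hz) && (beta_peak_hz < 13 || beta_peak_hz > 35)) {
    stopf("beta_peak_hz must lie in [13, 35] (got %g)", beta_peak_hz)
  }
  lf_power_gain <- lf_power_gain[c("STR", "GPe", "GPi")]
  beta_power_gain <- beta_power_gain[c("STR", "GPe", "GPi")]
  coupling_gain <- coupling_gain[c("str_gpi", "str_gpe", "gpe_gpi")]
  gains <- c(lf_power_gain, beta_power_gain, coupling_gain,
             common_source_gain, line_noise_amp, bg_gain)
  if (any(is.na(gains)) || any(gains < 0)) {
    stopf("all gains must be present and >= 0")
  }
  if (coupling_lag_ms <= 0) stopf("coupling_lag_ms must be > 0 (got %g)", coupling_lag_ms)
  structure(
    list(subject_id = subject_id, hemisphere = hemisphere,
         lf_peak_hz = lf_peak_hz, beta_peak_hz = beta_peak_hz,
         lf_power_gain = lf_power_gain, beta_power_gain = beta_power_gain,
         coupling_gain = coupling_gain, coupling_lag_ms = coupling_lag_ms,
         common_source_gain = common_source_gain,
         line_noise_amp = line_noise_amp, bg_gain = bg_gain,
         osc_bandwidth_hz = osc_bandwidth_hz),
    class = "bg_truth"
  )
}

# Gaussian-envelope narrowband noise via FFT spectral shaping, unit SD.
# Exact spectral control and unconditionally stable, unlike narrow IIR
# band-passes at low normalized frequencies.
narrowband_noise <- function(n, fs, f0, bandwidth_hz = 2) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f[f > fs / 2] <- f[f > fs / 2] - fs
  sigma_f <- bandwidth_hz / (2 * sqrt(2 * log(2)))
  g <- exp(-((abs(f) - f0)^2) / (2 * sigma_f^2))
  y <- Re(stats::fft(X * g, inverse = TRUE)) / n
  y / stats::sd(y)
}

# 1/f^alpha background noise via FFT spectral shaping, unit SD
pink_noise <- function(n, fs, alpha = 1) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f[f > fs / 2] <- abs(f[f > fs / 2] - fs)
  f[1] <- Inf                       # remove DC
  amp <- 1 / pmax(f, 0.5)^(alpha / 2)  # flatten below 0.5 Hz to bound variance
  y <- Re(stats::fft(X * amp, inverse = TRUE)) / n
  y / stats::sd(y)
}

# integer-sample delay, zero-padded at the head
delay_samples <- function(x, k) {
  n <- length(x)
  c(rep(0, k), x[seq_len(n - k)])
}

#' Generate one synthetic hemisphere recording
#'
#' Builds an 8-contact monopolar recording whose bipolar derivation yields
#' three structure-assigned channels (STR, GPe, GPi). Each structure signal
#' is a sum of 1/f background, a narrowband low-frequency oscillation
#' (bandwidth ~2 Hz around `lf_peak_hz`), an optional beta oscillation,
#' 50 Hz line noise, a shared zero-lag component (volume-conduction
#' surrogate) and delayed copies of the source oscillations implementing
#' directed coupling: STR drives GPi and GPe, and GPe and GPi exchange a
#' symmetric bidirectional coupling, all at `coupling_lag_ms`.
#'
#' The default contact layout mirrors a pallidal electrode trajectory:
#' contacts 1-2 in GPi, 5-6 in GPe, 7-8 in STR, contacts 3-4 in border
#' territory ("other"), so that exactly three of the seven adjacent pairs
#' survive structure assignment.
#'
#' @param truth a [ground_truth()] object.
#' @param duration_s recording length in seconds (default 180, i.e., three
#'   minutes of rest activity).
#' @param fs sampling frequency in Hz (default 1000). Must be at least four
#'   times the highest oscillation frequency.
#' @param seed integer seed; the same (truth, duration, fs, seed) tuple
#'   reproduces the recording bit-for-bit.
#' @param contact_noise_sd per-contact white measurement noise SD.
#' @param layout contact-to-structure assignment for the 8 contacts.
#' @return a `bg_recording` (monopolar, 8 contacts).
#' @export
generate_hemisphere <- function(truth, duration_s = 180, fs = 1000,
                                seed = NULL, contact_noise_sd = 0.2,
                                layout = c("GPi", "GPi", "other", "other",
                                           "GPe", "GPe", "STR", "STR")) {
  stopifnot(inherits(truth, "bg_truth"))
  if (duration_s <= 0) stopf("duration_s must be > 0 (got %g)", duration_s)
  fmax <- max(c(truth$lf_peak_hz, truth$beta_peak_hz, 50), na.rm = TRUE)
  if (fs < 4 * max(c(truth$lf_peak_hz, truth$beta_peak_hz), na.rm = TRUE)) {
    stopf("fs = %g Hz is below 4x the highest oscillation frequency", fs)
  }
  lag_k <- round(truth$coupling_lag_ms / 1000 * fs)
  if (lag_k < 1) {
    stopf("coupling lag %g ms is shorter than one sample at fs = %g Hz",
          truth$coupling_lag_ms, fs)
  }
  n <- round(duration_s * fs)
  with_seed(seed, {
    bw <- truth$osc_bandwidth_hz
    f0 <- truth$lf_peak_hz
    # independent unit-SD low-frequency sources per structure
    z <- list(STR = narrowband_noise(n, fs, f0, bw),
              GPe = narrowband_noise(n, fs, f0, bw),
              GPi = narrowband_noise(n, fs, f0, bw))
    cg <- truth$coupling_gain
    y <- list()
    for (s in c("STR", "GPe", "GPi")) {
      y[[s]] <- truth$bg_gain * pink_noise(n, fs) +
        truth$lf_power_gain[[s]] * z[[s]]
      if (!is.na(truth$beta_peak_hz) && truth$beta_power_gain[[s]] > 0) {
        y[[s]] <- y[[s]] +
          truth$beta_power_gain[[s]] *
            narrowband_noise(n, fs, truth$beta_peak_hz, bw)
      }
    }
    # directed coupling: delayed unit-SD copies of the source oscillation
    y$GPi <- y$GPi + cg[["str_gpi"]] * delay_samples(z$STR, lag_k)
    y$GPe <- y$GPe + cg[["str_gpe"]] * delay_samples(z$STR, lag_k)
    y$GPi <- y$GPi + cg[["gpe_gpi"]] * delay_samples(z$GPe, lag_k)
    y$GPe <- y$GPe + cg[["gpe_gpi"]] * delay_samples(z$GPi, lag_k)
    # zero-lag shared component: same narrowband source into all structures
    if (truth$common_source_gain > 0) {
      cmn <- narrowband_noise(n, fs, f0, bw)
      for (s in names(y)) y[[s]] <- y[[s]] + truth$common_source_gain * cmn
    }
    if (truth$line_noise_amp > 0) {
      tvec <- (seq_len(n) - 1) / fs
      phi <- stats::runif(1, 0, 2 * pi)
      line <- truth$line_noise_amp * sin(2 * pi * 50 * tvec + phi)
      for (s in names(y)) y[[s]] <- y[[s]] + line
    }
    # embed structure signals into 8 monopolar contacts such that the
    # ventral-minus-dorsal difference of each fully-contained pair
    # recovers the structure signal; a common reference term cancels in
    # the bipolar derivation
    reference <- pink_noise(n, fs)
    contacts <- matrix(0, nrow = 8, ncol = n)
    pair_of <- list(GPi = c(1, 2), GPe = c(5, 6), STR = c(7, 8))
    for (s in names(pair_of)) {
      p <- pair_of[[s]]
      contacts[p[1], ] <- y[[s]] / 2
      contacts[p[2], ] <- -y[[s]] / 2
    }
    for (i in 1:8) {
      contacts[i, ] <- contacts[i, ] + reference +
        contact_noise_sd * stats::rnorm(n)
    }
    new_recording(truth$subject_id, truth$hemisphere, fs, contacts,
                  contact_structure = setNames(layout, paste0("c", 1:8)))
  })
}

#' Default cohort generator configuration
#'
#' Distributions from which per-hemisphere ground truths are drawn, and the
#' severity model. Peak-frequency distributions mirror the observed ranges
#' (low-frequency peaks centered near 8.5 Hz within 3-12 Hz; beta peaks in
#' roughly two thirds of hemispheres). A per-subject latent disease factor
#' drives the STR-to-GPi coupling gain and (mildly) the GPi's own
#' low-frequency gain: pallidal low-frequency power is thus largely
#' striatally driven, so severity tracks both GPi power and STR-GPi
#' coupling through one mechanism, while STR/GPe power and STR-to-GPe
#' coupling are drawn independently as designed nulls. Default gain ranges
#' are calibrated so the designed effects are detectable at ten subjects
#' without saturating the variance-normalized power scale (see the
#' package vignette).
#'
#' @param lf_peak_mean,lf_peak_sd truncated-normal parameters of the
#'   low-frequency peak (Hz), truncated to \[3, 12\].
#' @param beta_prob probability that a hemisphere carries a beta peak.
#' @param beta_peak_mean,beta_peak_sd truncated-normal parameters of the
#'   beta peak (Hz), truncated to \[13, 35\].
#' @param gpi_gain_base,gpi_gain_slope GPi LF gain = base + slope * latent
#'   disease factor (+ jitter).
#' @param str_gpi_base,str_gpi_slope STR->GPi coupling gain, same latent.
#' @param gain_jitter_sd hemisphere-level jitter on latent-driven gains.
#' @param null_gain_range uniform range for the independent STR/GPe LF
#'   gains.
#' @param str_gpe_range,gpe_gpi_range uniform ranges for the null coupling
#'   gains.
#' @param coupling_lag_ms transmission delay (ms).
#' @param common_source_gain,line_noise_amp confound amplitudes.
#' @param bg_gain 1/f background amplitude.
#' @param osc_bandwidth_hz oscillation bandwidth (FWHM, Hz).
#' @param beta_gain beta oscillation amplitude (all structures).
#' @param severity_intercept,severity_w_power,severity_w_coupling,severity_noise_sd
#'   severity model: intercept + w_power * mean(GPi LF gain) +
#'   w_coupling * mean(STR->GPi coupling gain) + Gaussian noise, clamped at
#'   zero (clinical scores are non-negative).
#' @param drop_hemispheres data.frame with columns `subject` (index) and
#'   `hemisphere`; these hemispheres are omitted, emulating electrodes with
#'   no striatal contact. The default drops subject 7's left hemisphere so
#'   a 10-subject bilateral cohort yields 19 hemispheres.
#' @return list of class `bg_cohort_config`.
#' @export
cohort_config <- function(lf_peak_mean = 8.5, lf_peak_sd = 2.5,
                          beta_prob = 13 / 19,
                          beta_peak_mean = 22.8, beta_peak_sd = 6.6,
                          gpi_gain_base = 0.4, gpi_gain_slope = 0.2,
                          str_gpi_base = 0.05, str_gpi_slope = 1.3,
                          gain_jitter_sd = 0.06,
                          null_gain_range = c(0.8, 1.6),
                          str_gpe_range = c(0.25, 0.55),
                          gpe_gpi_range = c(0.1, 0.3),
                          coupling_lag_ms = 25,
                          common_source_gain = 0.3,
                          line_noise_amp = 0.5,
                          bg_gain = 1.3,
                          osc_bandwidth_hz = 2,
                          beta_gain = 0.3,
                          severity_intercept = 2,
                          severity_w_power = 6,
                          severity_w_coupling = 12,
                          severity_noise_sd = 1.0,
                          drop_hemispheres = data.frame(
                            subject = 7, hemisphere = "left")) {
  cfg <- as.list(environment())
  if (severity_noise_sd < 0) stopf("severity_noise_sd must be >= 0")
  if (gain_jitter_sd < 0) stopf("gain_jitter_sd must be >= 0")
  if (any(c(lf_peak_sd, beta_peak_sd) < 0)) stopf("peak sd must be >= 0")
  class(cfg) <- "bg_cohort_config"
  cfg
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v >= lo && v <= hi) break
    }
    out[i] <- v
  }
  out
}

#' Generate a synthetic cohort of hemisphere recordings
#'
#' Draws a ground truth per hemisphere from the configured distributions,
#' simulates each recording with [generate_hemisphere()], and computes each
#' subject's severity score as an affine function of the subject-mean GPi
#' low-frequency gain and STR-to-GPi coupling gain plus Gaussian noise,
#' clamped at zero.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param hemispheres_per_subject 1 or 2.
#' @param config a [cohort_config()].
#' @param seed integer master seed; the full cohort is reproducible
#'   bit-for-bit from it.
#' @param duration_s,fs passed to [generate_hemisphere()].
#' @return object of class `bg_cohort`: list with `recordings` (list of
#'   `bg_recording`), `truths` (list of `bg_truth`, aligned one-to-one),
#'   `subjects` (data.frame with `subject_id`, `severity`), `seed`,
#'   `config`.
#' @export
generate_cohort <- function(n_subjects = 10, hemispheres_per_subject = 2,
                            config = cohort_config(), seed = 1,
                            duration_s = 180, fs = 1000) {
  if (n_subjects < 1) stopf("n_subjects must be >= 1")
  stopifnot(inherits(config, "bg_cohort_config"))
  hemis <- c("left", "right")[seq_len(hemispheres_per_subject)]
  seeds <- derive_seeds(seed, n_subjects * hemispheres_per_subject + 1)
  truths <- list()
  recordings <- list()
  severity <- numeric(n_subjects)
  subject_ids <- sprintf("s%02d", seq_len(n_subjects))
  with_seed(seeds[length(seeds)], {
    for (si in seq_len(n_subjects)) {
      latent <- stats::runif(1)
      gpi_gains <- c()
      cpl_gains <- c()
      for (hi in seq_along(hemis)) {
        h <- hemis[hi]
        dropped <- nrow(config$drop_hemispheres) > 0 &&
          any(config$drop_hemispheres$subject == si &
                config$drop_hemispheres$hemisphere == h)
        lf_peak <- rtrunc_norm(1, config$lf_peak_mean, config$lf_peak_sd, 3, 12)
        beta_peak <- if (stats::runif(1) < config$beta_prob) {
          rtrunc_norm(1, config$beta_peak_mean, config$beta_peak_sd, 13, 35)
        } else NA_real_
        g_gpi <- max(config$gpi_gain_base + config$gpi_gain_slope * latent +
                       stats::rnorm(1, 0, config$gain_jitter_sd), 0.05)
        g_cpl <- max(config$str_gpi_base + config$str_gpi_slope * latent +
                       stats::rnorm(1, 0, config$gain_jitter_sd), 0)
        g_str <- stats::runif(1, config$null_gain_range[1], config$null_gain_range[2])
        g_gpe <- stats::runif(1, config$null_gain_range[1], config$null_gain_range[2])
        g_str_gpe <- stats::runif(1, config$str_gpe_range[1], config$str_gpe_range[2])
        g_gpe_gpi <- stats::runif(1, config$gpe_gpi_range[1], config$gpe_gpi_range[2])
        if (dropped) next
        gpi_gains <- c(gpi_gains, g_gpi)
        cpl_gains <- c(cpl_gains, g_cpl)
        truths[[length(truths) + 1]] <- ground_truth(
          subject_id = subject_ids[si], hemisphere = h,
          lf_peak_hz = lf_peak, beta_peak_hz = beta_peak,
          lf_power_gain = c(STR = g_str, GPe = g_gpe, GPi = g_gpi),
          beta_power_gain = c(STR = config$beta_gain, GPe = config$beta_gain,
                              GPi = config$beta_gain),
          coupling_gain = c(str_gpi = g_cpl, str_gpe = g_str_gpe,
                            gpe_gpi = g_gpe_gpi),
          coupling_lag_ms = config$coupling_lag_ms,
          common_source_gain = config$common_source_gain,
          line_noise_amp = config$line_noise_amp,
          bg_gain = config$bg_gain,
          osc_bandwidth_hz = config$osc_bandwidth_hz)
      }
      if (length(gpi_gains) == 0) {
        severity[si] <- NA_real_
        next
      }
      severity[si] <- max(0, config$severity_intercept +
                            config$severity_w_power * mean(gpi_gains) +
                            config$severity_w_coupling * mean(cpl_gains) +
                            stats::rnorm(1, 0, config$severity_noise_sd))
    }
  })
  for (i in seq_along(truths)) {
    recordings[[i]] <- generate_hemisphere(truths[[i]], duration_s, fs,
                                           seed = seeds[i])
  }
  structure(
    list(recordings = recordings, truths = truths,
         subjects = data.frame(subject_id = subject_ids,
                               severity = severity),
         seed = seed, config = config),
    class = "bg_cohort"
  )
}

#' @export
print.bg_cohort <- function(x, ...) {
  cat(sprintf("<bg_cohort> %d subjects, %d hemisphere recordings (seed %s)\n",
              nrow(x$subjects), length(x$recordings), x$seed))
  invisible(x)
}

#' Write a cohort's ground truth and provenance to disk
#'
#' Recordings go to the native binary + sidecar format, ground truths to a
#' CSV table, and the full generator configuration plus seed to a JSON
#' provenance file.
#'
#' @param cohort a `bg_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$recordings)) {
    rec <- cohort$recordings[[i]]
    base <- file.path(dir, sprintf("%s_%s", rec$subject_id, rec$hemisphere))
    write_recording(rec, paste0(base, ".bin"))
  }
  tt <- do.call(rbind, lapply(cohort$truths, function(tr) {
    data.frame(subject_id = tr$subject_id, hemisphere = tr$hemisphere,
               lf_peak_hz = tr$lf_peak_hz, beta_peak_hz = tr$beta_peak_hz,
               lf_gain_str = tr$lf_power_gain[["STR"]],
               lf_gain_gpe = tr$lf_power_gain[["GPe"]],
               lf_gain_gpi = tr$lf_power_gain[["GPi"]],
               coupling_str_gpi = tr$coupling_gain[["str_gpi"]],
               coupling_str_gpe = tr$coupling_gain[["str_gpe"]],
               coupling_gpe_gpi = tr$coupling_gain[["gpe_gpi"]],
               coupling_lag_ms = tr$coupling_lag_ms,
               common_source_gain = tr$common_source_gain)
  }))
  utils::write.csv(tt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  prov <- list(seed = cohort$seed,
               config = cohort$config[setdiff(names(cohort$config),
                                              "drop_hemispheres")],
               drop_hemispheres = cohort$config$drop_hemispheres)
  jsonlite::write_json(prov, file.path(dir, "generator_config.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
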