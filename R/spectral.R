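#' Default analysis frequency grid
#'
#' 1-98 Hz in 0.5 Hz steps, matching the spectral resolution of 2 s epochs
#' and the conditioning band.
#'
#' @param from,to,by grid limits and step in Hz.
#' @return numeric vector of frequencies.
#' @export
default_freqs <- function(from = 1, to = 98, by = 0.5) {
  seq(from, to, by = by)
}

#' Morlet wavelet time-frequency transform
#'
#' Convolves the continuous conditioned series with L2-normalized complex
#' Morlet wavelets (constant `n_cycles` across frequency) via FFT, then
#' indexes the coefficients by epoch. Epochs lying within one wavelet
#' half-length (at the lowest, i.e. longest, analysis frequency) of either
#' recording edge are flagged invalid and excluded from all downstream
#' averages, so every retained epoch is free of convolution edge effects at
#' every analysis frequency.
#'
#' @param ep a [epoch()]ed channel.
#' @param freqs analysis frequencies (Hz), all below Nyquist.
#' @param n_cycles wavelet width in cycles (>= 3 for a well-behaved
#'   Gaussian envelope).
#' @return object of class `bg_tfr`: complex coefficient matrix `coef`
#'   (time x frequency), `freqs`, `fs`, `epoch_starts`, `epoch_len`,
#'   `valid_epochs` (logical), `structure`, `signal_var`.
#' @export
morlet_transform <- function(ep, freqs = default_freqs(), n_cycles = 7) {
  stopifnot(inherits(ep, "bg_epochs"))
  fs <- ep$fs
  if (max(freqs) >= fs / 2) {
    stopf("max analysis frequency %g Hz is not below Nyquist (%g Hz)",
          max(freqs), fs / 2)
  }
  if (n_cycles < 3) stopf("n_cycles must be >= 3 (got %g)", n_cycles)
  x <- ep$samples
  n <- length(x)
  sigma_t <- n_cycles / (2 * pi * freqs)
  half_len <- pmin(ceiling(3.5 * sigma_t * fs), n - 1L)
  nfft <- next_pow2(n + 2 * max(half_len))
  X <- stats::fft(c(x, rep(0, nfft - n)))
  coef <- matrix(0i, nrow = n, ncol = length(freqs))
  for (j in seq_along(freqs)) {
    h <- half_len[j]
    tt <- (-h:h) / fs
    w <- exp(2i * pi * freqs[j] * tt) * exp(-tt^2 / (2 * sigma_t[j]^2))
    w <- w / sqrt(sum(Mod(w)^2))
    # wrap the wavelet so index 1 holds t = 0 and negative times sit at
    # the tail: circular cross-correlation then aligns coefficients with
    # sample times
    ww <- complex(length.out = nfft)
    ww[1:(h + 1)] <- w[(h + 1):(2 * h + 1)]
    ww[(nfft - h + 1):nfft] <- w[1:h]
    cc <- stats::fft(X * Conj(stats::fft(ww)), inverse = TRUE) / nfft
    coef[, j] <- cc[1:n]
  }
  edge <- max(half_len)
  valid_epochs <- (ep$epoch_starts > edge) &
    (ep$epoch_starts + ep$epoch_len - 1 <= n - edge)
  if (!any(valid_epochs)) {
    stopf("no epoch clears the wavelet edge zone (%d samples); use a longer recording",
          edge)
  }
  structure(
    list(coef = coef, freqs = freqs, fs = fs, n_cycles = n_cycles,
         epoch_starts = ep$epoch_starts, epoch_len = ep$epoch_len,
         valid_epochs = valid_epochs, structure = ep$structure,
         signal_var = stats::var(x)),
    class = "bg_tfr"
  )
}

# row indices of all valid-epoch samples, plus the epoch id of each row
tfr_epoch_rows <- function(tfr) {
  starts <- tfr$epoch_starts[tfr$valid_epochs]
  len <- tfr$epoch_len
  rows <- as.vector(vapply(starts, function(s) s:(s + len - 1L),
                           integer(len)))
  list(rows = rows,
       epoch_id = rep(seq_along(starts), each = len),
       n_epochs = length(starts))
}

#' Power spectrum from wavelet coefficients
#'
#' Power at each frequency is the mean squared coefficient magnitude over
#' all valid-epoch samples. With `normalize = TRUE` (default) the spectrum
#' is divided by the variance of the time-domain signal — equivalent to
#' scaling the channel to unit standard deviation before the transform —
#' which corrects for electrode impedance differences and makes spectra
#' comparable across channels and subjects.
#'
#' @param tfr a [morlet_transform()] result.
#' @param normalize divide by signal variance (default `TRUE`).
#' @param bands named list of 2-element frequency ranges for band
#'   averaging; defaults to low-frequency 3-12 Hz and beta 13-35 Hz.
#' @return object of class `bg_spectrum`: `freqs`, `power`, `band_means`,
#'   `structure`, `n_epochs`.
#' @export
power_spectrum <- function(tfr, normalize = TRUE, bands = BG_BANDS) {
  stopifnot(inherits(tfr, "bg_tfr"))
  idx <- tfr_epoch_rows(tfr)
  p <- colMeans(Mod(tfr$coef[idx$rows, , drop = FALSE])^2)
  if (normalize) {
    if (tfr$signal_var <= .Machine$double.eps) {
      stopf("signal variance is zero; variance normalization is undefined")
    }
    p <- p / tfr$signal_var
  }
  band_means <- vapply(bands, function(b) {
    sel <- tfr$freqs >= b[1] & tfr$freqs <= b[2]
    if (!any(sel)) return(NA_real_)
    mean(p[sel])
  }, numeric(1))
  structure(
    list(freqs = tfr$freqs, power = p, band_means = band_means,
         structure = tfr$structure, n_epochs = idx$n_epochs),
    class = "bg_spectrum"
  )
}

# 1/f trend removal: linear fit of log power on log frequency over the
# full grid, excluding the notch band; returns log-power residuals
flatten_spectrum <- function(freqs, power, notch_band = c(48, 52)) {
  lp <- log(pmax(power, .Machine$double.xmin))
  lf <- log(freqs)
  fit_sel <- freqs < notch_band[1] | freqs > notch_band[2]
  fit <- stats::lm.fit(cbind(1, lf[fit_sel]), lp[fit_sel])
  lp - (fit$coefficients[1] + fit$coefficients[2] * lf)
}

#' Detect an oscillatory peak in a frequency band
#'
#' Removes a 1/f trend (linear fit of log power on log frequency over the
#' whole grid, excluding the notch band), then returns the highest in-band
#' local maximum whose topographic prominence exceeds
#' `prominence_frac` times the flattened in-band range. Absence of a
#' qualifying peak is a valid outcome (`NULL`).
#'
#' @param spec a [power_spectrum()] result.
#' @param band `"lf"`, `"beta"`, or a 2-element numeric range (Hz).
#' @param prominence_frac prominence threshold as a fraction of the
#'   flattened in-band dynamic range (default 0.05).
#' @param notch_band frequency range excluded from the 1/f fit.
#' @return `NULL`, or a list with `freq_hz`, `prominence`, `height`
#'   (flattened log-power at the peak).
#' @export
detect_peak <- function(spec, band = "lf", prominence_frac = 0.05,
                        notch_band = c(48, 52)) {
  stopifnot(inherits(spec, "bg_spectrum"))
  if (is.character(band)) band <- BG_BANDS[[match.arg(band, names(BG_BANDS))]]
  flat <- flatten_spectrum(spec$freqs, spec$power, notch_band)
  in_band <- which(spec$freqs >= band[1] & spec$freqs <= band[2])
  if (length(in_band) < 3) stopf("band [%g, %g] covers fewer than 3 bins", band[1], band[2])
  rng <- diff(range(flat[in_band]))
  if (rng < 1e-8) return(NULL)  # numerically flat after 1/f removal
  n <- length(flat)
  best <- NULL
  for (i in in_band) {
    if (i == 1 || i == n) next
    if (!(flat[i] > flat[i - 1] && flat[i] >= flat[i + 1])) next
    # topographic prominence: drop to the key saddle on each side
    left_min <- flat[i]
    k <- i - 1
    while (k >= 1 && flat[k] < flat[i]) {
      left_min <- min(left_min, flat[k])
      k <- k - 1
    }
    if (k < 1) left_min <- min(flat[1:i])
    right_min <- flat[i]
    k <- i + 1
    while (k <= n && flat[k] < flat[i]) {
      right_min <- min(right_min, flat[k])
      k <- k + 1
    }
    if (k > n) right_min <- min(flat[i:n])
    prom <- flat[i] - max(left_min, right_min)
    if (prom > prominence_frac * rng) {
      if (is.null(best) || flat[i] > best$height) {
        best <- list(freq_hz = spec$freqs[i], prominence = prom,
                     height = flat[i])
      }
    }
  }
  best
}

#' Flatten spectra and align them on their individual peak frequencies
#'
#' 1/f-flattens each spectrum and shifts its frequency axis so the
#' detected in-band peak sits at relative frequency zero, for group-level
#' display of spectra whose peaks vary across hemispheres. Spectra without
#' a detected peak are skipped (recorded in `skipped`).
#'
#' @param specs list of `bg_spectrum`.
#' @param band band to align in (see [detect_peak()]).
#' @param prominence_frac forwarded to [detect_peak()].
#' @return list with `rel_freqs`, `aligned` (spectra x relative frequency
#'   matrix of flattened log power, NA where unobserved), `mean` (group
#'   mean), `peak_freqs`, `skipped` (indices).
#' @export
flatten_align <- function(specs, band = "lf", prominence_frac = 0.05) {
  stopifnot(length(specs) >= 1)
  peaks <- lapply(specs, detect_peak, band = band,
                  prominence_frac = prominence_frac)
  has_peak <- !vapply(peaks, is.null, logical(1))
  if (!any(has_peak)) stopf("no spectrum has a detected peak in the band")
  df <- stats::median(diff(specs[[1]]$freqs))
  keep <- which(has_peak)
  shifted <- lapply(keep, function(i) {
    flat <- flatten_spectrum(specs[[i]]$freqs, specs[[i]]$power)
    list(rel = specs[[i]]$freqs - peaks[[i]]$freq_hz, val = flat)
  })
  lo <- min(vapply(shifted, function(s) min(s$rel), numeric(1)))
  hi <- max(vapply(shifted, function(s) max(s$rel), numeric(1)))
  rel_freqs <- seq(lo, hi, by = df)
  aligned <- matrix(NA_real_, nrow = length(keep), ncol = length(rel_freqs))
  for (r in seq_along(shifted)) {
    j <- round((shifted[[r]]$rel - lo) / df) + 1L
    aligned[r, j] <- shifted[[r]]$val
  }
  list(rel_freqs = rel_freqs, aligned = aligned,
       mean = colMeans(aligned, na.rm = TRUE),
       peak_freqs = vapply(peaks[keep], `[[`, numeric(1), "freq_hz"),
       skipped = which(!has_peak))
}
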