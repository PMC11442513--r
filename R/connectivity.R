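#' Cross-spectrum between two wavelet-transformed channels
#'
#' Per-epoch cross-spectra are the in-epoch time averages of
#' `coef_a * Conj(coef_b)`; the reported cross-spectral density is their
#' mean across epochs. Per-epoch observations are retained because the
#' debiased weighted phase-lag index and the epoch-shuffle surrogates are
#' expectation-based measures that need repeated observations.
#'
#' @param tfr_a,tfr_b [morlet_transform()] results with identical epoching
#'   and frequency grids.
#' @return object of class `bg_cross_spectrum`: `pair`, `freqs`, `S_ab`
#'   (complex), `S_aa`, `S_bb` (real), `per_epoch_S_ab` (complex, epochs x
#'   freqs), `n_epochs`, `fs`.
#' @export
cross_spectrum <- function(tfr_a, tfr_b) {
  stopifnot(inherits(tfr_a, "bg_tfr"), inherits(tfr_b, "bg_tfr"))
  if (!isTRUE(all.equal(tfr_a$freqs, tfr_b$freqs))) {
    stopf("frequency grids differ between channels")
  }
  if (length(tfr_a$epoch_starts) != length(tfr_b$epoch_starts) ||
      any(tfr_a$epoch_starts != tfr_b$epoch_starts)) {
    stopf("epoch structure differs between channels")
  }
  valid <- tfr_a$valid_epochs & tfr_b$valid_epochs
  ta <- tfr_a; ta$valid_epochs <- valid
  idx <- tfr_epoch_rows(ta)
  A <- tfr_a$coef[idx$rows, , drop = FALSE]
  B <- tfr_b$coef[idx$rows, , drop = FALSE]
  P <- A * Conj(B)
  ne <- idx$n_epochs
  mean_by_epoch <- function(m) {
    rowsum(m, idx$epoch_id, reorder = TRUE) / ta$epoch_len
  }
  per_ab <- mean_by_epoch(Re(P)) + 1i * mean_by_epoch(Im(P))
  per_aa <- mean_by_epoch(Mod(A)^2)
  per_bb <- mean_by_epoch(Mod(B)^2)
  structure(
    list(pair = c(tfr_a$structure %||% "a", tfr_b$structure %||% "b"),
         freqs = tfr_a$freqs,
         S_ab = colMeans(per_ab), S_aa = colMeans(per_aa),
         S_bb = colMeans(per_bb),
         per_epoch_S_ab = per_ab, n_epochs = ne, fs = tfr_a$fs),
    class = "bg_cross_spectrum"
  )
}

#' Imaginary part of coherence
#'
#' `Im(S_ab / sqrt(S_aa * S_bb))` per frequency. The imaginary part
#' reflects connectivity without zero phase lag and is therefore immune to
#' instantaneous volume conduction, at the price of also discounting any
#' genuinely zero-lag interaction.
#'
#' @param cs a [cross_spectrum()].
#' @return numeric vector over `cs$freqs`, in \[-1, 1\].
#' @export
imaginary_coherence <- function(cs) {
  stopifnot(inherits(cs, "bg_cross_spectrum"))
  denom <- cs$S_aa * cs$S_bb
  if (any(denom <= 0)) {
    stopf("zero auto-spectrum at %d frequency bin(s); coherency undefined",
          sum(denom <= 0))
  }
  Im(cs$S_ab / sqrt(denom))
}

#' Magnitude-squared coherence (diagnostic)
#'
#' `|S_ab|^2 / (S_aa * S_bb)`. Sensitive to volume conduction; used to
#' demonstrate that zero-lag leakage inflates magnitude coherence while
#' leaving the imaginary part at surrogate level.
#'
#' @param cs a [cross_spectrum()].
#' @return numeric vector over `cs$freqs`, in \[0, 1\].
#' @export
magnitude_coherence <- function(cs) {
  stopifnot(inherits(cs, "bg_cross_spectrum"))
  Mod(cs$S_ab)^2 / (cs$S_aa * cs$S_bb)
}

#' Debiased weighted phase-lag index
#'
#' From the per-epoch imaginary cross-spectra `I_j(f)`, the debiased wPLI
#' sums products over distinct epoch pairs:
#' `(sum I_j)^2 - sum I_j^2` over `(sum |I_j|)^2 - sum I_j^2`.
#' The estimator's null distribution is centered at zero and individual
#' estimates may be slightly negative; this hallmark distinguishes it from
#' the positively-biased plain wPLI. When every per-epoch imaginary part is
#' zero (e.g., a channel paired with itself) the value is 0 by the
#' degenerate-input rule, with a warning.
#'
#' @param cs a [cross_spectrum()] with at least 2 epochs.
#' @return numeric vector over `cs$freqs`, in \[-1, 1\].
#' @export
wpli <- function(cs) {
  stopifnot(inherits(cs, "bg_cross_spectrum"))
  if (cs$n_epochs < 2) stopf("debiased wPLI needs >= 2 epochs (got %d)", cs$n_epochs)
  imx <- Im(cs$per_epoch_S_ab)
  dwpli_from_im(imx)
}

dwpli_from_im <- function(imx, warn = TRUE) {
  s1 <- colSums(imx)
  s2 <- colSums(imx^2)
  sa <- colSums(abs(imx))
  num <- s1^2 - s2
  den <- sa^2 - s2
  out <- numeric(length(s1))
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  if (warn && any(!ok)) {
    warnf("all per-epoch imaginary parts are zero at %d bin(s); wPLI set to 0",
          sum(!ok))
  }
  out
}

#' Band average of a frequency-resolved measure
#'
#' @param x numeric vector over `freqs`.
#' @param freqs frequency grid (Hz).
#' @param band `"lf"`, `"beta"` or a 2-element range.
#' @param abs take `|x|` before averaging (appropriate for the imaginary
#'   part of coherence, whose sign only encodes lead/lag).
#' @return scalar band mean.
#' @export
band_mean <- function(x, freqs, band = "lf", abs = FALSE) {
  if (is.character(band)) band <- BG_BANDS[[match.arg(band, names(BG_BANDS))]]
  sel <- freqs >= band[1] & freqs <= band[2]
  if (!any(sel)) stopf("no frequency bins inside [%g, %g] Hz", band[1], band[2])
  if (abs) mean(base::abs(x[sel])) else mean(x[sel])
}

#' Epoch-shuffle surrogate distributions for coupling measures
#'
#' For each surrogate, the epoch sequence of channel b is randomly permuted
#' relative to channel a. This preserves both channels' marginal spectra
#' while destroying consistent cross-epoch phase relations, yielding the
#' null distribution of each coupling measure under "no coupling beyond
#' chance".
#'
#' @param tfr_a,tfr_b the wavelet coefficients the observed
#'   [cross_spectrum()] was computed from.
#' @param n_surrogates number of shuffles (>= 1; 1000 by default in the
#'   pipeline, smaller values are fine for tests).
#' @param seed integer seed; same seed, same draws.
#' @param measures subset of `c("icoh", "wpli")`.
#' @return list with matrices `icoh` and/or `wpli` of size
#'   `n_surrogates x n_freqs`, plus `freqs`.
#' @export
shuffle_surrogate <- function(tfr_a, tfr_b, n_surrogates = 1000, seed = NULL,
                              measures = c("icoh", "wpli")) {
  if (n_surrogates < 1) stopf("n_surrogates must be >= 1")
  measures <- match.arg(measures, several.ok = TRUE)
  valid <- tfr_a$valid_epochs & tfr_b$valid_epochs
  ta <- tfr_a; ta$valid_epochs <- valid
  idx <- tfr_epoch_rows(ta)
  if (idx$n_epochs < 2) stopf("epoch shuffling needs >= 2 valid epochs")
  A <- tfr_a$coef[idx$rows, , drop = FALSE]
  B <- tfr_b$coef[idx$rows, , drop = FALSE]
  ne <- idx$n_epochs
  len <- tfr_a$epoch_len
  nf <- length(tfr_a$freqs)
  # auto-spectra are invariant under epoch re-pairing
  S_aa <- colMeans(Mod(A)^2)
  S_bb <- colMeans(Mod(B)^2)
  # precompute the epoch-pair cross table T[i, j, f] = mean_t A_i conj(B_j);
  # every surrogate then reduces to an O(ne x nf) lookup
  Tarr <- array(0i, dim = c(ne, ne, nf))
  for (f in seq_len(nf)) {
    Af <- matrix(A[, f], nrow = len)
    Bf <- matrix(B[, f], nrow = len)
    Tarr[, , f] <- (t(Af) %*% Conj(Bf)) / len
  }
  out <- list(freqs = tfr_a$freqs)
  for (m in measures) out[[m]] <- matrix(NA_real_, n_surrogates, nf)
  i_seq <- seq_len(ne)
  f_off <- (seq_len(nf) - 1L) * ne * ne
  with_seed(seed, {
    for (s in seq_len(n_surrogates)) {
      perm <- sample.int(ne)
      base <- i_seq + (perm - 1L) * ne
      vals <- matrix(Tarr[outer(base, f_off, "+")], nrow = ne)
      per_im <- Im(vals)
      if ("icoh" %in% measures) {
        out$icoh[s, ] <- colMeans(per_im) / sqrt(S_aa * S_bb)
      }
      if ("wpli" %in% measures) {
        out$wpli[s, ] <- dwpli_from_im(per_im, warn = FALSE)
      }
    }
  })
  out
}

#' Restrict wavelet coefficients to a subset of the frequency grid
#'
#' Useful before [shuffle_surrogate()] when the null distribution is only
#' needed inside the analysis bands.
#'
#' @param tfr a `bg_tfr`.
#' @param sel logical or integer index into `tfr$freqs`.
#' @return the restricted `bg_tfr`.
#' @export
tfr_subset_freqs <- function(tfr, sel) {
  tfr$coef <- tfr$coef[, sel, drop = FALSE]
  tfr$freqs <- tfr$freqs[sel]
  tfr
}
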