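#' Preprocessing configuration
#'
#' Signal-conditioning parameters: target rate 200 Hz, zero-phase high-pass
#' at 1 Hz, low-pass at 98 Hz and 48-52 Hz band-stop, with non-overlapping
#' 2 s epochs. Filters are forward-backward (zero-phase) Butterworth;
#' `filter_order` is the per-pass order. Zero phase matters here: any phase
#' distortion would leak into the phase-based coupling measures downstream.
#'
#' @param fs_out output sampling rate (Hz).
#' @param hp_hz high-pass cutoff (Hz).
#' @param lp_hz low-pass cutoff (Hz).
#' @param notch_band two-element band-stop range (Hz).
#' @param filter_order per-pass Butterworth order.
#' @param epoch_length_s epoch length in seconds.
#' @param artifact_z when non-`NULL`, samples with |z| above this threshold
#'   on the conditioned signal are auto-masked as artifacts.
#' @return list of class `bg_preprocess_config`.
#' @export
preprocess_config <- function(fs_out = 200, hp_hz = 1, lp_hz = 98,
                              notch_band = c(48, 52), filter_order = 4,
                              epoch_length_s = 2, artifact_z = NULL) {
  cfg <- as.list(environment())
  stopifnot(fs_out > 0, hp_hz > 0, lp_hz > hp_hz, length(notch_band) == 2)
  class(cfg) <- "bg_preprocess_config"
  cfg
}

zero_phase <- function(filt, x) {
  as.numeric(signal::filtfilt(filt, x))
}

#' Condition a raw channel: anti-aliased decimation and zero-phase filtering
#'
#' Applies an anti-alias low-pass at the configured low-pass cutoff before
#' downsampling to `fs_out`, then zero-phase high-pass and band-stop
#' (notch) filters at the output rate. When the input rate is an integer
#' multiple of `fs_out`, decimation keeps every k-th sample; otherwise the
#' anti-aliased signal is linearly interpolated onto the output grid.
#'
#' @param x numeric vector (one channel) or a `bg_bipolar` channel.
#' @param fs_in input sampling rate (Hz). Ignored (taken from the object)
#'   when `x` is a `bg_bipolar`.
#' @param cfg a [preprocess_config()].
#' @return numeric vector of length `round(length(x) * fs_out / fs_in)`
#'   with attributes `fs` and `structure` (when available).
#' @export
condition <- function(x, fs_in = NULL, cfg = preprocess_config()) {
  struct <- NULL
  if (inherits(x, "bg_bipolar")) {
    struct <- x$structure
    fs_in <- x$fs
    x <- x$samples
  }
  if (is.null(fs_in)) stopf("fs_in is required for plain numeric input")
  if (fs_in < 2 * cfg$lp_hz) {
    stopf("fs_in = %g Hz cannot honor a %g Hz low-pass (need >= %g Hz)",
          fs_in, cfg$lp_hz, 2 * cfg$lp_hz)
  }
  n_in <- length(x)
  fs_out <- cfg$fs_out
  # low-pass doubles as the anti-alias filter, applied at the input rate
  w_lp <- cfg$lp_hz / (fs_in / 2)
  if (w_lp < 0.95) {
    x <- zero_phase(signal::butter(cfg$filter_order, w_lp, "low"), x)
  }
  if (fs_in != fs_out) {
    ratio <- fs_in / fs_out
    n_out <- round(n_in * fs_out / fs_in)
    if (abs(ratio - round(ratio)) < 1e-9) {
      x <- x[seq(1, by = round(ratio), length.out = n_out)]
    } else {
      t_in <- (seq_len(n_in) - 1) / fs_in
      t_out <- (seq_len(n_out) - 1) / fs_out
      x <- stats::approx(t_in, x, xout = t_out, rule = 2)$y
    }
  }
  x <- zero_phase(signal::butter(cfg$filter_order, cfg$hp_hz / (fs_out / 2),
                                 "high"), x)
  x <- zero_phase(signal::butter(cfg$filter_order / 2,
                                 cfg$notch_band / (fs_out / 2), "stop"), x)
  attr(x, "fs") <- fs_out
  attr(x, "structure") <- struct
  x
}

#' Segment a conditioned channel into artifact-free epochs
#'
#' Cuts the conditioned series into contiguous, non-overlapping epochs.
#' Epochs intersecting any masked sample are dropped. The continuous
#' samples are retained alongside the epoch index so that time-frequency
#' transforms can convolve the unbroken series and only then gather
#' epoch-wise observations.
#'
#' @param x conditioned channel from [condition()] (or any numeric vector).
#' @param epoch_length_s epoch length in seconds.
#' @param artifact_mask optional logical vector (TRUE = artifact), same
#'   length as `x`.
#' @param fs sampling rate; defaults to the `fs` attribute of `x`.
#' @param structure optional structure label carried through.
#' @return object of class `bg_epochs`: continuous `samples`, `fs`,
#'   `epoch_starts` (sample index of each retained epoch), `epoch_len`
#'   (samples), `structure`, and `n_dropped`.
#' @export
epoch <- function(x, epoch_length_s = 2, artifact_mask = NULL, fs = NULL,
                  structure = NULL) {
  fs <- fs %||% attr(x, "fs")
  structure <- structure %||% attr(x, "structure")
  if (is.null(fs)) stopf("fs is required (no fs attribute on input)")
  len <- round(epoch_length_s * fs)
  n <- length(x)
  if (n < len) {
    stopf("series (%d samples) is shorter than one epoch (%d samples)", n, len)
  }
  starts <- seq(1, n - len + 1, by = len)
  keep <- rep(TRUE, length(starts))
  if (!is.null(artifact_mask)) {
    stopifnot(length(artifact_mask) == n)
    for (i in seq_along(starts)) {
      idx <- starts[i]:(starts[i] + len - 1)
      if (any(artifact_mask[idx])) keep[i] <- FALSE
    }
  }
  if (!any(keep)) stopf("all %d epochs intersect masked artifacts", length(starts))
  structure(
    list(samples = as.numeric(x), fs = fs, epoch_starts = starts[keep],
         epoch_len = len, epoch_length_s = epoch_length_s,
         structure = structure, n_dropped = sum(!keep)),
    class = "bg_epochs"
  )
}

#' Amplitude-threshold artifact mask
#'
#' Flags samples whose absolute z-score on the conditioned signal exceeds
#' `z`. A deliberately simple automatic mask; off by default in the
#' pipeline.
#'
#' @param x conditioned channel.
#' @param z threshold (default 5).
#' @return logical vector, TRUE at artifact samples.
#' @export
artifact_mask_z <- function(x, z = 5) {
  abs((x - mean(x)) / stats::sd(x)) > z
}
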