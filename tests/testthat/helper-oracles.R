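# Independent oracles and fixture builders shared across tests.
# These deliberately avoid the package's estimation path: Welch/DFT-segment
# spectra for coherency, a closed-form / OLS-fitted VAR route for spectral
# Granger causality, and a brute-force Benjamini-Hochberg step-up.

# DFT-segment (Welch, Hann window) auto/cross spectra
welch_spectra <- function(x, y, fs, seg_s = 2) {
  len <- round(seg_s * fs)
  ns <- floor(length(x) / len)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, len - 1) / (len - 1))
  Sxx <- Syy <- 0
  Sxy <- 0
  for (k in seq_len(ns)) {
    idx <- ((k - 1) * len + 1):(k * len)
    X <- stats::fft(x[idx] * w)
    Y <- stats::fft(y[idx] * w)
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + X * Conj(Y)
  }
  f <- (seq_len(len) - 1) * fs / len
  keep <- f > 0 & f <= fs / 2
  list(freqs = f[keep], Sxx = Sxx[keep] / ns, Syy = Syy[keep] / ns,
       Sxy = Sxy[keep] / ns)
}

welch_icoh <- function(x, y, fs, seg_s = 2) {
  w <- welch_spectra(x, y, fs, seg_s)
  list(freqs = w$freqs, icoh = Im(w$Sxy / sqrt(w$Sxx * w$Syy)))
}

# simulate a bivariate VAR(1); rows of A: x_t equation, y_t equation
simulate_var1 <- function(A, n, seed) {
  withr::with_seed(seed, {
    X <- matrix(0, 2, n)
    e <- matrix(stats::rnorm(2 * n), 2, n)
    for (t in 2:n) X[, t] <- A %*% X[, t - 1] + e[, t]
    X
  })
}

# parametric spectral Granger causality oracle: OLS VAR(1) fit, then
# Geweke's formula from the fitted transfer function
var1_granger_oracle <- function(X, fs, freqs) {
  n <- ncol(X)
  Y <- t(X[, 2:n])
  Z <- t(X[, 1:(n - 1)])
  B <- solve(crossprod(Z), crossprod(Z, Y))
  E <- Y - Z %*% B
  Sig <- crossprod(E) / (nrow(Y) - 2)
  fwd <- rev <- numeric(length(freqs))
  for (k in seq_along(freqs)) {
    z1 <- exp(-2i * pi * freqs[k] / fs)
    H <- solve(diag(2) - t(B) * z1)
    S <- H %*% Sig %*% Conj(t(H))
    s22 <- Re(S[2, 2])
    s11 <- Re(S[1, 1])
    fwd[k] <- log(s22 / (s22 - (Sig[1, 1] - Sig[1, 2]^2 / Sig[2, 2]) *
                            Mod(H[2, 1])^2))
    rev[k] <- log(s11 / (s11 - (Sig[2, 2] - Sig[1, 2]^2 / Sig[1, 1]) *
                            Mod(H[1, 2])^2))
  }
  list(freqs = freqs, fwd = fwd, rev = rev)
}

# analytic spectral matrix and Geweke causality of a known VAR(1)
var1_true_spectrum <- function(A, Sig, fs, freqs) {
  s11 <- s22 <- numeric(length(freqs))
  s12 <- complex(length.out = length(freqs))
  fwd <- rev <- numeric(length(freqs))
  for (k in seq_along(freqs)) {
    z1 <- exp(-2i * pi * freqs[k] / fs)
    H <- solve(diag(2) - A * z1)
    S <- H %*% Sig %*% Conj(t(H))
    s11[k] <- Re(S[1, 1]); s22[k] <- Re(S[2, 2]); s12[k] <- S[1, 2]
    fwd[k] <- log(s22[k] / (s22[k] - (Sig[1, 1] - Sig[1, 2]^2 / Sig[2, 2]) *
                               Mod(H[2, 1])^2))
    rev[k] <- log(s11[k] / (s11[k] - (Sig[2, 2] - Sig[1, 2]^2 / Sig[1, 1]) *
                               Mod(H[1, 2])^2))
  }
  list(freqs = freqs, s11 = s11, s22 = s22, s12 = s12, fwd = fwd, rev = rev)
}

# brute-force Benjamini-Hochberg adjusted p-values
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  adj[o] <- pmin(rev(cummin(rev(p[o] * n / seq_len(n)))), 1)
  adj
}

# wrap a plain numeric channel into the wavelet pipeline
quick_tfr <- function(x, fs, freqs = default_freqs(), epoch_s = 2,
                      n_cycles = 7) {
  morlet_transform(epoch(x, epoch_s, fs = fs), freqs, n_cycles)
}

# small conditioned structure-pair fixture from the generator
generator_pair <- function(truth, duration_s, fs, seed,
                           structures = c("STR", "GPi"),
                           freqs = default_freqs()) {
  rec <- generate_hemisphere(truth, duration_s, fs, seed = seed)
  ch <- assign_structures(derive_bipolar(rec))
  out <- lapply(ch[structures], function(c) {
    quick_tfr(as.numeric(condition(c)), 200, freqs)
  })
  names(out) <- structures
  out
}
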