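# bgosc — basal ganglia LFP oscillations and connectivity

`bgosc` is an R pipeline for parallel rest-state local field potential
(LFP) recordings from **striatum, GPe and GPi**, as obtained through an
eight-contact pallidal DBS electrode whose trajectory traverses all three
nuclei. It is aimed at electrophysiologists who want a tested, seeded,
end-to-end implementation of:

- **montage handling** — adjacent-pair bipolar derivation (8 contacts → 7
  channels) and the structure-assignment rule that retains only channels
  whose both contacts lie inside one nucleus;
- **conditioning** — zero-phase Butterworth filtering (high-pass 1 Hz,
  low-pass 98 Hz, notch 48–52 Hz), anti-aliased decimation to 200 Hz,
  epoching;
- **spectral analysis** — Morlet wavelet spectra (7 cycles, 1–98 Hz in
  0.5 Hz steps) normalized to signal variance, canonical band averages
  (low-frequency 3–12 Hz, beta 13–35 Hz), 1/f-flattened peak detection and
  peak-aligned group spectra;
- **coupling robust to volume conduction** — imaginary part of coherence
  iCOH(f) = Im( S_ab / √(S_aa·S_bb) ),
  the debiased weighted phase-lag index, and nonparametric spectral
  Granger causality (Wilson factorization of the cross-spectral matrix,
  Geweke's formula) with **time-reversal correction**, plus the bin-count
  rule designating hemispheres as striatal-driving;
- **statistics** — seeded epoch-shuffle surrogates, Monte Carlo
  permutation tests, Benjamini–Hochberg FDR and cluster permutation, and
  Pearson correlation of hemisphere-averaged estimates with a per-subject
  severity score (BFMDRS) after a Monte Carlo Lilliefors normality screen;
- **a synthetic cohort generator** with exact ground truth (peak
  frequencies, coupling gains/lags/directions, zero-lag leakage, line
  noise, severity model), so every stage has a parameter-recovery test.

Recordings are read/written as raw float64 + JSON sidecar or TSV; there is
no dependency on vendor acquisition formats.

## Worked example

Simulate one hemisphere with a known 8 Hz rhythm and striatum→GPi coupling
(25 ms lag), run the full chain, and ask the questions the pipeline is
built for:

```r
library(bgosc)

truth <- ground_truth(lf_peak_hz = 8,
                      coupling_gain = c(str_gpi = 0.8, str_gpe = 0.3,
                                        gpe_gpi = 0.2))
rec <- generate_hemisphere(truth, duration_s = 180, fs = 1000, seed = 42)
rec
#> <bg_recording> subject s01, left hemisphere
#>   8 contacts x 180000 samples @ 1000 Hz (180.0 s)
#>   structures: c1=GPi c2=GPi c3=other c4=other c5=GPe c6=GPe c7=STR c8=STR

channels <- assign_structures(derive_bipolar(rec))   # GPi, GPe, STR retained
tfrs <- lapply(channels, function(ch) {
  morlet_transform(epoch(condition(ch)), default_freqs(), n_cycles = 7)
})

spec <- power_spectrum(tfrs$GPi)
detect_peak(spec, "lf")$freq_hz        # recovered peak frequency
#> [1] 8
round(spec$band_means, 2)              # normalized band power (a.u.)
#>   lf beta
#> 9.04 0.24

cs <- cross_spectrum(tfrs$STR, tfrs$GPi)
round(band_mean(imaginary_coherence(cs), cs$freqs, "lf", abs = TRUE), 3)
#> [1] 0.283                            # low-frequency |iCOH|, STR-GPi

sur <- shuffle_surrogate(tfrs$STR, tfrs$GPi, n_surrogates = 200, seed = 1)
null_bm <- apply(sur$icoh, 1, band_mean, freqs = sur$freqs,
                 band = "lf", abs = TRUE)
round(quantile(null_bm, 0.95), 3)      # epoch-shuffle null, 95th pctile
#>   95%
#> 0.047

g <- granger_time_reversed(cs)
directionality_designation(g$fwd_corrected, g$rev_corrected,
                           g$freqs)[c("striatal_driving",
                                      "n_bins_str", "n_bins_gpi")]
#> $striatal_driving  [1] TRUE
#> $n_bins_str        [1] 15
#> $n_bins_gpi        [1] 4
```

The coupled pair's low-frequency iCOH (0.283) sits far above its shuffled
null (95th percentile 0.047), and the time-reversed-corrected Granger
spectra attribute the majority of low-frequency bins (15 of 19) to
striatal drive — the configured ground truth.

For a full cohort:

```r
cfg <- run_config(seed = 1)            # 10 subjects, 19 hemispheres
res <- run_all(cfg, out_dir = "bgosc_run")
res$correlations                       # severity correlation battery
```

`run_all()` writes hemisphere/subject tables, the correlation battery,
group figures, a JSON summary and the resolved configuration (with seed)
into the run directory. A thin command-line wrapper with `simulate`, `run`
and `validate` subcommands ships in `inst/scripts/bgosc.R`.

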