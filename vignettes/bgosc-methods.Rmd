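---
title: "Basal ganglia LFP spectra, cross-nucleus coupling, and severity correlation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Basal ganglia LFP spectra, cross-nucleus coupling, and severity correlation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Pallidal deep brain stimulation (DBS) electrodes implanted for dystonia can
traverse three basal ganglia nuclei at once — striatum, external pallidum
(GPe) and internal pallidum (GPi) — so that a single eight-contact electrode
yields parallel rest-state local field potential (LFP) recordings from all
three. Such recordings raise three questions that this package answers as a
reusable, tested pipeline:

1. **Spectral structure.** Do the three nuclei share oscillatory activity,
   in particular low-frequency (3–12 Hz) and beta (13–35 Hz) rhythms, and at
   which individual peak frequencies?
2. **Oscillatory connectivity.** Are the nuclei coupled at those rhythms,
   once the trivial explanation — one source volume-conducting into several
   contacts — is ruled out? And in which direction does the low-frequency
   interaction flow between striatum and GPi?
3. **Clinical correlation.** Do band-limited power and coupling estimates,
   averaged to one value per subject, correlate with dystonic symptom
   severity (BFMDRS, a non-negative global score)?

Patient recordings of this kind are not freely redistributable, so the
package pairs the analysis chain with a synthetic cohort generator whose
ground truth (peak frequencies, coupling gains, lags, directions, confound
amplitudes, severity model) is known exactly. Every stage of the pipeline
then has a parameter-recovery test surface, and all package-level claims are
statements about recovery of known structure — not about patients.

## Recording model and montage

A `bg_recording` holds monopolar contact samples in ventral-to-dorsal order
with a contact-to-structure map. `derive_bipolar()` forms the standard
adjacent-pair montage (8 contacts → 7 channels; sign convention ventral
minus dorsal — the sign is irrelevant to power and coherence magnitudes but
fixed for reproducibility). `assign_structures()` retains exactly those
bipolar channels whose two contacts lie in the same nucleus and discards
every straddling pair; when several adjacent pairs qualify for one
structure, the most ventral pair is kept. That tie-break is a declared
package convention: a montage-reduction rule has to pick one channel per
structure per hemisphere, and depth-first is the only anatomical ordering
available. A hemisphere without, say, a striatal pair simply lacks STR in
all downstream tables; unilateral subjects stay in the cohort.

## Signal conditioning

`condition()` low-passes at 98 Hz (the filter doubles as the anti-alias
filter, applied at the input rate), decimates to 200 Hz, high-passes at
1 Hz, and band-stops 48–52 Hz around the European mains frequency. All
filters are forward–backward (zero-phase) Butterworth, order 4 per pass
(order 2 per pass for the band-stop, giving an order-4 magnitude response).
Zero phase is not cosmetic here: any frequency-dependent phase shift would
masquerade as lag structure in the phase-based coupling measures
downstream. `epoch()` cuts the conditioned series into contiguous,
non-overlapping 2 s epochs (0.5 Hz resolution, matching the analysis grid)
and drops any epoch touching a masked artifact sample; a simple |z| > 5
amplitude mask is available but off by default, since the expectation is
that segments entering the pipeline were already screened.

## Spectral estimation

`morlet_transform()` convolves the *continuous* conditioned signal with
L2-normalized complex Morlet wavelets (7 cycles at every frequency, grid
1–98 Hz in 0.5 Hz steps) and only afterwards indexes coefficients by epoch.
Convolving per epoch would be incorrect at low frequencies: at 3 Hz a
7-cycle wavelet is longer than a 2 s epoch. Epochs lying within one wavelet
half-length (at the lowest analysis frequency, the longest wavelet) of
either recording edge are flagged invalid and excluded from every average,
so all retained observations are edge-effect-free at all frequencies.

`power_spectrum()` averages squared coefficient magnitudes over valid-epoch
samples and divides by the time-domain signal variance. This variance
normalization is the package's reading of "normalize to the standard
deviation": its purpose is to cancel electrode-impedance scale differences,
which multiply the raw voltage, so the natural operation is scaling the
channel to unit SD (equivalently dividing power by the variance). Normalized
spectra are exactly invariant under positive rescaling of the input — a
property the tests assert to machine precision. Absolute power is in
arbitrary units by construction; only scale-invariant structure is
meaningful.

`detect_peak()` removes a 1/f trend (linear fit of log power on log
frequency over the full grid, excluding the notch band) and reports the
highest in-band local maximum whose topographic prominence exceeds 5% of the
flattened in-band range. The threshold is a convention — presence/absence of
a peak needs *some* criterion — and is exposed as a parameter. Absence is a
valid, non-error outcome. `flatten_align()` shifts flattened spectra so
individual peaks coincide at relative frequency zero for group display.

## Coupling measures

All coupling statistics are computed from one estimation path: per-epoch
wavelet cross-spectra (`cross_spectrum()`), time-averaged within epochs and
then across epochs.

- **Imaginary part of coherence** (`imaginary_coherence()`):
  `Im(S_ab / sqrt(S_aa S_bb))`. Volume conduction is instantaneous, so a
  common source contributes only to the real part; a non-zero imaginary
  part requires a consistent non-zero phase lag. The cost is blindness to
  genuinely zero-lag physiological interaction — accepted, as the
  conservative choice.
- **Debiased weighted phase-lag index** (`wpli()`): products of per-epoch
  imaginary cross-spectra over distinct epoch pairs, normalized by the
  pairwise magnitude products. Its null distribution is centered at zero
  and individual estimates may be slightly negative — the hallmark of the
  debiased estimator, and the reason it was chosen: shuffled-data wPLI
  means should scatter around zero, not above it. A channel paired with
  itself has identically zero imaginary parts; the estimator returns 0
  with a warning rather than 0/0.
- **Nonparametric spectral Granger causality** (`granger_nonparametric()`):
  Wilson's iterative factorization of the 2×2 spectral density matrix into
  its minimum-phase factor, followed by Geweke's frequency-resolved
  causality. No autoregressive model is fit; the wavelet spectral matrix is
  the only input (a single estimation path keeps the Granger spectra
  commensurable with the coherence spectra).
- **Time-reversal correction** (`granger_time_reversed()`): the Granger
  spectra are recomputed on time-reversed data and subtracted. Reversal
  flips every lag, so genuine lagged drive changes direction while
  asymmetries that merely mimic directionality (unequal SNR between
  channels being the classic case) reproduce and cancel. For stationary
  estimates, channel-wise time reversal conjugates the cross-spectral
  density and leaves auto-spectra unchanged, so the reversed-data spectral
  matrix is obtained exactly, without re-estimation. Corrected values may
  be negative; band summaries never clip them, since clipping would bias
  the net-direction comparison.

### Numerical notes on the factorization

The iteration starts from the Cholesky factor of the lag-zero covariance
and stops when the mean relative change of the spectral factor falls below
1e-9 (at most 200 iterations). Analytic spectra (e.g., of a known
autoregression) reach that tolerance in a few dozen iterations. *Estimated*
spectra generally cannot: a finite-lag factorization of a noisy, smoothed,
notch-shaped spectrum settles into a small limit cycle instead. The
implementation detects the stall (no 1% improvement over ten iterations)
and then accepts the factor if and only if the reconstruction `psi psi^H`
matches the input matrix within a 5e-3 relative residual; otherwise it
errors, reporting both residuals. Non-positive-definite inputs receive
diagonal loading starting at 1e-12 of the mean trace, escalating tenfold
only as far as needed. The spectrum is interpolated onto the uniform
0–Nyquist grid the factorization requires, padding below 1 Hz and above
98 Hz with edge values.

### Directionality designation

Following the bin-count rule, a hemisphere is designated striatal-driving
when the corrected striatum-as-source spectrum exceeds the
pallidum-as-source spectrum in a strict majority of low-frequency bins;
exact ties count toward neither side and are logged. The pipeline
additionally gates the designation on the pair's coupling being
surrogate-significant (band-mean |iCOH| above the epoch-shuffle 95th
percentile): under a pure zero-lag confound the corrected spectra are
near-zero noise, and an ungated majority count would flip a coin per
hemisphere. Directionality is only interpretable where coupling exists;
the gate expresses exactly that and is exposed as an argument
(`coupling_significant = NULL` recovers the plain rule).

## Surrogates and statistics

`shuffle_surrogate()` permutes the epoch sequence of one channel relative
to the other and recomputes each measure. This preserves both marginal
spectra exactly while destroying cross-epoch phase consistency, which is
the property the coupling measures rely on. Alternatives (time-segment
rotation, phase randomization) alter the marginals or the within-epoch
structure; epoch permutation is the least invasive scheme available once
epochs exist, and is the package's declared convention. Draws are seeded;
1000 surrogates is the module default, and the pipeline uses 200 per pair
(a 95th percentile from 200 draws has a Monte Carlo standard error of
about 1.5 percentile points, ample for gating; the count is a config key).

Group inference uses Monte Carlo permutation tests (difference of means;
sign-flipped paired differences or label exchange; two-sided add-one
p-values, so p is never exactly zero and is floored at 1/(n_perm+1));
Benjamini–Hochberg FDR within each analysis family (power comparisons;
coupling vs surrogate; severity correlations); and cluster-based
permutation across frequency bins for dependent spectral comparisons
(bin-wise paired t thresholded at 0.05, contiguous same-sign
supra-threshold runs summed into cluster masses, max-mass null). Pearson
correlations with severity are preceded by a Lilliefors normality screen
whose null is simulated (1000 seeded Monte Carlo draws) rather than read
from approximation tables; a violation flags the estimate but does not
suppress the correlation, which mirrors how such screens are used in
practice. Hemisphere estimates are averaged to one value per subject
before correlation, because the clinical score is a single global number
per subject.

## The synthetic cohort generator

`generate_hemisphere()` builds each structure signal as a sum of

- 1/f background (FFT-shaped Gaussian noise, spectral exponent 1);
- a narrowband low-frequency oscillation: Gaussian-envelope filtered noise
  (FWHM 2 Hz) rather than a sinusoid, so coherence stays below 1 and
  surrogate statistics are non-degenerate;
- optionally a beta oscillation of the same construction;
- delayed, scaled copies of the *source* oscillations implementing
  directed coupling (striatum → GPi, striatum → GPe, GPe ↔ GPi) at a 25 ms
  lag — about a quarter cycle at 10 Hz, which keeps the imaginary part of
  coherency large at the peak;
- a zero-lag narrowband component shared by all structures (the volume
  conduction surrogate);
- 50 Hz line noise with a random phase.

The structure signals are embedded into eight monopolar contacts (split
across each retained pair with opposite signs) plus a common reference
term that cancels in the bipolar derivation and per-contact white noise.
Delay-and-sum coupling is deliberately the simplest generative mechanism
with unambiguous Granger direction; conductance-based or neural-mass
dynamics are out of scope.

`generate_cohort()` draws per-hemisphere ground truths: low-frequency peaks
from a truncated normal (8.5 ± 2.5 Hz on [3, 12]); beta peaks present with
probability 13/19 (22.8 ± 6.6 Hz on [13, 35]); and gains organized around a
per-subject latent disease factor. Severity is
`2 + 6·mean(GPi LF gain) + 12·mean(STR→GPi coupling gain) + N(0, 1)`,
clamped at zero. One default hemisphere (subject 7, left) is dropped to
emulate an electrode without a striatal contact pair, so ten bilateral
subjects yield nineteen hemispheres.

### Why the default gains look the way they do

Two findings from calibrating the generator shaped the defaults, and both
are properties of the *measurement*, not of the generator:

1. **Variance-normalized power saturates.** Normalized band power is
   oscillation variance over total variance; once the oscillation rivals
   the background, further gain increases barely move the estimate, and
   recovery *worsens*. Effects must therefore live in the sensitive regime
   (oscillation variance at or below background variance), not at maximal
   gain.
2. **Band-edge peaks lose mass.** A hemisphere whose peak sits near 3 or
   12 Hz loses part of its (wavelet-smoothed) bump outside the canonical
   band, which acts as multiplicative noise on measured band power. Since
   the peak-frequency spread is a fixed study condition, the designed
   effect has to dominate this nuisance rather than eliminate it.

Hence the defaults make the striatum→GPi coupled component the dominant
latent-driven share of GPi low-frequency power (coupling gain
0.05 + 1.3·latent) with only a mild latent slope on the GPi's own
oscillation (0.4 + 0.2·latent), background 1.3, common source 0.3.
Mechanistically this says: pallidal low-frequency activity is largely
striatally driven, and severity scales with that drive — one mechanism
expressed in both of the linked estimates, while STR/GPe power and
STR→GPe coupling vary independently as designed nulls.

### What the generator does and does not emulate

It emulates the statistical structure the analysis assumes: 1/f
background, shared narrowband rhythms with individual peak frequencies,
lagged directed coupling, zero-lag leakage, line noise, montage geometry,
and a severity score tied to two of the estimates. It does not emulate
nonstationarity, movement or stimulation artifacts, cross-frequency
coupling, electrode drift, or any biophysics of conduction. Passing
parameter-recovery tests on this cohort therefore demonstrates that the
estimators recover the structure they model, under the confounds they
claim immunity to — it does not certify behavior on arbitrary clinical
data.

## Problem sizes used by the test suite

The packaged experiments run on one CPU in minutes, with sizes chosen as
the smallest that leave comfortable statistical margins: oracle
comparisons on 180 s (coherency) and 1e5 samples (Granger vs a fitted
autoregression); confound and direction-recovery batteries on twenty 90 s
hemispheres each; peak recovery on fifty 90 s hemispheres; and fifty
10-subject cohorts of 60 s hemispheres generated at 400 Hz for the
severity-pattern experiment. The full-length default (180 s at 1 kHz)
changes none of the conclusions, only the runtime.

## Known limitations

- Granger estimates inherit the wavelet's frequency-dependent smoothing;
  against sharply resonant spectra the band values are biased where the
  spectrum curves strongly within a wavelet bandwidth.
- The epoch-permutation surrogate assumes epochs are exchangeable; strong
  slow nonstationarity would widen the true null relative to it.
- The bipolar montage reduction keeps one channel per structure and
  discards straddling pairs; no attempt is made to model partial volume
  sensitivity of a contact at a nuclear boundary.
- Severity modeling is linear-Gaussian with clamping; floor effects of
  real clinical scales are not reproduced beyond the clamp.
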