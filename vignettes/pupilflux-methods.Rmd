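---
title: "Methods: frequency-resolved coupling of pupil-linked arousal and cortical activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency-resolved coupling of pupil-linked arousal and cortical activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`pupilflux` quantifies how non-luminance-driven fluctuations of pupil
diameter — a peripheral readout of neuromodulatory arousal — covary with
band-limited cortical population activity recorded on many channels
(MEG/EEG sensors or source time courses). The pipeline runs from raw pupil
and gaze traces plus multichannel neural time series to five families of
coupling estimates:

1. **Standardized mutual information (MI)** between pupil and spectral
   power envelopes, per channel and frequency, standardized against
   time-shift surrogates.
2. **Lagged cross-correlation** of power envelopes with pupil (and its
   derivative), with anterior-posterior spatial binning and band
   averaging.
3. **Forward-shifted Spearman correlation maps** of power with pupil.
4. **Aperiodic (1/f) parameterization** of segment-wise spectra: coupling
   of the spectral exponent with pupil, and residualized (periodic-only)
   band-power coupling.
5. **Binned quadratic (inverted-U) models** of power or exponent as a
   function of pupil state.

Group-level inference is a two-tailed one-sample t-test of per-subject
values against zero per cell, with Benjamini-Hochberg FDR control at
q = 0.1 across each analysis map.

All stages are validated end-to-end by parameter recovery on a bundled
synthetic-data generator with a serializable ground-truth manifest; no
external recordings are required.

# Pupil preprocessing

Pupil area is linearized to diameter (`d = 2 * sqrt(a / pi)`). Blink gaps
(non-finite or sentinel samples) are padded by 150 ms per side and
linearly interpolated; a second pass interpolates velocity outliers
(|dx/dt| beyond 16 MAD, a package-chosen rule since published pipelines
defer this to external tooling). Canonical pupil responses to blinks and
saccades are modeled as a gamma-family kernel
`h(t) = t^w * exp(-t / tau)` with `w = 10.1`, `tau = 0.93 / w` s — peak
dilation at 930 ms, the canonical latency — with per-event-type amplitudes
fitted by least squares and subtracted. The trace is then band-passed to
0.005-2 Hz and resampled to 400 Hz; the derivative is the forward
difference times the sampling rate (last sample repeated).

**Numerical choice — the band-pass.** A recursive second-order Butterworth
band-pass with a 0.005 Hz low cutoff is numerically degenerate at 400 Hz
(normalized cutoff 2.5e-5: pole radii within 1e-5 of the unit circle and
transients comparable to the trace length; a constant input leaves
residuals of order half the input level). The filter is therefore applied
as the exact two-pass Butterworth *magnitude* response in the frequency
domain after even-reflection padding, which is the response a
forward-reverse recursive filter realizes, is zero-phase by construction,
and removes DC to machine precision. Its 10 Hz vs 0.1 Hz attenuation
(56 dB) matches the recursive implementation where that one is stable.

The pupil spectrum is a sine-taper multitaper estimate (half-bandwidth
0.035 Hz, zero-padded to at least 2^19 samples), parameterized with at
most 3 peaks, detection threshold 0.5 SD and widths 0.1-0.5 Hz to report
the Hippus peak frequency and the pupil spectral exponent.

# Spectral decomposition

Morlet wavelets
`w(t, f) = (sigma_t sqrt(pi))^(-1/2) exp(-t^2 / (2 sigma_t^2)) exp(-i 2 pi f t)`
are evaluated at 25 log-spaced centers `f_k = 2 * 2^(k/4)` (2-128 Hz).
Each frequency's band is the half-octave `[f 2^(-1/4), f 2^(1/4)]`; the
spectral width is set so one standard deviation of the Gaussian spectral
profile spans the band (`sigma_f = (hi - lo) / 2`,
`sigma_t = 1 / (2 pi sigma_f)`), so the `+/- 1 sigma_f` interval is
exactly the half-octave band. Wavelets are truncated at `+/- 3 sigma_t` and
unit-energy normalized; windows step by 20% of the support (80% overlap),
window centers are the envelope timestamps, windows reaching past the
recording are dropped, and windows touching masked samples are flagged
invalid. Power is the squared coefficient magnitude.

For spectral parameterization, the recording is cut into non-overlapping
2 s segments (non-overlapping by default; overlap is configurable) and each segment gets a single Hann-tapered
Welch spectrum at 0.5 Hz resolution, 2-128 Hz. Each segment is paired
with the mean pupil diameter over the segment window shifted forward by
930 ms — so the pupil is read where its dilation reflects neural activity
within the segment — and the mean pupil derivative over the unshifted
window (derivative-neuromodulation correlations are near-instantaneous).

# Coupling estimators

**Gaussian-copula MI.** Each series is rank-transformed to uniform
margins and mapped through the inverse normal CDF; MI is the Gaussian MI
`-0.5 log2(1 - rho^2)` of the transformed pair. This is invariant to
monotone marginal transforms and needs no binning. Pupil is brought to
each envelope's time base by averaging over the wavelet window support.
Observed MI is standardized against 200 surrogate MIs from circular time
shifts drawn uniformly outside a +/- 10 s guard:
`z = (log MI_obs - mean(log MI_surr)) / sd(log MI_surr)`. Because copula
scores of a circularly shifted series are the shifted scores, all
surrogate correlations come from one FFT circular cross-correlation per
cell — exactly equal to the brute-force loop (asserted in tests) but
hundreds of times faster. Circular shifts (rather than truncation)
preserve marginals and autocorrelation. Note a structural property the
tests document: under the null, surrogate MI is proportional to a 1-df
chi-square, so log MI has SD ~2.2 and even a perfectly coupled envelope
caps z near 5-6; null calibration, not large z per se, is the meaningful
property.

**Cross-correlograms.** `r(tau) = cor(power(t), pupil(t + tau))` at every
integer envelope-sample lag up to +/- 10 s, computed exactly via
cumulative sums and FFT cross-products. Sign convention: positive lags
mean the neural signal precedes the pupil; an injected generator lag of
-0.93 s (neural leads) yields an extremum at +0.93 s. Channels are sorted
anterior to posterior and split into 39 equal-count bins (remainder to
the most posterior bins); per band (2-4, 8-16, 64-128 Hz) correlograms
are linearly interpolated onto the lag grid of the band's highest center
before averaging.

**Peak-lag estimation.** The correlogram's expected shape is the pupil
autocorrelation (seconds wide) shifted by the coupling lag, so its peak
is flat and a raw argmax is dominated by envelope noise (envelope CV = 1
for narrowband Gaussian signals). `binned_peak_lag()` therefore smooths
the band-averaged correlogram with a 0.08 s Gaussian — half the
resolution limit of the 2 Hz-band-limited pupil signal, below which
correlogram structure cannot be coupling — before taking the signed
extremum within +/- 5 s.

**Spearman maps.** Spearman correlation of power with pupil shifted
forward 0.93 s (0 s for the derivative), realized as the nearest integer
number of envelope samples; by construction identical to the lagged rank
correlation at that lag, which the acceptance suite asserts to 1e-12.

# Aperiodic parameterization

Log spectra in 3-40 Hz are fitted as
`L(f) = offset - chi * log10(f)` plus up to six Gaussians (min height
0.05, width 1-8 Hz taken as bounds on 2 sigma, knee fixed at zero):
(1) OLS seed of the aperiodic line; (2) robust refit on points not above
the line (positive residuals above the 2.5th-percentile threshold
excluded); (3) iterative peak extraction from the flattened spectrum,
largest first, stopping below `max(0.05, 2 SD)`; (4) joint bounded
L-BFGS-B refinement of all Gaussians (centers constrained within two seed
widths); (5) aperiodic refit on the peak-subtracted spectrum. Internal
constants (robust percentile, peak seeding, optimizer and its bounds) are
pinned for determinism.
Recovery: exact on pure power laws and flat spectra; adding a compliant
peak moves the exponent by < 0.1; segment-noise bias < 0.1 over 500
2 s segments.

Per-segment exponents are correlated with per-segment pupil (Pearson by
default, Spearman by flag), and a 14-bin exponent-by-pupil curve is reported. Residualized
band power (log spectrum minus the fitted aperiodic line, averaged over
each half-octave band inside 3-40 Hz) isolates periodic coupling.
**Known limitation:** peak-aperiodic separation is imperfect; a strongly
pupil-modulated oscillation leaks a small opposite-signed bias
(|r| ~ 0.1, an order below the injected effect of ~0.8) into off-band
residual coupling, and exponent modulation leaves |group mean r| < ~0.06
of residual structure. The validation bounds encode exactly this
separation of scales.

# Inverted-U model

Segments are sorted into 14 equidistant pupil bins spanning the observed
range (equidistant in pupil value, not in occupancy; more than 4 empty
bins is an error, empty bins are excluded),
bin means are z-scored, and `P = b0 + b1 x + b2 x^2` is fitted by least
squares with `x` the z-scored per-bin mean pupil. z-scoring x (an open
choice: bin index, bin center and member mean were all possible; member
mean is the most information-preserving) makes coefficients comparable
across subjects and invariant to raw pupil units. `b2 < 0` indicates an
inverted-U. Group maps test per-cell `b2` against zero with BH-FDR.

# Microsaccade control

Gaze velocities come from the 5-point moving-window derivative; the noise
scale per axis is `eta = sqrt(median(v^2) - median(v)^2)`; an event needs
`(vx / (6 eta_x))^2 + (vy / (6 eta_y))^2 > 1` for at least 5 samples
(12.5 ms); candidates closer than 20 ms are merged (the merge window is
a package choice). Detection is
monocular. Event-locked spectra use 0.5 s Hann windows stepped by 50 ms
over -0.5 to 2 s, averaged over events, as percent change against the
bin centered at -0.25 s; pupil uses the Hann-weighted windowed sum
likewise.

# Synthetic-data generator

The generator is first-class, tested code and the source of every
expected value in validation (via its JSON manifest).

* **Pupil**: slow drift band-limited to 0.005-2 Hz with a 1/f^2 in-band
  spectrum (`drift_exponent = 2`; spontaneous pupil spectra are steep, and
  a flat-band process would leave 2 s segment means almost no pupil
  variance, making slow-state analyses structurally impossible); a
  narrowband Hippus component at 0.2 Hz (bandwidth 0.05 Hz, amplitude 0.3
  SD); blink gaps of 100-400 ms (NaN) with a biphasic recovery
  deflection, at 0.25 events/s; saccade-locked canonical dilations at
  1 event/s riding on ballistic 20 ms gaze steps.
* **Neural channels**: an aperiodic background synthesized by FFT-masking
  white noise with `f^(-chi/2)` in overlapping Hann windows, the
  per-window exponent following the lagged z-scored pupil
  (`chi(t) = chi0 + slope * zp(t - lag)`); masks are normalized to unit
  RMS over 3-40 Hz so exponent changes tilt rather than rescale spectra.
  Oscillations are narrowband-filtered noise on half-octave bands (so
  envelopes fluctuate naturally) with instantaneous amplitude
  `max(0, 1 + gain * zp(t - lag) + quad * zp(t - lag)^2)`. Channel
  coordinates span +1 (anterior) to -1 (posterior); couplings can target
  either half.
* **What it does not emulate**: sensor physics and field spread (channels
  are statistically independent given the pupil), realistic eye-tracker
  noise beyond blinks/saccades, heteroscedastic measurement noise, and
  any cross-channel correlation structure. Passing recovery tests
  therefore demonstrates estimator correctness, not robustness to
  volume-conducted confounds.

Presets: `null`, `linear` (+0.5 gain at 11.3 Hz, lag -0.93 s),
`quadratic` (-0.5 at 11.3 Hz), `slope` (exponent slope -0.2 per z-pupil),
`full` (low-frequency negative and high-frequency positive linear
coupling, inverted-U at 11.3 Hz with opposite anterior/posterior signs,
negative exponent slope). Effect sizes in generative units have no
empirical reference; they are package choices fixed once at values
giving clear detection at 5 min of recording.

# Validation studies and problem sizes

The `study_*` functions define the validation experiments; the test suite
and `scripts/acceptance.R` run them at these sizes (chosen as the
package's own validation design):

* copula MI vs closed form: rho in {0, 0.3, 0.6, 0.9}, n = 50 000, 100
  seeds; max |error| < 0.01 bits.
* surrogate null: 5 subjects x 10 channels x 25 frequencies, 200
  surrogates, 300 s; mean z within +/- 0.1, |z| > 1.96 rate in
  [0.03, 0.07].
* lag recovery: 50 seeds, lags {-0.93, -0.5, +0.2} s rotated over bands
  {2-4, 8-16, 64-128} Hz, 8 channels, gain 1, artifact-free pupil (the
  study validates the lag estimator; artifact handling has its own
  tests); success = error within one envelope sample of the band's
  highest center, required in >= 90% of cells.
* inverted-U: 20 subjects, quad -0.5 at 11.3 Hz; group b2 < 0 with FDR
  rejection at the injected centers, false-positive fraction <= q among
  2-4 and 64-128 Hz centers.
* exponent recovery: chi in {0.5 ... 3} noiseless (< 0.05), 500 noisy
  segments (bias < 0.1), peak perturbation (< 0.1).
* exponent coupling: 20 subjects at slope -0.2; negative r in >= 95% of
  subjects; residual coupling bounds as in the limitation note above.
* microsaccades: precision and recall >= 0.9 at 5x-threshold events;
  suppression sign in >= 95% of 20 runs.
* determinism: the `full` preset, 5 subjects x 120 s x 4 channels, run
  twice with one seed, byte-identical.

# Known limitations

* The surrogate-z ceiling (log-chi-square null) discussed above.
* Sub-envelope-sample lag estimation at the highest band (8.6 ms at
  128 Hz) is only reliable with band/channel averaging and correlogram
  smoothing; per-channel raw argmax jitters by several samples.
* Aperiodic/periodic leakage biases of order 0.05-0.1 in residual
  coupling correlations.
* The pipeline assumes a common clock for pupil and neural recordings;
  no realignment is performed.
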