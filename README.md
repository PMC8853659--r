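# pupilflux

Frequency-resolved coupling between pupil-linked arousal and cortical
population activity.

Spontaneous fluctuations of pupil diameter under constant illumination
track the brain's neuromodulatory arousal state. `pupilflux` is an R
package for researchers in human neurophysiology who want to relate
continuous pupil recordings to multichannel electrophysiological data
(MEG/EEG sensor or source time courses) at rest. It implements a complete,
validated pipeline:

- **Pupil preprocessing** — blink detection and interpolation, removal of
  canonical blink/saccade responses (gamma kernel
  `h(t) = t^w e^{-t/τ}` peaking at 930 ms), zero-phase 0.005–2 Hz
  band-pass, resampling to 400 Hz, first derivative.
- **Spectral decomposition** — Morlet wavelet power envelopes
  `Y(t, f) = |X(t, f)|²` on 25 log-spaced center frequencies
  `f_k = 2·2^{k/4}` (2–128 Hz, half-octave bands, 80 % window overlap),
  plus 2 s segment-wise Welch spectra at 0.5 Hz resolution.
- **Coupling estimators** —
  Gaussian-copula mutual information `MI = −½ log₂(1 − ρ²)` standardized
  against 200 circular time-shift surrogates
  (`z = (log MI_obs − mean log MI_perm) / sd log MI_perm`);
  lagged cross-correlograms `r(τ) = cor(power(t), pupil(t + τ))` up to
  ±10 s with anterior–posterior spatial binning and band averaging;
  Spearman maps of power against pupil shifted forward by 930 ms.
- **Aperiodic parameterization** — each segment's log spectrum is fitted
  in 3–40 Hz as `offset − χ·log₁₀ f` plus up to six Gaussian peaks; the
  spectral exponent χ is correlated with pupil, and residualized
  (aperiodic-subtracted) band power isolates oscillatory coupling.
- **Inverted-U model** — per-subject segments are sorted into 14
  equidistant pupil bins and the z-scored binned power is fitted with
  `P = β₀ + β₁x + β₂x²`; `β₂ < 0` indicates an inverted-U
  (Yerkes–Dodson-like) arousal dependence.
- **Microsaccade control** — Engbert-style velocity-threshold detection
  (median-based noise scale, threshold 6, minimum duration 5 samples) and
  event-locked percent change of spectral power and pupil size.
- **Group statistics** — two-tailed one-sample t-tests per cell with
  Benjamini–Hochberg FDR control (q = 0.1) per analysis map.
- **Synthetic-data generator** — pupil (slow drift + 0.2 Hz Hippus +
  blinks/saccades) and neural channels with 1/f^χ(t) backgrounds and
  band-limited oscillations whose envelopes couple to the lagged pupil
  linearly or quadratically, with a JSON ground-truth manifest; every
  analysis stage is validated by parameter recovery against it.

## Worked example

Simulate a subject whose 11.3 Hz oscillation envelope follows the pupil
with gain 0.5 and a −0.93 s lag (neural leads pupil), then recover the
coupling:

```r
library(pupilflux)

s   <- synth_subject("linear", duration_s = 300, fs_hz = 400,
                     n_channels = 4, seed = 42)
tr  <- preprocess_pupil(s$pupil)
tr
#> <pupil_trace> 300.0 s at 400 Hz, 12.6% interpolated
#> steps: blink interpolation -> event-response removal ->
#>   bandpass 0.005-2.0 Hz two-pass -> resample 400 Hz ->
#>   forward-difference derivative

env <- wavelet_envelopes(s$neural)
mi  <- mi_with_surrogates(tr, env, n_perm = 200, seed = 43)
mi
#> <mi_result> 4 channels x 25 frequencies, 200 surrogates (guard 10 s)
#>   mean z = 0.30, max |z| = 3.68
mi$mi_z[, which(env$grid$center > 11 & env$grid$center < 12)]
#> [1] 1.84 1.98 1.80 2.05     # elevated only at the injected frequency

xc <- xcorr_lagged(tr, env)
bx <- bin_and_average_xcorr(xc, s$neural$coords, n_bins = 1)
binned_peak_lag(bx)
#>   band_lo band_hi bin peak_lag      peak_r
#> 1       2       4   1   4.9500 -0.01519509
#> 2       8      16   1   0.9450  0.46924700
#> 3      64     128   1  -3.1575  0.00781259
```

The standardized MI spectrum peaks at the injected 11.3 Hz; the 8–16 Hz
band-averaged correlogram has its extremum at +0.945 s — the injected
0.93 s neural-leads-pupil lag recovered to within one envelope sample —
with r ≈ 0.47, while the non-injected bands show near-zero correlations
(their "peak" lags are the argmax of noise and carry no information).

Segment-level analyses follow the same pattern:

```r
seg <- segment_spectra(s$neural, tr)          # 2 s Welch spectra + pupil
es  <- exponent_series(seg)                   # per-segment 1/f exponent
qf  <- fit_quadratic(bin_by_pupil(segment_band_power(seg)$power[, 11],
                                  seg$seg_pupil))
```

`run_pipeline(run_config(...))` orchestrates all stages over multiple
subjects and returns per-subject results plus FDR-controlled group maps;
`write_run()` exports them as CSV/JSON.

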