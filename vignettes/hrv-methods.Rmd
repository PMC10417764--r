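---
title: "Methods: heart rate variability analysis with hrvkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heart rate variability analysis with hrvkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvkit)
```

## The problem

Heart rate variability (HRV) is the beat-to-beat fluctuation of the RR
interval — the time between consecutive heartbeats — and is a non-invasive
window on autonomic cardiovascular regulation. Long-term (Holter-style)
monitoring produces a *tachogram*: an ordered series of RR intervals,
roughly 100,000 beats over 24 hours. Reduced variability accompanies
ischemic heart disease and several arrhythmias, and clinical practice
summarizes a recording with a battery of standardized statistics that are
compared against published normal ranges.

`hrvkit` implements that battery for RR series supplied as plain text or
CSV, together with seeded synthetic generators that provide ground truth
for every estimator, cohort-level statistics, and out-of-norm flagging.
Everything upstream of the tachogram — ECG/PPG acquisition, QRS detection,
vendor formats — is out of scope: the RR series is the input contract.

## The tachogram and its cleaning

An `rr_series` stores intervals in milliseconds; the cumulative time axis
(seconds) is always re-derived from the intervals, so files carrying a
time column are trusted only for row ordering. Preprocessing is
deliberately minimal: intervals outside the physiologic plausibility
bounds 333–2000 ms (180 down to 30 beats/min) are dropped, interpolated
from their valid neighbours, or cause an error, per policy. No
normal-to-normal (ectopic-beat) classification is attempted — nothing in
the input distinguishes beat morphologies — and this is the package's
main limitation on real recordings: time-domain statistics, RMSSD above
all, are sensitive to residual artifacts inside the plausibility band. A
violation rate above 20 % always warns.

## Time-domain and geometric measures

For intervals $RR_1,\dots,RR_N$ with successive differences
$\Delta_i = RR_{i+1} - RR_i$:

* $\mathrm{SDNN} = \mathrm{sd}(RR)$, $\mathrm{RMSSD} =
  \sqrt{\tfrac{1}{N-1}\sum \Delta_i^2}$;
* $\mathrm{NN50} = \#\{|\Delta_i| > 50\ \mathrm{ms}\}$ (strict
  inequality), $\mathrm{pNN50} = 100\,\mathrm{NN50}/(N-1)$;
* SDANN is the sd of per-5-minute-window mean RR, and the SDNN index the
  mean of per-window sd, over consecutive 300 s windows of cumulative
  time.

Two conventions are worth making explicit. First, sample ($n-1$) standard
deviations are used everywhere, matching reference HRV software; a
`population_sd` switch exists for the $n$-denominator variant and the
choice is irrelevant at $N \approx 10^5$. Second, the pNN50 denominator is
the number of successive differences, $N-1$; definitions that divide by
the total interval count differ negligibly at recording scale. Windows
with fewer than 30 beats are excluded from SDANN and the SDNN index — the
per-window sd is unstable on short blocks and the trailing partial window
of a long recording would otherwise contaminate the summary.

The geometric measures derive from the RR histogram with half-open bins
anchored at 0 ms and width 1/128 s (7.8125 ms), the conventional
resolution inherited from 128 Hz ECG sampling. The HRV triangular index
is total count over modal count. TINN fits the least-squares triangle
with its apex pinned to the empirical mode and base endpoints $m_1, m_2$
searched over the bin-edge grid; because the triangle is zero outside its
base, the residual splits into independent left and right sums, so each
endpoint is optimized separately and the result equals the exhaustive
all-pairs search (the test suite verifies this against a brute-force
oracle). With fewer than three nonzero bins the fit is meaningless and
the nonzero support width is returned, flagged degenerate. Mode ties
break toward the shorter interval.

## Nonlinear measures

**DFA.** The integrated, mean-centred profile is divided into
non-overlapping boxes of $n$ beats — counted from the start *and* from
the end of the record, so no tail is discarded — each box is detrended by
a least-squares line (order configurable), and $F(n)$ is the RMS
residual. The exponents are slopes of $\log_2 F$ on $\log_2 n$:
$\alpha$ over all boxes, $\alpha_1$ over 4–16 beats, $\alpha_2$ over
16–64 beats. The 4–64 range with the split at 16 is the de facto HRV
standard; box sizes are quarter-octave spaced. $\alpha = 0.5$ marks an
uncorrelated series, values below 0.5 anti-correlation, 0.5–1
persistence. Linear detrending at the smallest boxes biases the
white-noise slope slightly upward (about 0.53 at $N = 10^4$); this is a
known property of DFA-1 shared by standard implementations, and the
anchor checks in the test suite use the ±0.05 band around 0.5 that the
bias stays within.

**Poincaré.** SD1/SD2 come from the moment identities
$\mathrm{SD1}^2 = \tfrac{1}{2}\mathrm{Var}(\Delta)$ and
$\mathrm{SD2}^2 = 2\,\mathrm{Var}(RR) - \mathrm{SD1}^2$ with population
variances — they are identities on the scatter of $(RR_i, RR_{i+1})$,
not estimators, and the package preserves
$\mathrm{SD1}^2 + \mathrm{SD2}^2 = 2\,\mathrm{Var}(RR)$ exactly. The
construction can make $\mathrm{SD2}^2$ negative for extreme
anti-correlation at very short lengths (constructible for $n < 10$,
never seen in physiologic tachograms); such inputs are flagged
`degenerate` with SD2 = 0 rather than silently absorbed.

**Entropies.** ApEn and SampEn use Chebyshev distance with embedding
$m = 2$ and tolerance $r = 0.2\,\mathrm{sd}$ (the literature convention;
both are configurable). ApEn includes self-matches, SampEn excludes
them and is exactly zero on strictly periodic input; when no templates
match, SampEn is reported absent with a flag rather than infinite. The
$O(n^2)$ template counts are implemented in C++; the analysis battery
caps the entropy segment at the first 10,000 beats of very long
recordings, where the estimates have long stabilized.

**Hurst exponent.** Rescaled-range analysis partitions the series into
blocks per window size, averages $R/S$ over blocks (skipping zero-sd
blocks), and regresses $\log(R/S)$ on $\log w$. The raw slope is a
biased estimator at finite window sizes — about 0.55 on uncorrelated
data at $N = 10^4$ — so the package applies the Anis–Lloyd–Peters
correction by default: $h = 0.5 + \hat\beta - \hat\beta_{\mathrm{iid}}$,
where $\hat\beta_{\mathrm{iid}}$ is the slope of the exact iid
expectation of $R/S$ over the same windows. Window sizes default to ten
log-spaced values from $\max(8, \min(64, N/32))$ to $N/4$: the lower
cut-off avoids the most bias-dominated windows on long records while
retaining a factor-8 span on short ones. With these defaults the
estimator recovers the generator exponent of fractional Gaussian noise
to within ±0.1 across $H \in \{0.6, 0.7, 0.8, 0.9\}$ and returns
0.50 ± 0.01 on white noise (20 seeds, $n = 10^4$); the raw slope remains
available (`slope_rs`, `correction = "none"`).

## Time–frequency analysis

Fourier and wavelet methods need uniform sampling, so the tachogram is
first cubic-spline interpolated at 4 Hz — the HRV convention,
comfortably above twice the 0.4 Hz upper edge of the HF band. The
spline is faithful below ~0.4 Hz but necessarily attenuates content
approaching the mean beat rate, which is why spectral-flatness checks
in the tests are confined to the HRV band.

The STFT spectrogram uses Hann-windowed, per-segment mean-removed,
one-sided periodograms normalized so the PSD integrates to the segment
variance (Parseval holds within 5 % on white-noise fixtures); Welch's
PSD is the segment average, with a 300 s default window so that the
1/300 Hz resolution resolves the VLF lower edge. The continuous wavelet
spectrum uses an analytic Morlet mother wavelet ($\omega_0 = 6$,
Torrence–Compo normalization) evaluated by FFT per scale, with the
requested frequency grid mapped through the Morlet center-frequency
relation. Band powers integrate the PSD by the trapezoidal rule over
the Task-Force bands VLF 0.003–0.04, LF 0.04–0.15, HF 0.15–0.4 Hz;
bands not covered by the grid are flagged missing rather than silently
zero.

## Synthetic ground truth

The generators emulate the cohort signal structures the analyses are
designed to distinguish, with defaults chosen once as the study
conditions:

* `healthy_gaussian` — i.i.d. Gaussian intervals, mean 750 ms, sd 60 ms:
  a symmetric bell-shaped histogram with its mode at 0.75 s.
* `arrhythmia_bimodal` — a 60/40 Gaussian mixture at 600 and 420 ms
  (sd 25 ms): the double-peaked histogram of frequent extrasystoles.
* `ischemia_lowvar` — Gaussian at 710 ms with sd compressed to 25 ms:
  shorter mean interval and depressed SDNN relative to healthy, the
  direction (not the magnitudes) of the clinical contrast.
* `fgn` — fractional Gaussian noise by circulant embedding
  (Davies–Harte), chosen because it reproduces the target autocovariance
  exactly, giving DFA and R/S a controlled Hurst exponent to recover;
  Cholesky fallback for non-PSD embeddings up to $n = 4096$.
* `modulated`, `alternating`, `ramp`, `periodic` — single-tone,
  anti-correlated, maximally persistent and strictly regular fixtures
  for the spectral, DFA, Hurst and entropy limits.

Intervals are clipped to a 1 ms floor with the clip count reported,
never silently. Every generator is a pure function of (parameters,
seed); cohorts derive distinct per-subject seeds from a master seed.
What the generators do *not* emulate matters for interpretation: no
respiratory sinus arrhythmia, no circadian trend, no ectopic-beat
morphology, no missing data. Passing tests demonstrate estimator
correctness on controlled structure, not clinical validity on real
recordings.

## Cohort statistics and flagging

Group comparisons use the two-sided unequal-variance (Welch) t-test by
default — the pooled test is a switch — and paired comparisons the
paired t-test, with means ± sample sd per group and p-values banded
`<0.001`, `<0.005`, `<0.01`, `<0.05`, `NS`. Significance is the
inclusive rule $p \le 0.05$, so the boundary value is significant and
the top band admits it. No multiple-testing correction is applied
across the battery by design; `p.adjust` can be layered on by the user.
Zero-variance degeneracies return p = 1 (equal means) or p = 0
(unequal), flagged, instead of erroring.

Normal-range flagging uses closed intervals (boundary values are in
range) against published healthy-adult references: SDNN 102–180 ms,
SDANN 92–162 ms, RMSSD 15–39 ms, triangular index 22–52, mean heart
rate 60–100 beats/min, and the 333/2000 ms physiologic interval bounds
(reconciling tables that print those bounds as 0.333/2.0 under an "ms"
header — the values are seconds; the package works in milliseconds
throughout). Parameters without an accepted reference — pNN50, TINN,
SDNN index, the nonlinear and spectral sets — are flagged
`no_reference`, never force-fitted to a range.

## Numerical and interface choices

* Configuration files are YAML; `hrv_config()` exposes every constant
  named above (bin width, DFA ranges and order, entropy $m$/$r$ factor
  and cap, Hurst correction, resampling rate, window lengths, bands,
  t-test variant).
* The command-line front end (`inst/cli/hrv.R`) is a thin wrapper over
  the exported functions: `analyze`, `synth`, `compare`.
* Reports serialize to JSON with `NA` mapped to `null`; repeated runs on
  identical input and configuration are byte-identical.
* Test and validation problem sizes were chosen to make stochastic
  checks decisive yet quick: 10,000-beat series and 20 seeds for the
  DFA/Hurst anchors (sd of the mean ≈ 0.002 for the white-noise
  anchor), 1,000 replicates for t-test calibration, exhaustive oracles
  at $n \le 40$ where enumeration is exact.

## Known limitations

Bounds-based cleaning cannot recognize ectopic beats inside the
plausibility band; TINN is quantized to the bin-edge grid; DFA-1 carries
the small-box bias discussed above; the R/S correction assumes
iid-Gaussian finite-sample behaviour and can overcorrect strongly
persistent short series; spline resampling distorts the spectrum near
and above the mean beat frequency; and the synthetic cohorts are
stationary by construction, so SDANN — which measures slow drift — is
small on them relative to real 24 h recordings.
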