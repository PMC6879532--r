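---
title: "Methods: the frontal theta/gamma index pipeline"
author: "stmli package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the frontal theta/gamma index pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmli)
```

This vignette is the package's account of its science: the measurement
model, the tunable parameters and why their defaults are what they are, what
the synthetic-data generator does and does not emulate, the numerical
choices, and the known limitations. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The measurement model

The quantity of interest is a frontal-midline short-term memory load index:
the ratio of relative theta (3–7 Hz) to relative gamma (30–40 Hz) power
spectral density at Fz, computed for every one-second epoch of each timed
task and aggregated per participant × task with a 5% per-tail trimmed mean.
"Relative" means each 1-Hz bin's power divided by the summed power over
bins 1–40, which makes the index invariant to amplifier gain and to any
×100-style rescaling of the relative values.

The chain mirrors a hardware EEG stack:

- 9 scalp channels + 2 mastoids at 256 Hz, linked-mastoid referencing
  (each scalp channel minus the mastoid average; guarded against double
  application).
- Zero-phase Butterworth band-pass 0.5–65 Hz and notches at
  50/60/100/120 Hz.
- Rule-based artifact detection, then **zero insertion**: flagged samples
  are replaced by exactly zero rather than corrected. Zeros are countable
  downstream, which is what the rejection rules key on.
- Per epoch, three 50%-overlapping one-second overlays (256 samples each)
  are Kaiser-tapered and FFT'd into 1-Hz bins 1–40. An overlay with more
  than 128 inserted zeros is rejected; an epoch with fewer than two usable
  overlays is invalid. Valid overlays are averaged, then normalized to
  relative power.
- Band values are plain means of their constituent relative bins
  (theta 3–7, alpha 8–12, low beta 13–19, high beta 20–29, gamma 30–40).

### Overlay geometry

The overlay scheme for the epoch starting at time *t* uses windows at
*t* − 0.5 s, *t*, and *t* + 0.5 s, clamped to the task interval: the first
and last epochs of a task proceed with their two available overlays, and a
one-second task (a single overlay) yields only invalid epochs. This is the
symmetric reading of "50% overlapping windows across three one-second
overlays"; the exact alignment at task starts is a declared convention, not
something the hardware documents.

### Relative-power domain

Two conventions are implemented (`relDomain` in `pipelineOptions()`):

- `"linear"` (default): bin power divided by the 1–40 Hz sum. Bins sum to
  one; band values are small positive fractions; theta exceeds gamma in
  1/f-dominated EEG, so the index is greater than one on the synthetic
  data.
- `"log10"`: the log-relative convention, −log10 of the linear relative
  bin. This is unit-free and positive, and band averages land on the
  magnitude scale vendor stacks report (theta ≈ 1.2, gamma ≈ 2.5 for
  typical 1/f EEG), with index values near 0.5. We do not assert that this
  is the convention behind any published table; the printed values cannot
  be reverse-engineered unambiguously. Note that a literal
  "relative-of-log-power" construction (log10 PSD divided by the sum of
  log10 PSDs) is ill-defined on realistic microvolt data — bin powers
  below 1 µV² make the logs change sign and the denominator can pass
  through zero — which is why the monotone log-relative form is used
  instead.

Because −log10 is monotone *decreasing*, a group effect driven by gamma
power has opposite sign in the two conventions: more gamma lowers the
linear-domain index and raises the log-domain index. The pipeline tests
assert exactly this pair of signs. Within either convention the index is
scale-invariant, so the choice affects interpretation, not detectability.

### Spectral normalization

Overlay powers carry a Parseval normalization
(2|X<sub>k</sub>|²/(N·Σw²)): the total one-sided power equals the mean
square amplitude, so a unit-RMS sinusoid contributes unit total power
regardless of the taper shape. A taper necessarily spreads that power over
its main lobe (about ±2 bins for Kaiser β = 8), so single-bin
concentration is checked over the peak bin plus direct neighbors. The
Kaiser β defaults to 8 (≈ −58 dB sidelobes), configurable.

## Artifact detection

The acquisition vendor's detectors are proprietary; the package ships one
auditable rule per artifact class, all thresholds configurable
(`artifactThresholds()`):

| class | rule (defaults) |
|---|---|
| saturation | \|x\| ≥ 1000 µV for ≥ 4 consecutive samples |
| spike | successive-difference jump > 40 µV |
| excursion | \|x − 1-s running median\| > 200 µV |
| EMG | sliding 0.25-s RMS of the ≥ 30 Hz component > 30 µV, grown to 0.5× threshold |
| blink | 0.5–8 Hz frontal component > 75 µV peak, grown to 0.2× threshold, padded 0.1 s |

Two defaults deserve justification. The spike threshold is expressed on the
*filtered* signal: an isolated 200 µV single-sample spike emerges from the
0.5–65 Hz zero-phase chain as an oscillatory transient whose largest
successive difference is near 60 µV, so a raw-amplitude-scale threshold
would miss it entirely. Similarly the blink threshold sits below the
nominal 100 µV deflection floor because the 0.5–8 Hz component retains only
~80% of a 0.4-s blink's peak. Detected events are extended by hysteresis
(the surrounding region where the detection signal stays above a fraction
of threshold) and padded, because blink and EMG onsets/offsets taper below
any fixed threshold; without the extension, sample-level recall on
threshold-grazing events plateaus near 75%.

Detection quality is measured against the generator's truth mask as
*union* recall: an artifact sample counts as caught if any detector class
flags it (a filtered saturation plateau, for instance, is legitimately
claimed partly by the excursion rule). The suite requires ≥ 90% recall per
injected class and < 1% false positives on clean sessions.

## Filter design choices

All filters are applied forward–backward (zero phase), which squares the
magnitude response. Design parameters account for this:

- The band-pass is an order-4 high-pass plus order-4 low-pass cascade
  rather than a single order-8 band-pass polynomial (numerically safer at
  0.5 Hz/256 Hz). Cutoffs are widened in the bilinear-prewarped domain so
  the *overall* response is −3 dB at 0.5 and 65 Hz.
- Each notch is two cascaded second-order sections with a constant 3.2 Hz
  design stopband, prewarped so the width holds in Hz at every center
  frequency. A single wider biquad cannot simultaneously achieve ≥ 20 dB
  attenuation within ±0.5 Hz and < 1 dB change at ±5 Hz for the 120 Hz
  notch, which sits close to the 128 Hz Nyquist frequency; the cascade
  does, at all four line frequencies.

## The synthetic-data generator

`simulateSession()` builds, per channel, 1/f<sup>α</sup> Gaussian
background (α = 1, 10 µV RMS) plus fixed-frequency sinusoids at the band
centers (theta 5 Hz, alpha 10 Hz, gamma 35 Hz) with a fresh random phase
each second, then injects artifacts: 0.4-s raised-cosine blinks
(100–300 µV, frontal channels), 1–3 s broadband 20–100 Hz EMG bursts
(60 µV RMS, the level of a jaw clench), single-sample 200 µV spikes, and
0.5-s rail saturations, at default rates of 4, 2, 1 and 0.5 events/minute.
Mastoids are near-zero noise, so linked-mastoid referencing is exercised
without distorting the scalp truth.

Defaults encode the emulated study: 56 participants without and 17 with a
concussion history, nine 60-second tasks, and a 25% gamma-amplitude
elevation in the concussion group on the four visuo-motor-loaded tasks
(PS, HRT, EHC, GNG) — the direction and locus of the group effect the
index is meant to detect, sized so the planted effect is comfortably
detectable at these group sizes. Oscillator RMS amplitudes (theta 4,
alpha 3, gamma 2 µV) are ordinary resting-EEG magnitudes against the 10 µV
background. Between-participant variability is a per-band lognormal
amplitude multiplier with sdlog 0.05; real populations vary far more, but
the generator's role is to provide a known, recoverable ground truth, not
population realism.

Because the generating amplitudes are known, each session carries analytic
relative band powers (oscillator RMS² plus the closed-form 1/f band
integral, normalized over 1–40 Hz). Two technical notes: the background is
synthesized down to 0.125 Hz — half an octave below the 0.5 Hz analysis
edge — because truncating it at exactly 0.5 Hz starves the tapered bin-1
estimate of leak-in and biases every *relative* band value upward by
~10%; and the per-epoch phase reset introduces slight leakage in overlays
that straddle epoch boundaries, which the band averages absorb.

What the generator does **not** emulate: head-model/volume-conduction
structure across channels (channels share oscillators but have independent
backgrounds), cross-frequency phase–amplitude coupling, non-stationary
band power within a task, realistic inter-channel artifact topographies,
or behavioral test scores. Passing tests therefore demonstrate that the
chain recovers known spectral contrasts under realistic noise and artifact
load — not that the index separates clinical groups in real recordings.

## Statistics

The statistics mirror the SPSS-style chain such studies report:

- **Levene-gated t-tests.** The mean-centered Levene test at α = 0.05
  selects the pooled or Welch variant per measure. An optional per-tail
  trim (floor(0.05·n) values per side) mirrors the trimmed-means treatment
  of skewed behavioral scores.
- **Dunn–Bonferroni.** Two-tailed per-comparison level α/m, critical t
  from the t quantile at the stated degrees of freedom. For nine
  comparisons at df = 71 this quantile is `qt(1 - 0.025/9, 71)` ≈ 2.77;
  published tables sometimes print slightly different critical values
  whose provenance (df or table used) is not recoverable, so the package
  always computes the quantile from its stated inputs.
- **Mahalanobis screening.** Squared distances against χ²(df = number of
  tasks) at p < 0.001, the conventional cutoff; exceeders are excluded and
  logged.
- **Mixed ANOVA.** Classical weighted cell-mean decomposition for one
  between × one within design. Cell frequencies are proportional by
  construction (every subject supplies every task), so the partition is
  orthogonal and matches `aov()`'s error strata exactly (a test asserts
  this). Mauchly's test uses the two-term Box series approximation (as in
  `stats::mauchly.test` and SPSS) on the pooled within-group covariance;
  when significant at 0.05, Greenhouse–Geisser ε rescales the
  within-effect degrees of freedom. ε is reported with its analytic bounds
  1/(k−1) ≤ ε ≤ 1, and partial η² = SS<sub>effect</sub>/(SS<sub>effect</sub> +
  SS<sub>error</sub>) per effect. With two within levels (the component
  ANOVA) sphericity is trivial and no correction is attempted.
- **PCA.** Eigen-decomposition of the correlation matrix (unit-free
  loadings), retention at eigenvalue > 0.80, varimax rotation with Kaiser
  normalization (`stats::varimax`, tolerance 1e-6), column signs fixed so
  loading sums are non-negative. KMO is computed from anti-image partial
  correlations; Bartlett's χ² = −(n−1−(2p+5)/6)·log det R with
  df = p(p−1)/2.
- **Anderson–Rubin scores.** Z R⁻¹ L (Lᵀ R⁻¹ L)<sup>−1/2</sup>, which have
  exactly zero mean and identity covariance in-sample; this defining
  property is asserted to 1e-6.

One derived property deserves a note: when a group effect lives on one of
two uncorrelated unit-variance components, the between-group main effect
and the group × component interaction have *equal* noncentrality, so
neither F systematically exceeds the other; what is guaranteed — and what
the tests check — is that the interaction itself is detected at large
effect sizes.

## Numerical and degenerate-input conventions

- Marker intervals are 0-based, half-open `[start, end)`; trailing partial
  seconds of a task are discarded; sub-second tasks yield zero epochs with
  a warning.
- EDF is written with a fixed ±3276.8 µV physical range (0.1 µV/bit);
  out-of-range samples clip with a warning; recordings are zero-padded to
  whole one-second records.
- Epochs whose relative gamma power is exactly zero (possible only on
  degenerate synthetic input) are dropped with a logged reason rather than
  yielding infinite ratios.
- Missing participant × task cells are explicit `NA`s; each analysis
  applies listwise deletion and reports what it removed. Single-group
  cohorts are refused by the statistics stage.
- Determinism: every simulation is a pure function of (config, seed);
  per-participant seeds derive from the cohort seed; the run report is
  byte-identical across repeated runs on the same inputs.

## Problem sizes used by the checks

The test suite and acceptance script run at deliberately chosen scales:
spectral conservation over 1000 epochs; rejection boundaries exhaustively;
the trimmed-mean oracle on 1000 random vectors; type-I error from 10,000
(t-test) and 5,000 (mixed ANOVA) null replicates; full-chain recovery on
50 cohorts of 56 + 17 participants with 10-second tasks; PCA recovery at
n = 500. The 10-second task length keeps a 73-session cohort to a few
seconds of compute while still giving each participant × task ten epochs —
enough for the trimmed mean to act and for the planted contrast to
dominate epoch noise.

## Limitations

- The artifact detectors are reasonable single-rule stand-ins, not a
  reimplementation of any vendor's proprietary algorithms; agreement with
  the original hardware's rejection behavior cannot be verified.
- The published study's real-data statistics (group means, F values, KMO,
  loadings) are not reproducible here because the underlying recordings
  are not publicly available; the package's accountability is to its
  synthetic ground truth and to analytic/oracle checks.
- The relative-PSD convention behind published band-value magnitudes is
  ambiguous; both supported conventions are explicit, and the index's
  group-difference *direction* depends on that choice (see above).
- Classical repeated-measures ANOVA, not mixed-effects models: missing
  cells cost the whole row, and epoch-level uncertainty is not propagated
  past the trimmed mean.
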