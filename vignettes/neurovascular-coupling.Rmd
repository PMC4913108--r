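---
title: "Estimating tDCS-evoked neurovascular coupling from joint NIRS-EEG recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating tDCS-evoked neurovascular coupling from joint NIRS-EEG recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvcoupling)
```

## The problem

Anodal transcranial direct current stimulation (tDCS) perturbs both
cortical excitability and regional hemodynamics. When cerebral oximetry
(rSO2, sampled at 10 Hz) and EEG (500 Hz) are recorded together under a
randomized ON/OFF block design — 50 s ON with 5 s ramps, 60 s OFF, fifteen
trials per hemisphere — the temporal relation between slow rSO2
fluctuations and the envelope of EEG band power carries information about
neurovascular coupling (NVC). The signature of interest is a positive
cross-correlation at a *negative* lag: the rSO2 slow component temporally
leads the EEG mean-power series, by roughly 15 s in the motivating
recordings, emerging only after several hundred seconds of cumulative
stimulation.

`nvcoupling` implements this analysis as a reproducible pipeline and ships
a synthetic-session generator with planted coupling so every stage can be
validated by parameter recovery. No patient data are distributed; the
generator stands in for them.

## Per-trial analysis chain

Each trial contributes the middle 50 s of its 60 s OFF period (5 s trimmed
from each end; half-open intervals so integer-ratio sampling rates give
exactly 500 rSO2 samples and 25 000 EEG samples). The EEG channel of
interest is spatially sharpened by a surround average — F3 minus the mean
of F1, FC3 and F5 on the left, F4 minus F2, FC4, F6 on the right; the
montage is configurable. Epochs failing an automated two-rule artifact
screen (any sample deviating more than `amp_threshold` = 100 µV from the
epoch median, or any 1 s window with variance above `var_ratio` = 25 times
the median window variance) are excluded and reported as missing. The
screen replaces interactive visual inspection for the sake of
reproducibility; it is a stand-in, not a reconstruction of expert
judgement.

Both epochs are then decomposed by Empirical Mode Decomposition. The
sifting loop subtracts the mean of the cubic-spline envelopes through the
maxima and minima until either the Cauchy criterion
$\sum (h_{k-1}-h_k)^2 / \sum h_{k-1}^2 < 0.2$ (the classic default) or the
extrema and zero-crossing counts agree within one for three consecutive
iterations (S-number rule), capped at 200 iterations — all three exposed
in the configuration. Envelope ends are handled by mirroring the two
extrema nearest each boundary, which limits end swing on the short
500-sample rSO2 epochs. Equal-valued plateaus contribute their centre
index once, a deterministic tie-break. Decomposition stops when the
residual has fewer than two maxima or two minima. The element-wise sum of
modes plus residual reproduces the input to a relative error below
$10^{-8}$, which the test suite verifies on a thousand random signals.

EEG intrinsic mode functions (IMFs) whose Hann-periodogram peak exceeds
50 Hz are discarded (a single full-length periodogram rather than Welch
averaging, preserving fine resolution on short epochs). Each retained EEG
IMF is converted to a log10 mean-power series: non-overlapping 0.1 s
windows of squared samples, floored at $10^{-12}$ times the epoch mean
power so the logarithm stays finite, which lands the power series on the
10 Hz grid of the rSO2 data without an extra anti-alias filter.

The normalized cross-correlation between a NIRS IMF $x$ and an EEG power
series $y$ is

$$ r(k) = \frac{\sum_t (x_{t+k}-\bar x)(y_t-\bar y)}{N s_x s_y}, $$

with the divisor fixed at $N$ (the biased estimator that standard
econometric cross-correlation routines use) and $k$ spanning ±20 s. Under
this convention a negative peak lag means the NIRS series leads the EEG
power. Values inside ±3 standard deviations of the white-noise estimation
error, $3/\sqrt{N}$, are set to zero; a lag-dependent
$3/\sqrt{N-|k|}$ variant is available. The bound, the lag window and the
number of standard deviations are all configurable.

## Aggregating across trials

EMD mode indices are not stable across epochs: the same physiological
oscillation can surface as the third mode in one trial and the fourth in
the next, because the stochastic high-frequency cascade above it varies.
Cross-trial aggregation therefore supports three pairing schemes. `rank`
(the default for single-trial inspection) pairs the i-th retained EEG IMF
with the i-th NIRS IMF; `all` crosses every combination; `band` — the
recommended mode for recovery — first assigns each IMF to a physiological
band by its peak frequency (NIRS: below 0.15 Hz, respiratory, cardiac;
EEG: slow, delta, theta, alpha, beta, gamma), sums same-band IMFs into one
representative series, and crosses the bands. The band sum matters:
EMD routinely splits a single oscillation across neighbouring modes, and
slow components with about one cycle per epoch partially leak into the
monotone residual, so the linearly-detrended residual joins the lowest
band. Band identity, unlike mode rank, is the same in every trial.

Correlations between two autocorrelated series overstate their evidence
if judged by $N$; a smooth rSO2 mode against a smooth power series can
reach $|r| > 0.5$ by chance. Every correlogram therefore carries a
Pyper-Peterman effective sample size,
$1/N_\mathrm{eff} = 1/N + (2/N)\sum_k w_k \rho_x(k)\rho_y(k)$, computed
from the two series' sample autocorrelations. Per-trial correlations
become approximate z-scores $\operatorname{atanh}(r)\sqrt{N_\mathrm{eff}-3}$.

The dominant IMF pair is selected by pooled evidence matched to the block
design: for each pair, lag and candidate onset trial $t_0$, the suffix sum
$\sum_{t \ge t_0} z_t(k) / \sqrt{T-t_0+1}$ is an approximately standard
normal scan statistic under the null; the pair whose maximum is largest
wins, provided it is present in at least half the trials and exceeds
`stouffer_min` = 3.6. That threshold was fixed once against simulated
uncoupled sessions, whose maximum scan scores concentrate between 2.4 and
3.4; coupled sessions under the default generator score between about 4
and 6.5. Sessions without coupling therefore report no dominant pair
rather than a spurious one.

A literal per-pair tally — "the pair with significant values in the most
trials" — is also provided (`dominant_imf()`), but note that under the
null roughly 1–2 % of the 401 lag bins survive the ±3σ rule, so nearly
every trial of every pair contains at least one surviving bin and the
tally saturates; it is kept for descriptive use and its documented
tie-break (lower index wins).

The coupling onset is the smallest hemisphere-local trial that *itself*
shows a surviving positive peak inside the lag band (default [−20, 0] s,
the NIRS-leads side) *and* from which at least `persistence` = 0.8 of the
remaining trials do too. Requiring the onset trial itself to qualify is
essential: without it the persistence inequality is satisfied one or two
trials before the true onset whenever the post-onset block is long enough,
purely by arithmetic. Cumulative stimulation time at onset counts the 50 s
ON plateaus only (ramps excluded), so an onset at hemisphere-local trial
11 corresponds to 550 s of anodal tDCS. The recovered coupling lag is the
peak of the effective-n-weighted pooled correlogram over post-onset
trials, which averages out the ±1–2 s peak jitter of individual trials.

## The synthetic session generator

Per hemisphere, a unit-variance Gaussian process $s(t)$ band-limited to
0.03–0.08 Hz drives both modalities. The rSO2 series is
`baseline + coupling_gain * s(t)` plus Mayer (0.1 Hz), respiratory
(0.25 Hz) and cardiac (1 Hz) sinusoids with random phases and white noise,
clamped to the physiological 40–90 % range. From the first sample of the
onset trial's ON interval, the EEG carrier envelope becomes the rectified
affine map `carrier_amp * max(0, 1 + envelope_mod * s(t - |lag|))`;
before onset it is constant. A negative `planted_lag` therefore makes the
rSO2 slow component lead the EEG power, matching the pipeline's sign
convention. An `eeg_leads` variant convolves $s$ with a gamma-variate
kernel on the NIRS side instead, for generality. EEG channels are the
carrier (centre channels F3/F4 only) plus independent 1/f noise (Kellet
three-pole filter), white noise, and a hemisphere-wide common-mode 1/f
component that the surround reference cancels exactly. Designated
artifact trials receive one to three 2–5 s bursts at ten times the
carrier amplitude inside the analysed OFF window.

Defaults, chosen once as physiologically plausible values (the motivating
study reports no noise amplitudes or baselines, so these are free
parameters of the generator, not fitted values): rSO2 baseline 65 %, slow
amplitude 2 % with 0.5/0.3/0.3 % systemic sinusoids and 0.15 % white
noise; EEG carrier 15 µV at 10 Hz with modulation depth 0.6, 8 µV white,
8 µV 1/f and 5 µV common-mode noise. All randomness flows from a single
integer seed; identical configuration and seed give bit-identical
sessions.

What the generator does *not* emulate: real EEG artifacts (eye blinks,
EMG) beyond stereotyped bursts, quasi-periodic rather than sinusoidal
systemic interference, rSO2 baseline drift, inter-subject variability, or
any biophysical neurovascular model. Passing recovery tests therefore
demonstrates that the pipeline measures what it claims under its own
generative assumptions — not that those assumptions exhaust real data.

## Validation by parameter recovery

The test suite and `scripts/acceptance.R` rerun, at fixed seeds:

* EMD completeness on 1000 random tone-plus-noise signals of 500–25 000
  samples (200 in the faster acceptance script);
* two-tone separation (10 Hz + 1 Hz) with frequency-ordered modes;
* exact agreement of the cross-correlation with a double-loop
  implementation at every lag, and a 150-sample shift test peaking at
  −15 s;
* a 50-session recovery study with the planted lag drawn uniformly from
  [−18, −5] s and the onset trial from {5, …, 12}; the session-level
  recovered lag (hemisphere mean) falls within ±1 s of truth and the
  onset is identified exactly at the rates the tests assert (observed in
  development: 100 % and 95 % of hemisphere analyses respectively);
* type-I control: across 1000 uncoupled white-noise pairs, well under 2 %
  of lag bins survive the ±3σ rule;
* the block-protocol arithmetic (550 s through trial 11; fifteen trials
  per hemisphere in the reference order; 50 s trimmed epochs).

These problem sizes keep the whole suite within a coffee break on one
core while leaving the statistical conclusions stable across seeds.

## Geometry helper

A slim spherical model supports probe-placement arithmetic: a
least-squares sphere through a packaged idealized 10-20/10-10 coordinate
set (synthetic, constructed from the standard arc-fraction scheme on a
92 mm sphere — not digitized human positions), great-circle placement of
a source 15 mm from FC1 toward Cz and detectors at 8 and 30 mm along-arc
toward F3, and both chord and along-arc separations. Printed MNI probe
coordinates from the motivating montage give a source-to-short-detector
chord of √98 ≈ 9.9 mm, usefully different from the 8 mm along-scalp
specification — the helper reports both metrics and adjudicates neither.
Forward modelling (FEM current flow, photon transport) is out of scope.

## Known limitations

* A 50 s epoch contains roughly five effective degrees of freedom of the
  0.03–0.08 Hz band, capping per-trial evidence regardless of noise
  level; all power comes from pooling trials, so designs with fewer than
  about four post-onset trials are near the detection floor.
* The onset rule reports the first trial of *sustained* coupling; a
  single isolated coupled trial is treated as noise.
* Onset indices are hemisphere-local (trial k of that hemisphere's
  fifteen), matching per-hemisphere trial-by-lag maps.
* EDF input is not supported; sessions are CSV plus a JSON sidecar.
* `rank` pairing reproduces the historical analysis style but cannot find
  coupling when mode ranks differ across modalities; use `band` for
  recovery.
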