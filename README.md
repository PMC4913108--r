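# nvcoupling

Neurovascular coupling (NVC) analysis for joint NIRS–EEG recordings under
transcranial direct current stimulation (tDCS) block designs.

When cerebral oximetry (regional hemoglobin oxygen saturation, rSO2, at
10 Hz) and EEG (500 Hz) are recorded together through a randomized block
protocol — 50 s of anodal tDCS with 5 s ramps, 60 s OFF, fifteen trials
per hemisphere — the lagged relation between slow rSO2 fluctuations and
the EEG band-power envelope probes the coupling between neural activity
and perfusion. The package is for researchers running such multimodal
stimulation protocols (and for anyone who wants a tested, from-scratch
Empirical Mode Decomposition in R).

## Method

Per trial, on the middle 50 s of each OFF period:

1. surround-average spatial referencing (F3 − mean(F1, FC3, F5), and the
   right-hemisphere mirror), plus an automated amplitude/variance artifact
   screen;
2. Empirical Mode Decomposition of both the rSO2 and referenced EEG
   epochs by cubic-spline envelope sifting (Cauchy criterion 0.2,
   S-number 3, mirrored boundaries);
3. EEG intrinsic mode functions with periodogram peak power above 50 Hz
   are discarded; the rest are converted to log10 mean-power series on
   0.1 s windows, landing on the 10 Hz rSO2 grid;
4. normalized cross-correlation over lags of ±20 s,

   r(k) = Σₜ (x₍ₜ₊ₖ₎ − x̄)(yₜ − ȳ) / (N·sₓ·s_y),

   with x the NIRS mode and y the EEG power series, so a **negative peak
   lag means NIRS leads EEG power**; values within ±3 standard deviations
   of the white-noise estimation error (3/√N) are zeroed.

Across trials the correlograms are assembled into trial-by-lag maps, the
dominant IMF pair is selected by an onset-aware pooled-evidence scan
(per-trial correlations weighted by their Pyper–Peterman effective sample
size), the coupling onset trial is detected by a persistence rule, and
the coupling lag is read off the pooled post-onset correlogram. A
synthetic session generator with a planted lag, onset trial and artifact
trials makes the whole chain verifiable by parameter recovery; a slim
spherical geometry helper handles NIRS probe placement along the F3–Cz
scalp arc.

## Worked example

Simulate a session whose rSO2 slow component leads the EEG alpha-power
envelope by 15 s from the eighth trial per hemisphere onward, then
recover those parameters:

```r
library(nvcoupling)

cfg <- session_config(planted_lag = -15, coupling_onset_trial = 8,
                      rng_seed = 11)
session <- generate_session(cfg)
report <- run_pipeline(run_config(pairing = "band"), session = session)
glance(report)
#>   hemisphere dominant_pair pair_label imf_nirs imf_eeg onset_trial
#> 1       left             4  lowxalpha        4       3           8
#> 2      right             4  lowxalpha        4       3           8
#>   cumulative_stim_s recovered_lag_s n_rejected
#> 1               400           -14.7          0
#> 2               400           -14.9          0
```

Reading the output: in both hemispheres the dominant pair couples the
low-frequency (< 0.15 Hz) rSO2 mode to the alpha-band EEG power
(`lowxalpha`); coupling is detected from trial 8 — i.e. after
8 × 50 s = 400 s of cumulative stimulation — and the recovered lags of
−14.7 and −14.9 s sit within 0.3 s of the planted −15 s, negative because
the NIRS mode leads. `autoplot(report)` draws the trial-by-lag heatmaps;
`tidy(report)` returns them as a long tibble; `write_session()` /
`read_session()` round-trip sessions through CSV + JSON for use with real
recordings in the same layout.

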