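#' Configuration for a synthetic joint NIRS-EEG session
#'
#' Encodes the block-design protocol (15 trials per hemisphere of 50 s ON
#' with 5 s ramps and 60 s OFF, EEG at 500 Hz, rSO2 at 10 Hz) together with
#' the planted coupling structure and noise model of the generator. Defaults
#' are the study conditions the pipeline is designed for; noise amplitudes
#' and baselines are documented free parameters.
#'
#' @param n_trials_per_hemisphere Trials per hemisphere (default 15).
#' @param on_duration ON plateau, seconds (default 50).
#' @param ramp_duration Ramp-up and ramp-down, seconds (default 5).
#' @param off_duration OFF period, seconds (default 60).
#' @param eeg_rate EEG sampling rate, Hz (default 500); must be an integer
#'   multiple of `nirs_rate`.
#' @param nirs_rate rSO2 sampling rate, Hz (default 10).
#' @param planted_lag Seconds, scalar or named `c(left=, right=)`; negative
#'   means the NIRS slow component leads the EEG mean-power envelope
#'   (default -15).
#' @param coupling_onset_trial 1-based hemisphere-local trial index at whose
#'   ON start the coupling switches on; scalar or named pair (default 11).
#' @param coupling_gain Amplitude (rSO2 % units) of the slow latent process
#'   in the rSO2 series; 0 disables coupling entirely (default 2).
#' @param mayer_amp,resp_amp,cardiac_amp Amplitudes (rSO2 %) of the ~0.1 Hz
#'   Mayer, ~0.25 Hz respiratory and ~1 Hz cardiac interference sinusoids.
#' @param eeg_noise_sd Broadband white EEG noise SD, microvolts (default 8).
#' @param artifact_trials Integer vector of chronological session trial
#'   indices whose EEG receives high-amplitude transient contamination
#'   (default none).
#' @param rng_seed Integer seed; identical config + seed gives bit-identical
#'   sessions.
#' @param nirs_noise_sd White rSO2 noise SD, percent (default 0.15).
#' @param nirs_baseline rSO2 baseline, percent (default 65).
#' @param carrier_freq EEG carrier frequency, Hz (default 10, alpha/mu band).
#' @param carrier_amp EEG carrier amplitude, microvolts (default 15).
#' @param envelope_mod Modulation depth of the carrier envelope by the slow
#'   process (default 0.6); the envelope is the rectified affine map
#'   `carrier_amp * max(0, 1 + envelope_mod * s(t - |lag|))`.
#' @param pink_sd Per-channel 1/f EEG noise SD, microvolts (default 8).
#' @param common_mode_sd SD of the 1/f component shared by all channels of a
#'   hemisphere (cancelled exactly by surround referencing; default 5).
#' @param slow_band Passband (Hz) of the slow latent process
#'   (default `c(0.03, 0.08)`).
#' @param coupling_mode `"nirs_leads"` (default; EEG envelope follows the
#'   delayed slow process, so rSO2 leads) or `"eeg_leads"` (rSO2 is the slow
#'   process convolved with a gamma-variate kernel peaking at `|planted_lag|`).
#' @return A validated list of class `nvc_session_config`.
#' @export
session_config <- function(n_trials_per_hemisphere = 15,
                           on_duration = 50,
                           ramp_duration = 5,
                           off_duration = 60,
                           eeg_rate = 500,
                           nirs_rate = 10,
                           planted_lag = -15,
                           coupling_onset_trial = 11,
                           coupling_gain = 2,
                           mayer_amp = 0.5,
                           resp_amp = 0.3,
                           cardiac_amp = 0.3,
                           eeg_noise_sd = 8,
                           artifact_trials = integer(0),
                           rng_seed = 1L,
                           nirs_noise_sd = 0.15,
                           nirs_baseline = 65,
                           carrier_freq = 10,
                           carrier_amp = 15,
                           envelope_mod = 0.6,
                           pink_sd = 8,
                           common_mode_sd = 5,
                           slow_band = c(0.03, 0.08),
                           coupling_mode = c("nirs_leads", "eeg_leads")) {
  coupling_mode <- match.arg(coupling_mode)
  cfg <- list(
    n_trials_per_hemisphere = as.integer(n_trials_per_hemisphere),
    on_duration = on_duration, ramp_duration = ramp_duration,
    off_duration = off_duration, eeg_rate = eeg_rate, nirs_rate = nirs_rate,
    planted_lag = both_hemispheres(planted_lag),
    coupling_onset_trial = both_hemispheres(coupling_onset_trial),
    coupling_gain = coupling_gain, mayer_amp = mayer_amp,
    resp_amp = resp_amp, cardiac_amp = cardiac_amp,
    eeg_noise_sd = eeg_noise_sd,
    artifact_trials = as.integer(artifact_trials),
    rng_seed = as.integer(rng_seed),
    nirs_noise_sd = nirs_noise_sd, nirs_baseline = nirs_baseline,
    carrier_freq = carrier_freq, carrier_amp = carrier_amp,
    envelope_mod = envelope_mod, pink_sd = pink_sd,
    common_mode_sd = common_mode_sd, slow_band = slow_band,
    coupling_mode = coupling_mode
  )
  validate_session_config(cfg)
  structure(cfg, class = "nvc_session_config")
}

both_hemispheres <- function(x) {
  if (length(x) == 1) {
    return(c(left = unname(x), right = unname(x)))
  }
  if (length(x) == 2 && all(c("left", "right") %in% names(x))) {
    return(x[c("left", "right")])
  }
  abort("per-hemisphere values must be a scalar or named c(left=, right=).",
        class = "nvc_invalid_argument")
}

validate_session_config <- function(cfg) {
  stop_if <- function(cond, msg) {
    if (cond) abort(msg, class = "nvc_invalid_argument")
  }
  stop_if(cfg$n_trials_per_hemisphere < 1, "n_trials_per_hemisphere must be >= 1")
  durs <- c(cfg$on_duration, cfg$ramp_duration, cfg$off_duration)
  stop_if(any(durs <= 0), "all durations must be > 0")
  stop_if(cfg$eeg_rate <= 0 || cfg$nirs_rate <= 0, "rates must be > 0")
  stop_if(cfg$eeg_rate %% cfg$nirs_rate != 0,
          "eeg_rate must be an integer multiple of nirs_rate")
  stop_if(any(cfg$coupling_onset_trial < 1 |
                cfg$coupling_onset_trial > cfg$n_trials_per_hemisphere),
          "coupling_onset_trial must lie in 1..n_trials_per_hemisphere")
  stop_if(cfg$coupling_gain < 0, "coupling_gain must be >= 0")
  n_session <- 2L * cfg$n_trials_per_hemisphere
  stop_if(length(cfg$artifact_trials) > 0 &&
            any(cfg$artifact_trials < 1 | cfg$artifact_trials > n_session),
          "artifact_trials must index session trials 1..2n")
  stop_if(length(cfg$slow_band) != 2 || cfg$slow_band[1] >= cfg$slow_band[2],
          "slow_band must be c(low, high) with low < high")
  invisible(cfg)
}

#' Full run configuration for the analysis pipeline
#'
#' Collects every tunable of the pipeline in one fail-closed list: unknown
#' names are rejected before any computation. The effective configuration is
#' echoed into the output manifest of [run_pipeline()].
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A list of class `nvc_run_config`.
#' @section Tunables:
#' `lead_trim`, `trail_trim` (s); `amp_threshold` (uV), `var_ratio`
#' (artifact screen); `cutoff_hz` (IMF screen); `max_lag_s`, `n_std`,
#' `lag_dependent_bound`; `sd_thresh`, `s_number`, `max_iter`, `max_imfs`
#' (sifting); `pairing` ("rank", "all" or "band"); `min_r` (NULL = any
#' value surviving the zeroing rule), `lag_band`, `persistence` (onset
#' rule); `stouffer_min` (pooled-evidence score a pair must reach to be
#' reported as dominant);
#' `target_rate` (Hz); `montages` (named list of center/surround);
#' `input_dir`, `output_dir`, `session` (a config for simulation), `seed`.
#' @export
run_config <- function(...) {
  defaults <- list(
    lead_trim = 5, trail_trim = 5,
    amp_threshold = 100, var_ratio = 25,
    cutoff_hz = 50, max_lag_s = 20, n_std = 3, lag_dependent_bound = FALSE,
    sd_thresh = 0.2, s_number = 3, max_iter = 200, max_imfs = 12,
    pairing = "rank", target_rate = 10,
    min_r = NULL, lag_band = c(-20, 0), persistence = 0.8,
    stouffer_min = 3.6,
    montages = list(
      left = list(center = "F3", surround = c("F1", "FC3", "F5"), nirs = "left"),
      right = list(center = "F4", surround = c("F2", "FC4", "F6"), nirs = "right")
    ),
    input_dir = NULL, output_dir = NULL, session = NULL, seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown run_config key(s): ", paste(unknown, collapse = ", ")),
          class = "nvc_invalid_argument")
  }
  cfg <- utils::modifyList(defaults, dots, keep.null = TRUE)
  if (!cfg$pairing %in% c("rank", "all", "band")) {
    abort("pairing must be 'rank', 'all' or 'band'",
          class = "nvc_invalid_argument")
  }
  structure(cfg, class = "nvc_run_config")
}
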