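#' Randomized hemisphere order for a block-design session
#'
#' Each hemisphere label appears exactly `n_per_hemisphere` times; the
#' permutation is a deterministic function of the seed.
#'
#' @param n_per_hemisphere Trials per hemisphere (>= 1).
#' @param rng_seed Integer seed.
#' @param labels Two hemisphere labels (default `c("left", "right")`).
#' @return Character vector of length `2 * n_per_hemisphere`.
#' @export
make_trial_order <- function(n_per_hemisphere, rng_seed,
                             labels = c("left", "right")) {
  if (length(n_per_hemisphere) != 1 || n_per_hemisphere < 1) {
    abort("`n_per_hemisphere` must be a positive count.",
          class = "nvc_invalid_argument")
  }
  withr::with_seed(rng_seed, sample(rep(labels, n_per_hemisphere)))
}

# 1/f ("pink") Gaussian noise, m independent unit-SD columns, via the
# classic Kellet three-pole filter cascade (flat -3 dB/octave over ~3
# decades below Nyquist; cheap enough for megasample EEG records).
pink_noise <- function(n, m) {
  out <- matrix(0, n, m)
  for (j in seq_len(m)) {
    p <- cpp_kellet(rnorm(n))
    out[, j] <- p / sqrt(mean(p^2))
  }
  out
}

# Sampling rate from a time axis, snapped to integer when within 1e-6.
infer_rate <- function(time_s) {
  r <- 1 / median(diff(time_s))
  if (abs(r - round(r)) < 1e-6 * max(1, r)) round(r) else r
}

# Band-limited unit-variance Gaussian process sampled at `rate`.
band_limited_noise <- function(n, rate, band) {
  w <- rnorm(n)
  f <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1)) * rate / n
  keep <- f >= band[1] & f <= band[2]
  if (!any(keep)) keep <- abs(f - mean(band)) == min(abs(f - mean(band)))
  x <- Re(fft(fft(w) * keep, inverse = TRUE)) / n
  as.numeric(x / stats::sd(x))
}

# Gamma-variate kernel (unit area) peaking at `peak_s`, for the eeg_leads
# generator variant; shape fixed at 3.
gamma_kernel <- function(rate, peak_s, shape = 3) {
  scale <- peak_s / (shape - 1)
  t <- seq(0, peak_s * 4, by = 1 / rate)
  k <- stats::dgamma(t, shape = shape, scale = scale)
  k / sum(k)
}

#' Generate a synthetic two-hemisphere joint NIRS-EEG session
#'
#' Per hemisphere a slow band-limited Gaussian latent process `s(t)` enters
#' the rSO2 series directly (`baseline + coupling_gain * s(t)` plus Mayer,
#' respiratory and cardiac sinusoids and white noise), while from the onset
#' trial's ON start onward the EEG carrier amplitude envelope is a rectified
#' affine map of `s(t - |planted_lag|)` — so the NIRS slow component
#' temporally leads the EEG mean-power. EEG channels are the envelope-
#' modulated carrier (centre channels F3/F4 only) plus independent 1/f and
#' white noise and a common-mode 1/f component shared within a hemisphere.
#' Designated artifact trials receive 10x-amplitude transients inside the
#' analyzed OFF window of the centre channel.
#'
#' @param config A [session_config()].
#' @return A list of class `nvc_session` with elements `eeg` (tibble,
#'   `time_s` + 8 channels), `nirs` (tibble, `time_s`, `left`, `right`),
#'   `schedule` (tibble of trial intervals), `truth` (ground-truth record)
#'   and `config`.
#' @examples
#' s <- generate_session(session_config(n_trials_per_hemisphere = 2,
#'                                      rng_seed = 7))
#' s$schedule
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "nvc_session_config"))
  validate_session_config(config)
  withr::with_seed(config$rng_seed, generate_session_impl(config))
}

generate_session_impl <- function(cfg) {
  n_trial <- 2L * cfg$n_trials_per_hemisphere
  trial_len <- 2 * cfg$ramp_duration + cfg$on_duration + cfg$off_duration
  duration <- n_trial * trial_len
  order <- sample(rep(c("left", "right"), cfg$n_trials_per_hemisphere))

  starts <- (seq_len(n_trial) - 1) * trial_len
  schedule <- tibble::tibble(
    trial = seq_len(n_trial),
    hemisphere = order,
    marker_s = starts,
    on_start = starts + cfg$ramp_duration,
    on_end = starts + cfg$ramp_duration + cfg$on_duration,
    off_start = starts + 2 * cfg$ramp_duration + cfg$on_duration,
    off_end = starts + trial_len
  )

  n_e <- as.integer(round(duration * cfg$eeg_rate))
  n_n <- as.integer(round(duration * cfg$nirs_rate))
  t_e <- (seq_len(n_e) - 1) / cfg$eeg_rate
  t_n <- (seq_len(n_n) - 1) / cfg$nirs_rate

  montage <- list(left = c("F3", "F1", "FC3", "F5"),
                  right = c("F4", "F2", "FC4", "F6"))
  eeg <- matrix(0, n_e, 8,
                dimnames = list(NULL, unlist(montage, use.names = FALSE)))
  nirs <- matrix(0, n_n, 2, dimnames = list(NULL, c("left", "right")))

  for (h in c("left", "right")) {
    s <- band_limited_noise(n_n, cfg$nirs_rate, cfg$slow_band)
    lag <- abs(cfg$planted_lag[[h]])
    onset_local <- cfg$coupling_onset_trial[[h]]
    hemi_rows <- schedule[schedule$hemisphere == h, ]
    onset_time <- hemi_rows$on_start[onset_local]

    if (cfg$coupling_mode == "nirs_leads") {
      slow_nirs <- s
      # envelope follows the delayed slow process
      s_del <- stats::approx(t_n, s, xout = t_e - lag, rule = 2)$y
    } else {
      k <- gamma_kernel(cfg$nirs_rate, max(lag, 1 / cfg$nirs_rate))
      conv <- stats::filter(c(rep(s[1], length(k) - 1), s), k, sides = 1)
      slow_nirs <- as.numeric(conv[length(k):(length(k) - 1 + n_n)])
      slow_nirs <- slow_nirs / stats::sd(slow_nirs)
      s_del <- stats::approx(t_n, s, xout = t_e, rule = 2)$y
    }

    phases <- runif(3, 0, 2 * pi)
    nirs[, h] <- cfg$nirs_baseline +
      cfg$coupling_gain * slow_nirs +
      cfg$mayer_amp * sin(2 * pi * 0.1 * t_n + phases[1]) +
      cfg$resp_amp * sin(2 * pi * 0.25 * t_n + phases[2]) +
      cfg$cardiac_amp * sin(2 * pi * 1.0 * t_n + phases[3]) +
      rnorm(n_n, sd = cfg$nirs_noise_sd)

    active <- as.numeric(t_e >= onset_time) * (cfg$coupling_gain > 0)
    env <- cfg$carrier_amp *
      ((1 - active) + active * pmax(0, 1 + cfg$envelope_mod * s_del))
    carrier <- env * sin(2 * pi * cfg$carrier_freq * t_e + runif(1, 0, 2 * pi))

    pink <- pink_noise(n_e, 4) * cfg$pink_sd
    common <- pink_noise(n_e, 1)[, 1] * cfg$common_mode_sd
    chans <- montage[[h]]
    for (j in seq_along(chans)) {
      eeg[, chans[j]] <- pink[, j] + common +
        rnorm(n_e, sd = cfg$eeg_noise_sd) +
        if (j == 1) carrier else 0
    }
  }
  nirs <- pmin(pmax(nirs, 40), 90)

  # artifact transients: 1-3 bursts of 2-5 s at 10x carrier amplitude inside
  # the analyzed OFF window of the trial's centre channel
  for (tr in cfg$artifact_trials) {
    row <- schedule[tr, ]
    centre <- montage[[row$hemisphere]][1]
    n_burst <- sample(1:3, 1)
    for (b in seq_len(n_burst)) {
      dur <- runif(1, 2, 5)
      t0 <- runif(1, row$off_start + 5, row$off_end - 5 - dur)
      idx <- which(t_e >= t0 & t_e < t0 + dur)
      win <- 0.5 * (1 - cos(2 * pi * seq_along(idx) / (length(idx) + 1)))
      eeg[idx, centre] <- eeg[idx, centre] +
        10 * cfg$carrier_amp * win * sin(2 * pi * 3 * t_e[idx])
    }
  }

  structure(
    list(
      eeg = tibble::as_tibble(cbind(tibble::tibble(time_s = t_e),
                                    tibble::as_tibble(eeg))),
      nirs = tibble::tibble(time_s = t_n, left = nirs[, "left"],
                            right = nirs[, "right"]),
      schedule = schedule,
      truth = list(
        planted_lag = cfg$planted_lag,
        coupling_onset_trial = cfg$coupling_onset_trial,
        artifact_trials = cfg$artifact_trials,
        rng_seed = cfg$rng_seed,
        coupling_gain = cfg$coupling_gain,
        coupling_mode = cfg$coupling_mode
      ),
      config = cfg
    ),
    class = "nvc_session"
  )
}

#' @export
print.nvc_session <- function(x, ...) {
  cat(sprintf(
    "<nvc_session> %d trials (%d/hemisphere), %g s, EEG %g Hz x %d ch, rSO2 %g Hz\n",
    nrow(x$schedule), x$config$n_trials_per_hemisphere,
    max(x$schedule$off_end), x$config$eeg_rate, ncol(x$eeg) - 1,
    x$config$nirs_rate))
  invisible(x)
}

#' Stimulation-and-recording order of the reference session
#'
#' The hemisphere sequence (contralesional CH / lesional LH) of the 30-trial
#' single-subject recording session that the package's defaults emulate;
#' used in examples and protocol-arithmetic checks.
#'
#' @format Character vector of length 30 with values `"CH"` and `"LH"`.
#' @export
reference_stimulation_order <- c(
  "CH", "CH", "CH", "LH", "LH", "CH", "LH", "LH", "LH", "CH",
  "CH", "CH", "CH", "LH", "CH", "LH", "LH", "LH", "LH", "CH",
  "LH", "CH", "CH", "CH", "LH", "CH", "CH", "LH", "LH", "LH"
)
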