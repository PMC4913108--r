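#' Screen IMFs by peak power frequency
#'
#' Retains IMFs whose Hann-periodogram peak frequency does not exceed
#' `cutoff` (default 50 Hz), preserving original 1-based indices. At a
#' 10 Hz sampling rate every IMF survives the default screen (Nyquist 5 Hz).
#'
#' @param imfset An [emd()] result.
#' @param cutoff Cutoff in Hz (default 50).
#' @return A tibble with columns `imf_index` (original index), `peak_hz`,
#'   and list-column `samples`; zero rows when nothing is retained.
#' @export
select_imfs <- function(imfset, cutoff = 50) {
  stopifnot(inherits(imfset, "imf_set"))
  if (length(imfset$imfs) == 0) {
    return(tibble::tibble(imf_index = integer(0), peak_hz = numeric(0),
                          samples = list()))
  }
  peaks <- purrr::map_dbl(imfset$imfs, peak_power_frequency,
                          sampling_rate = imfset$sampling_rate)
  keep <- which(peaks <= cutoff)
  tibble::tibble(imf_index = keep, peak_hz = peaks[keep],
                 samples = imfset$imfs[keep])
}

#' Log10 mean-power series of an IMF at a lower rate
#'
#' Partitions the IMF into consecutive non-overlapping windows of
#' `sampling_rate / target_rate` samples (50 for 500 to 10 Hz) and returns
#' `log10(max(mean(window^2), floor))` per window, where the floor is
#' `1e-12` times the epoch mean power so the log stays finite under exact
#' zeros.
#'
#' @param imf Numeric vector.
#' @param sampling_rate Rate of `imf` in Hz; must be an integer multiple of
#'   `target_rate`.
#' @param target_rate Output rate in Hz (default 10).
#' @return Numeric vector of length `length(imf) * target_rate /
#'   sampling_rate`, sampled at `target_rate`.
#' @export
log_mean_power <- function(imf, sampling_rate, target_rate = 10) {
  ratio <- sampling_rate / target_rate
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort("sampling_rate must be an integer multiple of target_rate.",
          class = "nvc_invalid_argument")
  }
  ratio <- as.integer(round(ratio))
  nw <- length(imf) %/% ratio
  mp <- colMeans(matrix(imf[seq_len(nw * ratio)]^2, nrow = ratio))
  floor_p <- max(1e-12 * mean(imf^2), .Machine$double.xmin)
  log10(pmax(mp, floor_p))
}

#' Normalized cross-correlation over a symmetric lag grid
#'
#' With `x` the NIRS IMF and `y` the EEG mean-power series,
#' `r(k) = sum_t (x[t+k] - xbar) (y[t] - ybar) / (N * s_x * s_y)`, the sums
#' running over the valid overlap and the divisor fixed at `N` (biased
#' estimator, as the classic econometric cross-correlation routine). A
#' NEGATIVE peak lag means `x` (NIRS) leads `y` (EEG power).
#'
#' @param x,y Numeric vectors of equal length `N > max_lag * rate`.
#' @param max_lag Maximum lag in seconds (default 20).
#' @param rate Sampling rate in Hz (default 10).
#' @return A tibble of class `nvc_ccg` with columns `lag_s`, `r`;
#'   attributes `n` (sample count) and `rate`. Zero-variance input yields an
#'   all-zero correlogram with attribute `zero_variance = TRUE`.
#' @export
normalized_crosscorr <- function(x, y, max_lag = 20, rate = 10) {
  n <- length(x)
  if (length(y) != n) {
    abort("`x` and `y` must have equal length.", class = "nvc_invalid_argument")
  }
  lag_n <- as.integer(round(max_lag * rate))
  if (n <= lag_n) {
    abort("series too short for the requested lag window.",
          class = "nvc_invalid_argument")
  }
  zero_var <- var(x) == 0 || var(y) == 0
  r <- cpp_crosscorr(as.numeric(x), as.numeric(y), lag_n)
  out <- tibble::tibble(lag_s = (-lag_n:lag_n) / rate, r = r)
  class(out) <- c("nvc_ccg", class(out))
  attr(out, "n") <- n
  attr(out, "rate") <- rate
  if (zero_var) attr(out, "zero_variance") <- TRUE
  out
}

#' Zero cross-correlation values inside the estimation-error band
#'
#' Values within `n_std` standard deviations of the white-noise estimation
#' error are set to zero, treating the signals as uncorrelated there. The
#' default bound is the lag-independent `n_std / sqrt(N)`; a lag-dependent
#' `n_std / sqrt(N - |k|)` variant is available.
#'
#' @param ccg A correlogram from [normalized_crosscorr()].
#' @param n_std Number of standard deviations (default 3).
#' @param lag_dependent Use the overlap-corrected bound (default FALSE).
#' @return The correlogram with columns `bound` and `r_thresholded` added
#'   (or recomputed); thresholding is idempotent and only ever zeroes
#'   values.
#' @export
apply_significance_threshold <- function(ccg, n_std = 3,
                                         lag_dependent = FALSE) {
  n <- attr(ccg, "n")
  rate <- attr(ccg, "rate")
  stopifnot(!is.null(n), !is.null(rate))
  if (lag_dependent) {
    ccg$bound <- n_std / sqrt(n - abs(ccg$lag_s) * rate)
  } else {
    ccg$bound <- n_std / sqrt(n)
  }
  ccg$r_thresholded <- ifelse(abs(ccg$r) < ccg$bound, 0, ccg$r)
  ccg
}

#' Sidak-corrected bound for the maximum correlation over a lag grid
#'
#' Familywise bound used when counting a trial as coupling-positive from the
#' maximum of its correlogram: under the white-noise null each lag bin is
#' approximately Normal(0, 1/N), so the two-sided Sidak bound for the max
#' over `n_lags` bins at level `alpha` is `qnorm(1 - alpha2) / sqrt(N)` with
#' `alpha2 = (1 - (1 - alpha)^(1/n_lags)) / 2`.
#'
#' @param n Sample count of the correlated series.
#' @param n_lags Number of lag bins scanned.
#' @param alpha Familywise level (default 0.05).
#' @return Positive scalar bound on |r|.
#' @export
max_corr_bound <- function(n, n_lags, alpha = 0.05) {
  alpha2 <- (1 - (1 - alpha)^(1 / n_lags)) / 2
  qnorm(1 - alpha2) / sqrt(n)
}

#' Cross-correlation analysis of one trial
#'
#' The per-trial core of the pipeline: decompose the EEG and NIRS OFF
#' epochs by EMD, discard EEG IMFs with peak power above `cutoff_hz`,
#' compute the log10 mean-power series of each retained EEG IMF at the NIRS
#' rate, pair them with the NIRS IMFs, and return one thresholded
#' correlogram per pair over the `±max_lag_s` window.
#'
#' Pairing `"rank"` matches the i-th retained EEG IMF with the i-th NIRS
#' IMF up to the smaller count; `"all"` crosses every retained EEG IMF with
#' every NIRS IMF; `"band"` first assigns each IMF to a physiological
#' frequency band by its periodogram peak (NIRS: low < 0.15 Hz,
#' respiratory, cardiac; EEG: slow/delta/theta/alpha/beta/gamma), keeps the
#' highest-variance IMF per band and crosses the bands. Band pairing is the
#' recommended mode for cross-trial aggregation because EMD mode indices
#' are not stable across epochs while band identity is.
#'
#' @param eeg_epoch,nirs_epoch Single rows of an epoch tibble (same trial).
#' @param cutoff_hz IMF screen cutoff (default 50).
#' @param max_lag_s Lag window half-width in seconds (default 20).
#' @param n_std Zeroing rule width (default 3).
#' @param pairing `"rank"`, `"all"` or `"band"`.
#' @param target_rate Power-series rate, Hz (default 10).
#' @param lag_dependent_bound Passed to [apply_significance_threshold()].
#' @param sd_thresh,s_number,max_iter,max_imfs Sifting controls, see
#'   [emd()].
#' @return A tidy tibble with one row per (pair, lag): `trial`,
#'   `hemisphere`, `pair_index`, `imf_nirs`, `imf_eeg`, `lag_s`, `r`,
#'   `r_thresholded`, `bound`, `n`. Zero rows (with attribute `reason`)
#'   when an epoch is rejected or carries an extraction error.
#' @export
analyze_trial <- function(eeg_epoch, nirs_epoch, cutoff_hz = 50,
                          max_lag_s = 20, n_std = 3,
                          pairing = c("rank", "all", "band"),
                          target_rate = 10,
                          lag_dependent_bound = FALSE, sd_thresh = 0.2,
                          s_number = 3, max_iter = 200, max_imfs = 12) {
  pairing <- match.arg(pairing)
  empty <- function(reason) {
    out <- tibble::tibble(trial = integer(0), hemisphere = character(0),
                          pair_index = integer(0), imf_nirs = integer(0),
                          imf_eeg = integer(0), lag_s = numeric(0),
                          r = numeric(0), r_thresholded = numeric(0),
                          bound = numeric(0), n = integer(0),
                          n_eff = numeric(0), pair_label = character(0))
    attr(out, "reason") <- reason
    out
  }
  if (isTRUE(eeg_epoch$rejected) || isTRUE(nirs_epoch$rejected)) {
    return(empty("epoch rejected by artifact screen"))
  }
  if (!is.na(eeg_epoch$error) || !is.na(nirs_epoch$error)) {
    return(empty("epoch extraction error"))
  }
  stopifnot(eeg_epoch$trial == nirs_epoch$trial)

  dec_e <- emd(eeg_epoch$samples[[1]], eeg_epoch$sampling_rate,
               max_imfs = max_imfs, sd_thresh = sd_thresh,
               s_number = s_number, max_iter = max_iter)
  dec_n <- emd(nirs_epoch$samples[[1]], nirs_epoch$sampling_rate,
               max_imfs = max_imfs, sd_thresh = sd_thresh,
               s_number = s_number, max_iter = max_iter)
  kept_e <- select_imfs(dec_e, cutoff = cutoff_hz)
  kept_n <- select_imfs(dec_n, cutoff = cutoff_hz)
  if (nrow(kept_e) == 0 || nrow(kept_n) == 0) {
    return(empty("no IMFs retained by the peak-power screen"))
  }

  if (pairing == "band") {
    reps_n <- band_representatives(kept_n, dec_n$residual, nirs_band_of)
    reps_e <- band_representatives(kept_e, dec_e$residual, eeg_band_of)
    series_n <- reps_n$samples
    series_e <- reps_e$samples
    g <- tidyr::expand_grid(jn = seq_len(nrow(reps_n)),
                            je = seq_len(nrow(reps_e)))
    pairs <- tibble::tibble(
      pair_index = (as.integer(reps_n$band[g$jn]) - 1L) * 6L +
        as.integer(reps_e$band[g$je]),
      i_n = g$jn, i_e = g$je,
      pair_label = paste0(reps_n$band[g$jn], "x", reps_e$band[g$je]))
    idx_n <- reps_n$imf_index
    idx_e <- reps_e$imf_index
  } else {
    series_n <- kept_n$samples
    series_e <- kept_e$samples
    idx_n <- kept_n$imf_index
    idx_e <- kept_e$imf_index
    pairs <- if (pairing == "rank") {
      k <- seq_len(min(nrow(kept_e), nrow(kept_n)))
      tibble::tibble(pair_index = k, i_n = k, i_e = k,
                     pair_label = paste0("rank", k))
    } else {
      g <- tidyr::expand_grid(i_n = seq_len(nrow(kept_n)),
                              i_e = seq_len(nrow(kept_e)))
      tibble::tibble(pair_index = seq_len(nrow(g)), i_n = g$i_n, i_e = g$i_e,
                     pair_label = paste0("n", kept_n$imf_index[g$i_n],
                                         "xe", kept_e$imf_index[g$i_e]))
    }
  }
  power <- purrr::map(series_e, log_mean_power,
                      sampling_rate = eeg_epoch$sampling_rate,
                      target_rate = target_rate)

  # per-series autocorrelations for the Pyper-Peterman effective sample size
  acf_of <- function(v) autocorr_head(v, max(2L, length(v) %/% 5L))
  rho_n <- purrr::map(series_n, acf_of)
  rho_e <- purrr::map(power, acf_of)

  purrr::pmap_dfr(pairs, function(pair_index, i_n, i_e, pair_label) {
    ccg <- normalized_crosscorr(series_n[[i_n]], power[[i_e]],
                                max_lag = max_lag_s, rate = target_rate)
    ccg <- apply_significance_threshold(ccg, n_std = n_std,
                                        lag_dependent = lag_dependent_bound)
    tibble::tibble(trial = eeg_epoch$trial, hemisphere = eeg_epoch$hemisphere,
                   pair_index = pair_index,
                   imf_nirs = idx_n[i_n],
                   imf_eeg = idx_e[i_e],
                   lag_s = ccg$lag_s, r = ccg$r,
                   r_thresholded = ccg$r_thresholded, bound = ccg$bound,
                   n = attr(ccg, "n"),
                   n_eff = effective_n(attr(ccg, "n"),
                                       rho_n[[i_n]], rho_e[[i_e]]),
                   pair_label = pair_label)
  })
}

# Physiological frequency bands used to give IMF pairs an identity that is
# stable across trials (EMD mode indices are not: the same oscillation can
# surface at different ranks in different epochs).
nirs_band_of <- function(f) {
  cut(f, breaks = c(-Inf, 0.15, 0.5, Inf),
      labels = c("low", "resp", "cardiac"))
}

eeg_band_of <- function(f) {
  cut(f, breaks = c(-Inf, 1, 4, 7, 13, 30, Inf),
      labels = c("slow", "delta", "theta", "alpha", "beta", "gamma"))
}

# Band reconstruction: same-band IMFs are summed into one representative
# series per band (EMD splits a single oscillation across neighbouring
# modes often enough that the partial reconstruction is the faithful
# band estimate); the reported imf index is the largest-variance member.
# The linearly-detrended residual joins the lowest band present, because
# slow components with ~1 cycle per epoch partially leak into the
# monotone residual.
band_representatives <- function(kept, residual, classify) {
  bands <- classify(kept$peak_hz)
  v <- purrr::map_dbl(kept$samples, var)
  out <- tibble::tibble(band = bands, i = seq_len(nrow(kept)), v = v) |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(
      samples = list(Reduce(`+`, kept$samples[.data$i])),
      imf_index = kept$imf_index[.data$i[which.max(.data$v)]],
      peak_hz = kept$peak_hz[.data$i[which.max(.data$v)]],
      .groups = "drop")
  lowest <- which.min(as.integer(out$band))
  out$samples[[lowest]] <- out$samples[[lowest]] + detrend_linear(residual)
  out
}

detrend_linear <- function(x) {
  t <- seq_along(x)
  x - (mean(x) + cov(t, x) / var(t) * (t - mean(t)))
}

# Sample autocorrelation rho(1..k_max) (biased, divisor N), demeaned.
autocorr_head <- function(x, k_max) {
  n <- length(x)
  x <- x - mean(x)
  denom <- sum(x^2)
  if (denom == 0) return(rep(0, k_max))
  vapply(seq_len(k_max), function(k) {
    sum(x[1:(n - k)] * x[(k + 1):n]) / denom
  }, numeric(1))
}

# Pyper-Peterman effective sample size for the correlation of two
# autocorrelated series: 1/N_eff = 1/N + (2/N) sum_k w_k rho_x(k) rho_y(k),
# w_k = (N - k)/N; clamped to [2, N]. Smooth-by-smooth pairs get a small
# N_eff and hence a wide qualification bound in the report layer.
effective_n <- function(n, rho_x, rho_y) {
  k <- seq_len(min(length(rho_x), length(rho_y)))
  s <- sum((n - k) / n * rho_x[k] * rho_y[k])
  n_eff <- 1 / (1 / n + (2 / n) * max(0, s))
  min(max(n_eff, 2), n)
}
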