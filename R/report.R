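#' Analyze every trial of a session
#'
#' Runs the full per-trial chain on a recorded or synthetic session: spatial
#' surround referencing per hemisphere, trimmed OFF-epoch extraction for the
#' referenced EEG and the hemisphere's rSO2, the automated artifact screen
#' on the EEG epochs, and [analyze_trial()] per non-rejected trial.
#'
#' @param session An `nvc_session` (or any list with `eeg`, `nirs`,
#'   `schedule` in the same layout).
#' @param config A [run_config()].
#' @return A tibble of correlogram rows (see [analyze_trial()]) with an
#'   additional `hemi_trial` column (1-based chronological index within the
#'   hemisphere); attribute `rejections` holds a tibble of rejected or
#'   failed trials with reasons.
#' @export
analyze_session <- function(session, config = run_config()) {
  stopifnot(inherits(config, "nvc_run_config"))
  sched <- session$schedule
  eeg_rate <- infer_rate(session$eeg$time_s)
  nirs_rate <- infer_rate(session$nirs$time_s)

  out <- list()
  rejections <- list()
  for (h in names(config$montages)) {
    m <- config$montages[[h]]
    ref <- surround_reference(session$eeg, m$center, m$surround)
    sched_h <- sched[sched$hemisphere == h, ]
    if (nrow(sched_h) == 0) next
    ep_e <- extract_off_epochs(ref, sched_h, config$lead_trim,
                               config$trail_trim, sampling_rate = eeg_rate)
    nirs_h <- session$nirs[c("time_s", m$nirs)]
    ep_n <- extract_off_epochs(nirs_h, sched_h, config$lead_trim,
                               config$trail_trim, sampling_rate = nirs_rate)
    ep_e <- reject_artifacts(ep_e, config$amp_threshold, config$var_ratio)

    for (i in seq_len(nrow(ep_e))) {
      res <- analyze_trial(ep_e[i, ], ep_n[i, ],
                           cutoff_hz = config$cutoff_hz,
                           max_lag_s = config$max_lag_s,
                           n_std = config$n_std, pairing = config$pairing,
                           target_rate = config$target_rate,
                           lag_dependent_bound = config$lag_dependent_bound,
                           sd_thresh = config$sd_thresh,
                           s_number = config$s_number,
                           max_iter = config$max_iter,
                           max_imfs = config$max_imfs)
      if (nrow(res) == 0) {
        rejections[[length(rejections) + 1]] <- tibble::tibble(
          trial = ep_e$trial[i], hemisphere = h, hemi_trial = i,
          reason = attr(res, "reason") %||% "empty result")
      } else {
        res$hemi_trial <- i
        out[[length(out) + 1]] <- res
      }
    }
  }
  ccgs <- dplyr::bind_rows(out)
  attr(ccgs, "rejections") <- dplyr::bind_rows(rejections)
  ccgs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Most common significantly-coupled IMF pair
#'
#' Selects the pair index with the greatest number of trials containing at
#' least one surviving (nonzero thresholded) cross-correlation value; ties
#' break toward the lower index. With `min_r` set, a trial only counts when
#' the maximum |r_thresholded| (within `lag_band`, if given) reaches
#' `min_r` — the report workflow passes the Sidak max-over-lags bound
#' ([max_corr_bound()]) to keep the count from saturating under the null.
#'
#' @param ccgs Correlogram tibble with columns `pair_index`, `trial`,
#'   `lag_s`, `r_thresholded`.
#' @param min_r Minimum peak |r| for a trial to count (NULL = any nonzero).
#' @param lag_band Optional `c(lo, hi)` seconds restricting the scan.
#' @return Integer pair index, or `NA_integer_` when no trial of any pair
#'   has a surviving value; attribute `counts` holds the per-pair tally.
#' @export
dominant_imf <- function(ccgs, min_r = NULL, lag_band = NULL) {
  if (nrow(ccgs) == 0) return(NA_integer_)
  df <- ccgs
  if (!is.null(lag_band)) {
    df <- dplyr::filter(df, .data$lag_s >= lag_band[1],
                        .data$lag_s <= lag_band[2])
  }
  thr <- if (is.null(min_r)) .Machine$double.xmin else min_r
  adaptive <- !is.null(min_r) && "n_eff" %in% names(df)
  n_lags <- dplyr::n_distinct(df$lag_s)
  counts <- df |>
    dplyr::group_by(.data$pair_index, .data$trial) |>
    dplyr::summarise(
      hit = max(abs(.data$r_thresholded)) >=
        if (adaptive) max(thr, max_corr_bound(.data$n_eff[1], n_lags)) else thr,
      .groups = "drop") |>
    dplyr::group_by(.data$pair_index) |>
    dplyr::summarise(n_trials = sum(.data$hit), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_trials), .data$pair_index)
  if (nrow(counts) == 0 || counts$n_trials[1] == 0) {
    return(structure(NA_integer_, counts = counts))
  }
  structure(as.integer(counts$pair_index[1]), counts = counts)
}

#' Detect the coupling onset trial from a trial-by-lag map
#'
#' Returns the smallest trial `t0` such that trial `t0` itself has a peak
#' thresholded correlation within `lag_band` of at least `min_r` AND at
#' least `persistence` of the trials from `t0` onward do too; `NA` when no
#' trial qualifies. Rows must be in chronological trial order.
#'
#' @param mat Tibble with columns `trial`, `lag_s`, `r_thresholded` for one
#'   hemisphere and one pair.
#' @param min_r Minimum peak correlation (the report default is the Sidak
#'   bound from [max_corr_bound()]).
#' @param lag_band `c(lo, hi)` seconds; default `c(-20, 0)`, the NIRS-leads
#'   side.
#' @param persistence Required fraction of qualifying trials from the onset
#'   onward (default 0.8).
#' @return Trial index (value of the `trial` column) or `NA_integer_`.
#' @export
detect_coupling_onset <- function(mat, min_r, lag_band = c(-20, 0),
                                  persistence = 0.8) {
  peaks <- mat |>
    dplyr::filter(.data$lag_s >= lag_band[1], .data$lag_s <= lag_band[2]) |>
    dplyr::group_by(.data$trial) |>
    dplyr::summarise(peak = max(.data$r_thresholded), .groups = "drop") |>
    dplyr::arrange(.data$trial)
  q <- peaks$peak >= min_r
  n <- length(q)
  for (i in seq_len(n)) {
    if (q[i] && mean(q[i:n]) >= persistence) {
      return(as.integer(peaks$trial[i]))
    }
  }
  NA_integer_
}

#' Cumulative stimulation time through a trial
#'
#' ON-plateau seconds accumulated through the end of the given
#' hemisphere-local trial; ramps are excluded, so trial 11 of a 50 s ON
#' protocol gives 550 s.
#'
#' @param trial_index 1-based trial index (>= 1).
#' @param on_duration ON plateau per trial, seconds (default 50).
#' @return Seconds of cumulative stimulation.
#' @export
cumulative_stim_time <- function(trial_index, on_duration = 50) {
  if (any(trial_index < 1)) {
    abort("`trial_index` must be >= 1.", class = "nvc_invalid_argument")
  }
  trial_index * on_duration
}

#' Count trials of one hemisphere in a stimulation order
#'
#' @param order Character vector of hemisphere labels.
#' @param label Label to count.
#' @return Number of entries equal to `label`; an unknown label in a
#'   non-empty order returns 0 with a warning.
#' @export
count_hemisphere_trials <- function(order, label) {
  n <- sum(order == label)
  if (length(order) > 0 && n == 0) {
    warn(sprintf("label '%s' does not occur in the order", label))
  }
  n
}

#' Aggregate per-trial correlograms into a coupling report
#'
#' Per hemisphere this (1) selects the dominant IMF pair by pooled evidence
#' — each trial's correlation at each lag is converted to an approximate
#' z-score `r * sqrt(n_eff)` using the trial's effective sample size and
#' combined across trials Stouffer-style; the pair whose pooled profile
#' peaks highest (positively, inside the lag band) wins, provided it is
#' present in at least half the trials and its score reaches
#' `config$stouffer_min` — then (2) builds that pair's trial-by-lag map and
#' per-trial peaks, (3) detects the coupling onset (first trial that itself
#' qualifies and from which at least `persistence` of trials qualify, a
#' trial qualifying when its peak survives the zeroing rule and reaches
#' `config$min_r`), and (4) recovers the coupling lag as the peak of the
#' pooled profile over post-onset trials, plus the cumulative stimulation
#' time at onset.
#'
#' @param ccgs Output of [analyze_session()].
#' @param config The [run_config()] used (supplies the lag band, onset rule
#'   and selection threshold; `min_r = NULL` counts any surviving value).
#' @param on_duration ON plateau seconds for the stimulation arithmetic
#'   (default 50).
#' @param trial_order Optional character vector with the session's
#'   hemisphere order, echoed into the report.
#' @return An object of class `nvc_report`.
#' @export
coupling_report <- function(ccgs, config = run_config(), on_duration = 50,
                            trial_order = NULL) {
  lag_band <- config$lag_band
  hemis <- unique(ccgs$hemisphere)
  res <- list()
  for (h in hemis) {
    d <- dplyr::filter(ccgs, .data$hemisphere == h)
    t_h <- dplyr::n_distinct(d$hemi_trial)
    band_d <- d |>
      dplyr::filter(.data$lag_s >= lag_band[1], .data$lag_s <= lag_band[2])
    scores <- band_d |>
      dplyr::group_by(.data$pair_index) |>
      dplyr::group_modify(~ scan_score(.x)) |>
      dplyr::ungroup() |>
      dplyr::filter(.data$t_p >= ceiling(t_h / 2)) |>
      dplyr::arrange(dplyr::desc(.data$score), .data$pair_index)

    if (nrow(scores) == 0 || scores$score[1] < config$stouffer_min) {
      res[[h]] <- list(dominant_pair = NA_integer_, pair_label = NA_character_,
                       pair_scores = scores,
                       matrix = tibble::tibble(), trial_peaks = tibble::tibble(),
                       onset_trial = NA_integer_,
                       cumulative_stim_s = NA_real_,
                       recovered_lag_s = NA_real_)
      next
    }
    dom <- scores$pair_index[1]
    dd <- dplyr::filter(d, .data$pair_index == dom)
    min_r <- config$min_r %||% 0
    mat <- dd |>
      dplyr::select("hemi_trial", "trial", "lag_s", "r_thresholded")
    attr(mat, "rejections") <- NULL
    peaks <- dd |>
      dplyr::filter(.data$lag_s >= lag_band[1], .data$lag_s <= lag_band[2]) |>
      dplyr::group_by(.data$hemi_trial) |>
      dplyr::summarise(
        peak_r = max(.data$r_thresholded),
        peak_lag_s = .data$lag_s[which.max(.data$r_thresholded)],
        .groups = "drop") |>
      dplyr::arrange(.data$hemi_trial) |>
      dplyr::mutate(qualifies = .data$peak_r > min_r)
    q <- peaks$qualifies
    onset <- NA_integer_
    for (i in seq_along(q)) {
      if (q[i] && mean(q[i:length(q)]) >= config$persistence) {
        onset <- as.integer(peaks$hemi_trial[i])
        break
      }
    }
    recovered <- NA_real_
    if (!is.na(onset)) {
      prof <- dd |>
        dplyr::filter(.data$hemi_trial >= onset,
                      .data$lag_s >= lag_band[1],
                      .data$lag_s <= lag_band[2]) |>
        dplyr::group_by(.data$lag_s) |>
        dplyr::summarise(z = sum(.data$r * sqrt(.data$n_eff)),
                         .groups = "drop")
      recovered <- prof$lag_s[which.max(prof$z)]
    }
    res[[h]] <- list(
      dominant_pair = dom,
      pair_label = dd$pair_label[1],
      pair_scores = scores,
      imf_nirs = modal_int(dd$imf_nirs), imf_eeg = modal_int(dd$imf_eeg),
      matrix = mat, trial_peaks = peaks,
      onset_trial = onset,
      cumulative_stim_s = if (is.na(onset)) NA_real_ else
        cumulative_stim_time(onset, on_duration),
      recovered_lag_s = recovered,
      min_r = min_r
    )
  }
  structure(list(hemispheres = res,
                 rejections = attr(ccgs, "rejections") %||% tibble::tibble(),
                 trial_order = trial_order, lag_band = lag_band,
                 persistence = config$persistence),
            class = "nvc_report")
}

modal_int <- function(x) {
  tb <- sort(table(x), decreasing = TRUE)
  as.integer(names(tb)[1])
}

# Onset-aware pooled evidence for one pair: per-trial correlations become
# approximate z-scores r * sqrt(n_eff); for every lag and every candidate
# onset t0 the suffix sum over trials >= t0, normalized by sqrt(suffix
# length), is an approximately standard normal scan statistic under the
# null. The maximum over lags and onsets is the pair's score — matched to
# a block design whose coupling switches on partway through the session.
scan_score <- function(df) {
  zt <- df |>
    dplyr::group_by(.data$hemi_trial, .data$lag_s) |>
    dplyr::summarise(
      z = atanh(pmin(pmax(.data$r[1], -0.9999), 0.9999)) *
        sqrt(pmax(.data$n_eff[1] - 3, 1)),
      .groups = "drop")
  m <- zt |>
    tidyr::pivot_wider(names_from = "hemi_trial", values_from = "z") |>
    dplyr::arrange(.data$lag_s)
  lags <- m$lag_s
  zmat <- as.matrix(m[-1])  # lags x trials, trial columns in order
  zmat <- zmat[, order(as.integer(colnames(zmat))), drop = FALSE]
  zmat[is.na(zmat)] <- 0  # trials where this pair is absent contribute 0
  t_p <- ncol(zmat)
  suffix <- t(apply(zmat, 1, function(v) rev(cumsum(rev(v)))))
  if (t_p == 1) suffix <- matrix(suffix, ncol = 1)
  norm <- sqrt(rev(seq_len(t_p)))
  s <- sweep(suffix, 2, norm, "/")
  best <- arrayInd(which.max(s), dim(s))
  tibble::tibble(score = s[best], lag_at_peak = lags[best[1]],
                 scan_onset = as.integer(colnames(zmat)[best[2]]),
                 t_p = t_p)
}

#' @export
print.nvc_report <- function(x, ...) {
  cat("<nvc_report>\n")
  for (h in names(x$hemispheres)) {
    r <- x$hemispheres[[h]]
    cat(sprintf(
      "  %s: dominant pair %s (NIRS imf %s / EEG imf %s), onset trial %s, cum. stim %s s, lag %s s\n",
      h, r$dominant_pair, r$imf_nirs %||% NA, r$imf_eeg %||% NA,
      r$onset_trial, r$cumulative_stim_s, r$recovered_lag_s))
  }
  invisible(x)
}

#' @importFrom generics glance
#' @export
generics::glance

#' One-row-per-hemisphere summary of a coupling report
#'
#' @param x An `nvc_report`.
#' @param ... Unused.
#' @return Tibble with `hemisphere`, `dominant_pair`, `imf_nirs`,
#'   `imf_eeg`, `onset_trial`, `cumulative_stim_s`, `recovered_lag_s`,
#'   `n_rejected`.
#' @export
glance.nvc_report <- function(x, ...) {
  purrr::imap_dfr(x$hemispheres, function(r, h) {
    tibble::tibble(
      hemisphere = h,
      dominant_pair = r$dominant_pair,
      pair_label = r$pair_label %||% NA_character_,
      imf_nirs = r$imf_nirs %||% NA_integer_,
      imf_eeg = r$imf_eeg %||% NA_integer_,
      onset_trial = r$onset_trial,
      cumulative_stim_s = r$cumulative_stim_s,
      recovered_lag_s = r$recovered_lag_s,
      n_rejected = if (nrow(x$rejections) == 0) 0L else
        sum(x$rejections$hemisphere == h)
    )
  })
}

#' Long tibble of the dominant-pair trial-by-lag maps
#'
#' @param x An `nvc_report`.
#' @param ... Unused.
#' @return Tibble `hemisphere`, `hemi_trial`, `trial`, `lag_s`,
#'   `r_thresholded`.
#' @export
tidy.nvc_report <- function(x, ...) {
  purrr::imap_dfr(x$hemispheres, function(r, h) {
    if (nrow(r$matrix) == 0) return(tibble::tibble())
    dplyr::mutate(r$matrix, hemisphere = h, .before = 1)
  })
}

#' Trial-by-lag coupling heatmap
#'
#' Mirrors the classic block-design correlogram figure: hemisphere-local
#' trials on the vertical axis, lag on the horizontal, thresholded
#' correlation on a diverging colour scale.
#'
#' @param object An `nvc_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nvc_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_s, y = .data$hemi_trial,
                                   fill = .data$r_thresholded)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::scale_y_reverse(breaks = scales_int_breaks) +
    ggplot2::facet_wrap(ggplot2::vars(.data$hemisphere)) +
    ggplot2::labs(x = "lag (s)  [negative: NIRS leads EEG power]",
                  y = "trial", fill = "r")
}

scales_int_breaks <- function(x) {
  seq(ceiling(min(x)), floor(max(x)), by = max(1, round(diff(range(x)) / 8)))
}
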