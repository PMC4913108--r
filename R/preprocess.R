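#' Extract trimmed OFF-period epochs from a recorded series
#'
#' One epoch per scheduled trial, cropped to the half-open interval
#' `[off_start + lead_trim, off_end - trail_trim)` — with the protocol
#' defaults the middle 50 s of each 60 s OFF period. A sample at time `t`
#' belongs to the epoch iff `start <= t < end`, so integer-ratio rates give
#' exact sample counts (500 at 10 Hz, 25000 at 500 Hz).
#'
#' @param series A data frame with column `time_s` and one value column
#'   (e.g. the output of [surround_reference()]), plus attribute or argument
#'   `sampling_rate`.
#' @param schedule Trial schedule tibble with columns `trial`, `hemisphere`,
#'   `off_start`, `off_end`.
#' @param lead_trim,trail_trim Seconds trimmed from each end (defaults 5).
#' @param sampling_rate Sampling rate in Hz; inferred from `time_s` spacing
#'   when omitted.
#' @param value_col Name of the value column; defaults to the first
#'   non-time column.
#' @return A tibble with one row per trial: `trial`, `hemisphere`,
#'   `t_start`, `t_end`, `sampling_rate`, `rejected` (FALSE), `error`
#'   (NA or message for trials whose OFF interval falls outside the
#'   recording) and list-column `samples`.
#' @export
extract_off_epochs <- function(series, schedule, lead_trim = 5,
                               trail_trim = 5, sampling_rate = NULL,
                               value_col = NULL) {
  stopifnot(is.data.frame(series), "time_s" %in% names(series))
  if (is.null(value_col)) {
    value_col <- setdiff(names(series), "time_s")[1]
  }
  if (is.null(sampling_rate)) {
    sampling_rate <- infer_rate(series$time_s)
  }
  off_dur <- schedule$off_end - schedule$off_start
  if (any(lead_trim + trail_trim >= off_dur)) {
    abort("trims must be smaller than the OFF duration.",
          class = "nvc_invalid_argument")
  }
  t0 <- series$time_s[1]
  n <- nrow(series)
  x <- series[[value_col]]
  purrr::pmap_dfr(
    schedule[c("trial", "hemisphere", "off_start", "off_end")],
    function(trial, hemisphere, off_start, off_end) {
      a <- off_start + lead_trim
      b <- off_end - trail_trim
      i0 <- as.integer(round((a - t0) * sampling_rate)) + 1L
      i1 <- as.integer(round((b - t0) * sampling_rate))  # half-open: excludes b
      err <- NA_character_
      samples <- list(numeric(0))
      if (i0 < 1 || i1 > n) {
        err <- sprintf("trial %d: OFF interval [%g, %g) outside recording",
                       trial, a, b)
      } else {
        samples <- list(x[i0:i1])
      }
      tibble::tibble(trial = trial, hemisphere = hemisphere, t_start = a,
                     t_end = b, sampling_rate = sampling_rate,
                     rejected = FALSE, error = err, samples = samples)
    })
}

#' Surround-average spatial reference
#'
#' Subtracts the mean of the surround channels from the centre channel at
#' every sample: `out(t) = center(t) - mean(surround)(t)`. This is the
#' referencing used for F3 against F1/FC3/F5 (left) and F4 against
#' F2/FC4/F6 (right); the montage is fully configurable.
#'
#' @param channels Data frame with `time_s` and one column per channel.
#' @param center Name of the centre channel.
#' @param surround Character vector of surround channel names.
#' @return A tibble `time_s`, `value` with attribute `montage`.
#' @export
surround_reference <- function(channels, center, surround) {
  missing <- setdiff(c(center, surround), names(channels))
  if (length(missing) > 0) {
    abort(paste0("channel(s) not found: ", paste(missing, collapse = ", ")),
          class = "nvc_invalid_argument")
  }
  surround_mean <- rowMeans(as.matrix(channels[surround]))
  out <- tibble::tibble(time_s = channels$time_s,
                        value = channels[[center]] - surround_mean)
  attr(out, "montage") <- list(center = center, surround = surround)
  out
}

#' Automated artifact screen for epochs
#'
#' A reproducible stand-in for visual epoch inspection, flagging an epoch
#' when either (a) any sample deviates from the epoch median by more than
#' `amp_threshold`, or (b) the variance of any 1 s window exceeds
#' `var_ratio` times the median 1 s-window variance of the epoch. Flagged
#' epochs are excluded downstream but retained in reports as missing.
#'
#' @param epochs Epoch tibble from [extract_off_epochs()].
#' @param amp_threshold Amplitude threshold in signal units (default 100,
#'   calibrated for referenced EEG in microvolts).
#' @param var_ratio Window-variance ratio threshold (default 25).
#' @return The epoch tibble with the `rejected` flag updated.
#' @export
reject_artifacts <- function(epochs, amp_threshold = 100, var_ratio = 25) {
  flag_one <- function(s, rate) {
    if (length(s) == 0) return(FALSE)
    if (max(abs(s - median(s))) > amp_threshold) return(TRUE)
    w <- as.integer(round(rate))
    nw <- length(s) %/% w
    if (nw >= 2) {
      v <- apply(matrix(s[seq_len(nw * w)], nrow = w), 2, var)
      if (isTRUE(any(v > var_ratio * median(v)))) return(TRUE)
    }
    FALSE
  }
  epochs$rejected <- epochs$rejected |
    purrr::map2_lgl(epochs$samples, epochs$sampling_rate, flag_one)
  epochs
}
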