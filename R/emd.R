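#' Locate interior local extrema of a sampled signal
#'
#' Strict interior local maxima and minima; a plateau of equal values that
#' sits strictly above (below) both neighbouring samples contributes the
#' centre index of the plateau exactly once. The first and last samples, and
#' plateaus touching them, are never extrema.
#'
#' @param x Numeric vector, length at least 3.
#' @return A list with integer vectors `maxima` and `minima`, both strictly
#'   increasing 1-based indices into `x`.
#' @examples
#' find_extrema(sin(2 * pi * seq(0, 1, length.out = 100)))
#' @export
find_extrema <- function(x) {
  if (length(x) < 3) {
    abort("`x` must have at least 3 samples.", class = "nvc_invalid_argument")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort("`x` must be finite.", class = "nvc_invalid_argument")
  }
  cpp_find_extrema(as.numeric(x))
}

#' Mean of the cubic-spline extremal envelopes
#'
#' Pointwise mean of the upper envelope (natural cubic spline through the
#' maxima) and lower envelope (through the minima). Boundaries are handled by
#' mirroring the two extrema nearest each end about that end, which limits
#' end-swing on short epochs.
#'
#' @param x Numeric vector.
#' @return Numeric vector, same length as `x`.
#' @seealso [sift()], which iterates envelope-mean subtraction.
#' @export
envelope_mean <- function(x) {
  ext <- find_extrema(x)
  if (length(ext$maxima) < 2 || length(ext$minima) < 2) {
    abort("fewer than 2 maxima or minima: decomposition exhausted.",
          class = "nvc_decomposition_exhausted")
  }
  cpp_envelope_mean(as.numeric(x))
}

#' Extract one intrinsic mode function by sifting
#'
#' Iterates `h <- h - envelope_mean(h)` until the Cauchy criterion
#' `sum((h_prev - h)^2) / sum(h_prev^2) < sd_thresh`, or until the extrema
#' and zero-crossing counts differ by at most 1 for `s_number` consecutive
#' iterations, capped at `max_iter`. On hitting the cap the current iterate
#' is returned with a warning (not an error).
#'
#' @param x Numeric vector with at least 2 maxima and 2 minima.
#' @param sd_thresh Cauchy stopping threshold (default 0.2, the classic
#'   sifting default).
#' @param s_number Consecutive IMF-condition iterations required by the
#'   S-number fallback (default 3).
#' @param max_iter Iteration cap (default 200).
#' @return Numeric vector: the extracted intrinsic mode function, with
#'   attributes `iterations` and `converged`.
#' @export
sift <- function(x, sd_thresh = 0.2, s_number = 3, max_iter = 200) {
  ext <- find_extrema(x)
  if (length(ext$maxima) < 2 || length(ext$minima) < 2) {
    abort("fewer than 2 maxima or minima: nothing to sift.",
          class = "nvc_decomposition_exhausted")
  }
  res <- cpp_sift(as.numeric(x), sd_thresh, as.integer(s_number),
                  as.integer(max_iter))
  if (!res$converged) {
    warn(sprintf("sifting did not converge within %d iterations", max_iter))
  }
  structure(res$imf, iterations = res$iterations, converged = res$converged)
}

#' Empirical Mode Decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by repeated
#' sifting of the running residual, stopping when the residual has fewer
#' than 2 maxima or 2 minima (monotone or single-hump) or `max_imfs` is
#' reached. IMF 1 carries the highest-frequency content; frequency decreases
#' with index. The element-wise sum of all IMFs plus the residual reproduces
#' the input to floating-point accuracy.
#'
#' @param x Numeric vector, length at least 10, finite.
#' @param sampling_rate Sampling rate in Hz (metadata carried to spectral
#'   descriptors).
#' @param max_imfs Maximum number of IMFs to extract (default 12).
#' @inheritParams sift
#' @return An object of class `imf_set`: a list with `imfs` (list of numeric
#'   vectors), `residual`, `sampling_rate`, `source_length`.
#' @examples
#' t <- seq(0, 10, by = 1 / 500)
#' d <- emd(sin(2 * pi * 10 * t) + sin(2 * pi * t), sampling_rate = 500)
#' length(d$imfs)
#' @export
emd <- function(x, sampling_rate, max_imfs = 12, sd_thresh = 0.2,
                s_number = 3, max_iter = 200) {
  if (length(x) < 10) {
    abort("`x` must have at least 10 samples.", class = "nvc_invalid_argument")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    abort("`x` contains NaN/Inf.", class = "nvc_invalid_argument")
  }
  res <- cpp_decompose(as.numeric(x), as.integer(max_imfs), sd_thresh,
                       as.integer(s_number), as.integer(max_iter))
  if (res$n_unconverged > 0) {
    warn(sprintf("%d IMF(s) hit the sifting iteration cap", res$n_unconverged))
  }
  structure(
    list(imfs = res$imfs, residual = res$residual,
         sampling_rate = sampling_rate, source_length = length(x)),
    class = "imf_set"
  )
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMF(s) + residual, %d samples @ %g Hz\n",
              length(x$imfs), x$source_length, x$sampling_rate))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy an `imf_set` into a long tibble
#'
#' @param x An `imf_set`.
#' @param ... Unused.
#' @return A tibble with columns `time_s`, `component` ("imf1", ...,
#'   "residual"), `value`.
#' @export
tidy.imf_set <- function(x, ...) {
  tt <- (seq_len(x$source_length) - 1) / x$sampling_rate
  cols <- c(setNames(x$imfs, paste0("imf", seq_along(x$imfs))),
            list(residual = x$residual))
  purrr::imap_dfr(cols, function(v, nm) {
    tibble::tibble(time_s = tt, component = nm, value = v)
  })
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the components of an `imf_set`
#'
#' @param object An `imf_set`.
#' @param ... Unused.
#' @return A ggplot with one facet per component.
#' @export
autoplot.imf_set <- function(object, ...) {
  df <- tidy(object)
  df$component <- factor(df$component, levels = unique(df$component))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$component), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' Frequency of maximum periodogram power of an IMF
#'
#' Single Hann-windowed periodogram (kept at full epoch length so short
#' epochs retain fine resolution); the zero-frequency bin is excluded.
#'
#' @param imf Numeric vector, length at least 16.
#' @param sampling_rate Sampling rate in Hz.
#' @return Frequency in Hz of the periodogram maximum. An all-zero input
#'   returns 0 with attribute `flat = TRUE`.
#' @export
peak_power_frequency <- function(imf, sampling_rate) {
  n <- length(imf)
  if (n < 16) {
    abort("`imf` must have at least 16 samples.", class = "nvc_invalid_argument")
  }
  if (all(imf == 0)) {
    return(structure(0, flat = TRUE))
  }
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  p <- Mod(fft(imf * w))^2
  half <- 2:(floor(n / 2) + 1)
  k <- half[which.max(p[half])]
  (k - 1) * sampling_rate / n
}
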