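# Independent brute-force oracles used to check the compiled implementations.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Interior extrema by exhaustive scan over runs of equal values (plateau
# merged to its centre index), written independently of the C++ scan.
oracle_extrema <- function(x) {
  n <- length(x)
  runs <- rle(x)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  maxima <- integer(0)
  minima <- integer(0)
  k <- length(runs$values)
  for (r in seq_len(k)) {
    if (r == 1 || r == k) next
    v <- runs$values[r]
    centre <- (starts[r] + ends[r]) %/% 2
    if (v > runs$values[r - 1] && v > runs$values[r + 1]) {
      maxima <- c(maxima, centre)
    } else if (v < runs$values[r - 1] && v < runs$values[r + 1]) {
      minima <- c(minima, centre)
    }
  }
  list(maxima = as.integer(maxima), minima = as.integer(minima))
}

# Direct double-loop normalized cross-correlation, divisor N fixed.
oracle_crosscorr <- function(x, y, lag_n) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sx <- sqrt(sum((x - xb)^2) / n)
  sy <- sqrt(sum((y - yb)^2) / n)
  r <- numeric(2 * lag_n + 1)
  for (k in -lag_n:lag_n) {
    s <- 0
    for (t in seq_len(n)) {
      if (t + k >= 1 && t + k <= n) {
        s <- s + (x[t + k] - xb) * (y[t] - yb)
      }
    }
    r[k + lag_n + 1] <- s / (n * sx * sy)
  }
  r
}

# Hann periodogram argmax written independently of peak_power_frequency.
oracle_peak_freq <- function(x, rate) {
  n <- length(x)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
  p <- abs(fft(x * w))^2
  idx <- 2:(floor(n / 2) + 1)
  (idx[which.max(p[idx])] - 1) * rate / n
}

# Exhaustive onset scan: smallest t0 whose own trial qualifies and from
# which at least `persistence` of trials qualify.
oracle_onset <- function(qualifies, trials, persistence) {
  n <- length(qualifies)
  for (i in seq_len(n)) {
    if (qualifies[i] && mean(qualifies[i:n]) >= persistence) {
      return(trials[i])
    }
  }
  NA_integer_
}

# A small two-trial synthetic session reused across test files.
small_session <- function(seed = 1, ...) {
  generate_session(session_config(n_trials_per_hemisphere = 2,
                                  coupling_onset_trial = 1,
                                  rng_seed = seed, ...))
}
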