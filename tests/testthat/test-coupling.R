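fake_imf_set <- function(freqs, rate, duration = 10) {
  t <- seq(0, duration, by = 1 / rate)[-1]
  structure(list(imfs = lapply(freqs, function(f) sin(2 * pi * f * t)),
                 residual = numeric(length(t)), sampling_rate = rate,
                 source_length = length(t)),
            class = "imf_set")
}

test_that("the 50 Hz screen keeps low-frequency IMFs with original indices", {
  d <- fake_imf_set(c(60, 20, 4, 0.5), rate = 500)
  kept <- select_imfs(d, cutoff = 50)
  expect_equal(kept$imf_index, c(2L, 3L, 4L))

  # at 10 Hz sampling everything is below the 50 Hz cutoff
  d10 <- fake_imf_set(c(2, 0.5, 0.1), rate = 10, duration = 50)
  expect_equal(nrow(select_imfs(d10)), 3)

  # agreement with an independently computed peak-frequency filter
  set.seed(4)
  x <- rnorm(5000)
  de <- emd(x, 500)
  kept2 <- select_imfs(de, cutoff = 50)
  oracle_keep <- which(vapply(de$imfs, oracle_peak_freq, numeric(1),
                              rate = 500) <= 50)
  expect_equal(kept2$imf_index, oracle_keep)
})

test_that("log mean power has closed-form values and exact lengths", {
  expect_equal(log_mean_power(rep(3, 500), 500, 10),
               rep(log10(9), 10))

  x <- rnorm(25000)
  expect_length(log_mean_power(x, 500, 10), 500)

  # amplitude step a -> 2a steps the log-power by log10(4)
  t <- seq(0, 10, by = 1 / 500)[-1]
  step_sig <- sin(2 * pi * 10 * t) * rep(c(1, 2), each = 2500)
  lp <- log_mean_power(step_sig, 500, 10)
  expect_equal(mean(lp[51:100]) - mean(lp[1:50]), log10(4), tolerance = 1e-6)

  expect_error(log_mean_power(rnorm(100), 500, 7),
               class = "nvc_invalid_argument")

  # all-zero input stays finite via the power floor
  expect_true(all(is.finite(log_mean_power(numeric(500), 500, 10))))
})

test_that("cross-correlation matches the double-loop oracle exactly", {
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(200); y <- rnorm(200)
    cc <- normalized_crosscorr(x, y, max_lag = 2, rate = 10)
    expect_equal(cc$r, oracle_crosscorr(x, y, 20), tolerance = 1e-12)
  }
  x <- rnorm(300)
  cc <- normalized_crosscorr(x, x, max_lag = 5, rate = 10)
  expect_equal(which.max(cc$r), which(cc$lag_s == 0))
  expect_equal(max(cc$r), 1, tolerance = 1e-9)
})

test_that("a negative peak lag means the NIRS series leads", {
  set.seed(8)
  n <- rnorm(700)
  x <- n[151:650]       # NIRS
  y <- n[1:500]         # EEG power = NIRS delayed by 150 samples (15 s)
  cc <- normalized_crosscorr(x, y, max_lag = 20, rate = 10)
  expect_equal(cc$lag_s[which.max(cc$r)], -15)
})

test_that("cross-correlation symmetry and shift equivariance hold", {
  set.seed(9)
  x <- rnorm(400); y <- rnorm(400)
  rxy <- normalized_crosscorr(x, y, 10, 10)
  ryx <- normalized_crosscorr(y, x, 10, 10)
  expect_equal(rxy$r, rev(ryx$r), tolerance = 1e-12)

  # delaying x by m samples moves the peak by -m/rate
  base <- rnorm(600)
  x0 <- base[101:500]
  for (m in c(20, 55)) {
    xd <- base[(101 - m):(500 - m)]   # x delayed by m samples
    cc0 <- normalized_crosscorr(x0, x0, 15, 10)
    ccd <- normalized_crosscorr(xd, x0, 15, 10)
    p0 <- cc0$lag_s[which.max(cc0$r)]
    pd <- ccd$lag_s[which.max(ccd$r)]
    expect_equal(pd - p0, m / 10, tolerance = 0.1001)
  }

  flagged <- normalized_crosscorr(rep(1, 300), rnorm(300), 10, 10)
  expect_true(all(flagged$r == 0))
  expect_true(attr(flagged, "zero_variance"))
})

test_that("the 3-sigma zeroing rule uses the white-noise bound", {
  set.seed(10)
  cc <- normalized_crosscorr(rnorm(500), rnorm(500), 20, 10)
  th <- apply_significance_threshold(cc, n_std = 3)
  expect_equal(th$bound[1], 3 / sqrt(500), tolerance = 1e-4)
  expect_equal(round(th$bound[1], 4), 0.1342)

  # zeroes small values, never alters survivors; idempotent
  expect_true(all(th$r_thresholded[abs(th$r) < th$bound] == 0))
  keep <- abs(th$r) >= th$bound
  expect_identical(th$r_thresholded[keep], th$r[keep])
  th2 <- apply_significance_threshold(th, n_std = 3)
  expect_identical(th2$r_thresholded, th$r_thresholded)

  # all-zero correlogram is unchanged
  cc0 <- normalized_crosscorr(rep(1, 300), rnorm(300), 10, 10)
  th0 <- apply_significance_threshold(cc0)
  expect_true(all(th0$r_thresholded == 0))

  # lag-dependent variant widens with |lag|
  thl <- apply_significance_threshold(cc, n_std = 3, lag_dependent = TRUE)
  expect_equal(thl$bound[thl$lag_s == 0], 3 / sqrt(500))
  expect_gt(thl$bound[1], thl$bound[thl$lag_s == 0])
})

test_that("analyze_trial refuses rejected epochs and pairs IMFs", {
  s <- small_session(seed = 6)
  sched_l <- s$schedule[s$schedule$hemisphere == "left", ]
  ref <- surround_reference(s$eeg, "F3", c("F1", "FC3", "F5"))
  ep_e <- extract_off_epochs(ref, sched_l)
  ep_n <- extract_off_epochs(s$nirs[c("time_s", "left")], sched_l)

  rejected <- ep_e[1, ]
  rejected$rejected <- TRUE
  out <- analyze_trial(rejected, ep_n[1, ])
  expect_equal(nrow(out), 0)
  expect_match(attr(out, "reason"), "rejected")

  res <- analyze_trial(ep_e[1, ], ep_n[1, ], pairing = "rank")
  expect_gt(nrow(res), 0)
  expect_equal(unique(res$lag_s), seq(-20, 20, by = 0.1))
  expect_true(all(abs(res$r) <= 1 + 1e-12))
  # rank pairing: contiguous pair indices from 1
  expect_equal(sort(unique(res$pair_index)), seq_len(max(res$pair_index)))

  resb <- analyze_trial(ep_e[1, ], ep_n[1, ], pairing = "band")
  expect_true(any(grepl("alpha", resb$pair_label)))
  expect_true(all(resb$n_eff >= 2 & resb$n_eff <= 500))
})
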