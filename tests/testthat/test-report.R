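# Construct a correlogram tibble with given per-(pair, trial) peak values.
fake_ccgs <- function(peaks, lags = seq(-20, 0, by = 0.5)) {
  purrr::pmap_dfr(peaks, function(pair_index, trial, peak, peak_lag) {
    r <- numeric(length(lags))
    r[which.min(abs(lags - peak_lag))] <- peak
    tibble::tibble(pair_index = pair_index, trial = trial, lag_s = lags,
                   r_thresholded = r)
  })
}

test_that("dominant pair selection follows the stated counting rule", {
  peaks <- tidyr::expand_grid(pair_index = 1:4, trial = 1:6) |>
    dplyr::mutate(peak = ifelse(pair_index == 3, 0.5, 0), peak_lag = -10)
  expect_equal(as.integer(dominant_imf(fake_ccgs(peaks))), 3L)

  # tie between 2 and 3 resolves toward the lower index
  peaks2 <- tidyr::expand_grid(pair_index = 1:4, trial = 1:5) |>
    dplyr::mutate(peak = ifelse(pair_index %in% c(2, 3), 0.4, 0),
                  peak_lag = -5)
  expect_equal(as.integer(dominant_imf(fake_ccgs(peaks2))), 2L)

  # fully zeroed correlograms yield no dominant pair
  peaks0 <- tidyr::expand_grid(pair_index = 1:3, trial = 1:5) |>
    dplyr::mutate(peak = 0, peak_lag = -5)
  expect_true(is.na(dominant_imf(fake_ccgs(peaks0))))

  # invariant to trial ordering
  cc <- fake_ccgs(peaks)
  shuffled <- cc[sample(nrow(cc)), ]
  expect_equal(as.integer(dominant_imf(shuffled)),
               as.integer(dominant_imf(cc)))
})

test_that("onset detection matches its examples and the exhaustive oracle", {
  mk <- function(sig_trials, n = 15, peak = 0.5) {
    tidyr::expand_grid(pair_index = 1, trial = seq_len(n)) |>
      dplyr::mutate(peak = ifelse(trial %in% sig_trials, peak, 0),
                    peak_lag = -15) |>
      fake_ccgs()
  }
  expect_equal(detect_coupling_onset(mk(11:15), min_r = 0.1), 11L)
  expect_true(is.na(detect_coupling_onset(mk(integer(0)), min_r = 0.1)))

  # persistence = 1 with a noisy late miss pushes the onset past it
  m <- mk(c(8:11, 13:15))
  expect_equal(detect_coupling_onset(m, min_r = 0.1, persistence = 1), 13L)
  # oracle agreement over random qualification patterns
  set.seed(12)
  for (i in 1:25) {
    sig <- which(runif(15) < 0.4)
    pers <- sample(c(0.6, 0.8, 1.0), 1)
    got <- detect_coupling_onset(mk(sig), min_r = 0.1, persistence = pers)
    want <- oracle_onset(1:15 %in% sig, 1:15, pers)
    expect_identical(got, as.integer(want))
  }
})

test_that("raising min_r never yields an earlier onset", {
  set.seed(13)
  for (i in 1:10) {
    peaks <- tidyr::expand_grid(pair_index = 1, trial = 1:15) |>
      dplyr::mutate(peak = runif(15, 0, 0.8), peak_lag = -12)
    m <- fake_ccgs(peaks)
    thresholds <- c(0.1, 0.3, 0.5, 0.7)
    onsets <- vapply(thresholds, function(th) {
      o <- detect_coupling_onset(m, min_r = th)
      if (is.na(o)) 99L else o
    }, integer(1))
    expect_true(all(diff(onsets) >= 0))
  }
})

test_that("stimulation arithmetic follows the block protocol", {
  expect_equal(cumulative_stim_time(11, 50), 550)
  expect_equal(cumulative_stim_time(1, 50), 50)
  expect_equal(cumulative_stim_time(15, 50), 750)
  expect_error(cumulative_stim_time(0), class = "nvc_invalid_argument")
})

test_that("hemisphere counting handles the reference order and edge cases", {
  expect_equal(count_hemisphere_trials(reference_stimulation_order, "LH"), 15)
  expect_equal(count_hemisphere_trials(reference_stimulation_order, "CH"), 15)
  expect_equal(count_hemisphere_trials(character(0), "LH"), 0)
  expect_warning(n <- count_hemisphere_trials(c("LH", "LH"), "XX"))
  expect_equal(n, 0)
})

test_that("coupling reports round-trip through JSON exactly", {
  s <- small_session(seed = 31)
  rc <- run_config(pairing = "band", stouffer_min = 0)
  rep <- coupling_report(analyze_session(s, rc), rc)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  for (h in names(rep$hemispheres)) {
    a <- rep$hemispheres[[h]]; b <- back$hemispheres[[h]]
    expect_equal(b$matrix$r_thresholded, a$matrix$r_thresholded)
    expect_equal(b$matrix$lag_s, a$matrix$lag_s)
    expect_equal(b$onset_trial %||% NA_integer_, a$onset_trial)
    expect_equal(b$recovered_lag_s %||% NA_real_, a$recovered_lag_s)
    expect_equal(b$dominant_pair, a$dominant_pair)
  }
  expect_equal(tidy(back), tidy(rep))
})

test_that("glance and autoplot summarise a report", {
  s <- small_session(seed = 32)
  rc <- run_config(pairing = "band", stouffer_min = 0)
  rep <- coupling_report(analyze_session(s, rc), rc,
                         trial_order = s$schedule$hemisphere)
  g <- glance(rep)
  expect_setequal(g$hemisphere, c("left", "right"))
  expect_true(all(c("dominant_pair", "onset_trial", "recovered_lag_s",
                    "cumulative_stim_s") %in% names(g)))
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
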