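make_series <- function(rate, duration, value = NULL) {
  n <- duration * rate
  tibble::tibble(time_s = (seq_len(n) - 1) / rate,
                 value = value %||% rnorm(n))
}

one_trial_schedule <- tibble::tibble(
  trial = 1L, hemisphere = "left", marker_s = 0,
  on_start = 5, on_end = 55, off_start = 60, off_end = 120)

test_that("OFF epochs are trimmed to the half-open middle window", {
  set.seed(1)
  ser <- make_series(10, 120)
  ep <- extract_off_epochs(ser, one_trial_schedule)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$t_start, 65)
  expect_equal(ep$t_end, 115)
  expect_length(ep$samples[[1]], 500)  # 50 s at 10 Hz, exact
  # half-open: first sample is t = 65, last is t = 114.9
  expect_identical(ep$samples[[1]][1], ser$value[ser$time_s == 65])
  expect_identical(ep$samples[[1]][500], ser$value[1150])  # t = 114.9 s

  ep0 <- extract_off_epochs(ser, one_trial_schedule, lead_trim = 0,
                            trail_trim = 0)
  expect_length(ep0$samples[[1]], 600)

  expect_error(extract_off_epochs(ser, one_trial_schedule, 30, 30),
               class = "nvc_invalid_argument")
})

test_that("an OFF interval outside the recording yields a per-trial error", {
  ser <- make_series(10, 100)  # recording ends at 100 s < off_end
  ep <- extract_off_epochs(ser, one_trial_schedule)
  expect_false(is.na(ep$error))
  expect_length(ep$samples[[1]], 0)
})

test_that("surround referencing is exact arithmetic and linear", {
  set.seed(2)
  tt <- (0:99) / 10
  ch <- tibble::tibble(time_s = tt, c = rnorm(100), a = rnorm(100),
                       b = rnorm(100))
  out <- surround_reference(ch, "c", c("a", "b"))
  expect_equal(out$value, ch$c - (ch$a + ch$b) / 2)

  same <- tibble::tibble(time_s = tt, c = ch$c, a = ch$c, b = ch$c, d = ch$c)
  expect_true(all(surround_reference(same, "c", c("a", "b", "d"))$value == 0))

  # linearity: reference(alpha x + beta y) = alpha ref(x) + beta ref(y)
  ch2 <- tibble::tibble(time_s = tt, c = rnorm(100), a = rnorm(100),
                        b = rnorm(100))
  alpha <- 1.7; beta <- -0.4
  mix <- tibble::tibble(time_s = tt,
                        c = alpha * ch$c + beta * ch2$c,
                        a = alpha * ch$a + beta * ch2$a,
                        b = alpha * ch$b + beta * ch2$b)
  expect_equal(surround_reference(mix, "c", c("a", "b"))$value,
               alpha * surround_reference(ch, "c", c("a", "b"))$value +
                 beta * surround_reference(ch2, "c", c("a", "b"))$value,
               tolerance = 1e-12)

  expect_error(surround_reference(ch, "c", c("a", "zz")),
               class = "nvc_invalid_argument")
})

test_that("left and right montages are independent", {
  s <- small_session(seed = 5)
  # inject a large signal on left channels only
  s$eeg$F3 <- s$eeg$F3 + 50
  right <- surround_reference(s$eeg, "F4", c("F2", "FC4", "F6"))
  left <- surround_reference(s$eeg, "F3", c("F1", "FC3", "F5"))
  expect_gt(mean(left$value), 25)
  expect_lt(abs(mean(right$value)), 5)
})

test_that("the artifact screen flags amplitude and variance excursions only", {
  set.seed(3)
  clean <- tibble::tibble(trial = 1L, hemisphere = "left", t_start = 0,
                          t_end = 50, sampling_rate = 500,
                          rejected = FALSE, error = NA_character_,
                          samples = list(rnorm(25000, sd = 10)))
  expect_false(reject_artifacts(clean)$rejected)

  spike <- clean
  spike$samples[[1]][1000] <- 500
  expect_true(reject_artifacts(spike)$rejected)

  burst <- clean
  burst$samples[[1]][2000:3500] <- rnorm(1501, sd = 80)  # 3 s variance burst
  expect_true(reject_artifacts(burst, amp_threshold = Inf)$rejected)

  expect_false(reject_artifacts(spike, amp_threshold = Inf,
                                var_ratio = Inf)$rejected)
})
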