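test_that("find_extrema matches analytic cases", {
  t <- seq(0, 1, length.out = 101)  # one full sine period
  ext <- find_extrema(sin(2 * pi * t))
  expect_length(ext$maxima, 1)
  expect_length(ext$minima, 1)
  expect_equal(ext$maxima, 26, tolerance = 0)

  ramp <- find_extrema(seq(0, 5, length.out = 60))
  expect_length(ramp$maxima, 0)
  expect_length(ramp$minima, 0)

  expect_error(find_extrema(c(1, 2)), class = "nvc_invalid_argument")
  expect_error(find_extrema(c(1, NA, 2)), class = "nvc_invalid_argument")
})

test_that("find_extrema agrees with a brute-force scan, plateaus included", {
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(50)
    if (i %% 2 == 0) {
      # inject plateaus by rounding to a coarse grid
      x <- round(x, 1)
    }
    expect_identical(find_extrema(x), oracle_extrema(x))
  }
  # explicit plateau at a peak: centre index reported once
  x <- c(0, 1, 2, 2, 2, 1, 0)
  expect_identical(find_extrema(x)$maxima, 4L)
})

test_that("envelope mean vanishes for a pure tone and tracks offsets/trends", {
  t <- seq(0, 1, by = 1 / 500)  # 10 periods of 10 Hz
  s <- sin(2 * pi * 10 * t)
  interior <- 51:451
  expect_lt(max(abs(envelope_mean(s)[interior])), 0.05)

  em <- envelope_mean(s + 3.7)
  expect_lt(max(abs(em[interior] - 3.7)), 0.05)

  trend <- 2 * t
  em2 <- envelope_mean(s + trend)
  expect_lt(max(abs(em2[interior] - trend[interior])), 0.1)

  expect_error(envelope_mean(seq_len(20)),
               class = "nvc_decomposition_exhausted")
})

test_that("sifting fixes near-IMFs and separates a two-tone mixture", {
  t <- seq(0, 2, by = 1 / 500)
  s <- sin(2 * pi * 10 * t)
  out <- sift(s)
  expect_lt(max(abs(out - s)), 0.05)

  t10 <- seq(0, 10, by = 1 / 500)
  x <- sin(2 * pi * 10 * t10) + sin(2 * pi * 1 * t10)
  imf1 <- sift(x)
  interior <- seq(round(0.1 * length(x)), round(0.9 * length(x)))
  expect_gt(cor(imf1[interior], sin(2 * pi * 10 * t10)[interior]), 0.95)

  loose <- attr(sift(x, sd_thresh = 0.2), "iterations")
  tight <- attr(sift(x, sd_thresh = 0.02), "iterations")
  expect_gte(tight, loose)
})

test_that("emd terminates on monotone input and orders IMFs by frequency", {
  mono <- seq(0, 1, length.out = 100)^2
  d <- emd(mono, sampling_rate = 10)
  expect_length(d$imfs, 0)
  expect_equal(d$residual, mono)

  t <- seq(0, 10, by = 1 / 500)
  x <- sin(2 * pi * 10 * t) + sin(2 * pi * 1 * t)
  d2 <- emd(x, sampling_rate = 500)
  expect_gte(length(d2$imfs), 2)
  p1 <- peak_power_frequency(d2$imfs[[1]], 500)
  p2 <- peak_power_frequency(d2$imfs[[2]], 500)
  expect_gt(p1, p2)

  expect_error(emd(c(x[1:50], NaN), 500), class = "nvc_invalid_argument")
  expect_error(emd(rnorm(5), 10), class = "nvc_invalid_argument")
})

test_that("decomposition is complete and IMFs satisfy the mode conditions", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(300:3000, 1)
    rate <- 100
    t <- (seq_len(n) - 1) / rate
    f1 <- runif(1, 5, 20); f2 <- runif(1, 0.3, 1.5)
    x <- runif(1, 0.5, 2) * sin(2 * pi * f1 * t + runif(1, 0, 2 * pi)) +
      runif(1, 0.5, 2) * sin(2 * pi * f2 * t) + rnorm(n, sd = 0.3)
    d <- emd(x, rate)
    rec <- Reduce(`+`, d$imfs, numeric(n)) + d$residual
    expect_lt(max(abs(rec - x)), 1e-8 * diff(range(x)))
    # residual can host no further mode: fewer than 2 maxima or 2 minima
    rex <- find_extrema(d$residual)
    expect_true(length(rex$maxima) < 2 || length(rex$minima) < 2)
  }

  # IMF condition on a clean tone mixture
  t <- seq(0, 10, by = 1 / 200)
  x <- sin(2 * pi * 8 * t) + 0.8 * sin(2 * pi * 1 * t)
  d <- emd(x, 200)
  for (imf in d$imfs) {
    ext <- find_extrema(imf)
    n_ext <- length(ext$maxima) + length(ext$minima)
    zc <- sum(abs(diff(sign(imf[imf != 0]))) > 0)
    expect_lte(abs(n_ext - zc), 1)
  }
})

test_that("peak power frequency matches tones and an independent periodogram", {
  t <- seq(0, 10, by = 1 / 500)[-1]
  expect_equal(peak_power_frequency(sin(2 * pi * 10 * t), 500), 10,
               tolerance = 500 / length(t))
  expect_gt(peak_power_frequency(sin(2 * pi * 60 * t), 500), 50)

  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(512)
    expect_equal(peak_power_frequency(x, 500), oracle_peak_freq(x, 500))
  }

  z <- peak_power_frequency(numeric(64), 10)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "flat"))
  expect_error(peak_power_frequency(rnorm(8), 10),
               class = "nvc_invalid_argument")
})

test_that("imf_set tidiers expose components as long data", {
  t <- seq(0, 4, by = 1 / 100)
  d <- emd(sin(2 * pi * 5 * t) + 0.5 * t, 100)
  td <- tidy(d)
  expect_equal(nrow(td), (length(d$imfs) + 1) * d$source_length)
  expect_true("residual" %in% td$component)
  expect_s3_class(autoplot(d), "ggplot")
})
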