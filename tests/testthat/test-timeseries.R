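test_that("WMA imputation applies the 1/6, 1/3, 1/2 weights and sweeps forward", {
  expect_equal(impute_wma(c(6, 3, 2, NA))[4], 3)
  # constant series: weights sum to one, so gaps stay at the constant
  x <- rep(4.2, 20)
  x[c(5, 6, 12, 20)] <- NA
  expect_equal(as.numeric(impute_wma(x)), rep(4.2, 20))
  # linear ramp x_k = k: (1/6)(t-3) + (1/3)(t-2) + (1/2)(t-1) = t - 5/3
  ramp <- as.numeric(1:30)
  for (t in c(10, 23)) {
    r <- ramp
    r[t] <- NA
    expect_equal(impute_wma(r)[t], t - 5 / 3)
  }
  # forward sweep: imputations feed later imputations
  y <- c(1, 1, 1, NA, NA)
  out <- impute_wma(y)
  expect_equal(out[4], 1)
  expect_equal(out[5], 1)
  # observed points untouched, imputed indices recorded
  x2 <- c(2, 4, 6, NA, 8)
  out2 <- impute_wma(x2)
  expect_equal(out2[c(1, 2, 3, 5)], x2[c(1, 2, 3, 5)])
  expect_equal(attr(out2, "imputed"), 4L)
  # leading missings are back-filled from the first observation
  expect_equal(as.numeric(impute_wma(c(NA, NA, 5, 5, NA))), rep(5, 5))
  expect_error(impute_wma(rep(NA_real_, 5)), "no observed")
})

test_that("WMA imputation works on data frames with a provenance column", {
  d <- tibble::tibble(date = as.Date("2020-01-06") + 7 * 0:9,
                      value = c(1, 2, 3, NA, 5, 6, 7, 8, NA, 10))
  out <- impute_wma(d)
  expect_s3_class(out, "tbl_df")
  expect_false(anyNA(out$value))
  expect_equal(which(out$imputed), c(4L, 9L))
})

test_that("outlier correction replaces only spikes, with the WMA formula", {
  t <- seq(0, 3, by = 1 / 52)
  clean <- 5 + 2 * sin(2 * pi * t)
  expect_equal(attr(correct_outliers(clean, k = 5), "replaced"), integer(0))
  spiked <- clean
  spiked[80] <- spiked[80] + 8 # an unmistakable spike
  out <- correct_outliers(spiked, k = 4)
  expect_equal(attr(out, "replaced"), 80L)
  expect_equal(out[80], sum(c(1 / 6, 1 / 3, 1 / 2) * spiked[77:79]))
  expect_equal(out[-80], spiked[-80])
})

test_that("harmonic fit exactly recovers a noiseless annual tone", {
  t <- seq(0, 3, by = 1 / 52)
  fit <- suppressWarnings(fit_harmonic(2 * sin(2 * pi * t), t))
  expect_close(fit$a, 2, 1e-6)
  expect_close(fit$b, 0, 1e-6)
  expect_close(fit$intercept, 0, 1e-6)
  expect_close(fit$r2, 1, 1e-9)
  expect_close(fit$amplitude, 2, 1e-6)
  # amplitude identity and residual orthogonality to the regressors
  mix <- suppressWarnings(
    fit_harmonic(4 + 1.5 * sin(2 * pi * t) - 0.8 * cos(2 * pi * t), t)
  )
  expect_close(mix$amplitude^2, mix$a^2 + mix$b^2, 1e-9)
  expect_lt(abs(sum(mix$residuals * sin(2 * pi * mix$t))), 1e-6 * mix$n)
  expect_lt(abs(sum(mix$residuals * cos(2 * pi * mix$t))), 1e-6 * mix$n)
  expect_error(fit_harmonic(rep(1, 10), rep(0.5, 10)), "degenerate")
})

test_that("harmonic F-test is calibrated on white noise", {
  t <- seq(0, 3, length.out = 156)
  set.seed(42)
  rejections <- 0
  r2s <- numeric(60)
  for (i in 1:60) {
    fit <- fit_harmonic(rnorm(156), t)
    r2s[i] <- fit$r2
    rejections <- rejections + (fit$pvalue < 0.05)
  }
  expect_lte(rejections / 60, 0.10) # non-significant in >= 90% of seeds
  expect_lt(mean(r2s), 0.08)
})

test_that("harmonic fit recovers a configured one-third seasonal share", {
  # amplitude and noise chosen so the annual cycle carries 1/3 of the
  # variance, the scale reported for airborne bacterial abundance
  share <- 1 / 3
  amp <- 0.45
  noise_sd <- sqrt(amp^2 / 2 * (1 - share) / share)
  t <- seq(0, 3, by = 1 / 52.18)
  set.seed(7)
  r2 <- replicate(40, {
    y <- 4.3 + amp * cos(2 * pi * (t - 0.3)) + rnorm(length(t), sd = noise_sd)
    fit_harmonic(y, t)$r2
  })
  expect_close(mean(r2), share, 0.05)
})

test_that("phase lag is zero for identical fits and a quarter period for sine vs cosine", {
  t <- seq(0, 3, by = 1 / 52)
  fs <- suppressWarnings(fit_harmonic(sin(2 * pi * t), t))
  fc <- suppressWarnings(fit_harmonic(cos(2 * pi * t), t))
  expect_equal(phase_lag(fs, fs), 0)
  expect_close(phase_lag(fs, fc), 52.18 / 4, 0.1)
  # antisymmetry up to period wrap
  noisy <- fit_harmonic(sin(2 * pi * (t - 0.1)) + rnorm(length(t), sd = 0.2), t)
  expect_close(phase_lag(fs, noisy), -phase_lag(noisy, fs), 1e-9)
  flat <- suppressWarnings(fit_harmonic(rep(3, length(t)), t))
  expect_error(phase_lag(fs, flat), "amplitude")
})

test_that("periodogram finds the annual tone and satisfies Parseval", {
  t <- seq(1 / 52, 3, by = 1 / 52)
  x <- sin(2 * pi * t)
  pg <- periodogram(x, cadence_days = 365.25 / 52)
  expect_close(pg$dominant_period, 1, 0.05)
  # two tones: the larger annual one wins
  y <- 2 * sin(2 * pi * t) + 0.8 * sin(4 * pi * t)
  expect_close(periodogram(y, cadence_days = 365.25 / 52)$dominant_period, 1, 0.05)
  # Parseval: total power equals the biased variance
  set.seed(3)
  z <- rnorm(157)
  pg2 <- periodogram(z, cadence_days = 7)
  expect_close(pg2$total_power, mean((z - mean(z))^2), 1e-10)
  # white noise: no frequency dominates
  set.seed(11)
  conc <- replicate(40, {
    p <- periodogram(rnorm(156), cadence_days = 7)
    max(p$spectrum$power) / sum(p$spectrum$power)
  })
  expect_gte(mean(conc <= 0.2), 0.9)
})

test_that("classical decomposition is additive, centred, and exact on noiseless input", {
  t <- seq_len(156)
  x <- 10 + 0.01 * t + 2 * sin(2 * pi * t / 52)
  dec <- decompose_ts(x, period = 52)
  ok <- !is.na(dec$trend)
  expect_lt(max(abs(dec$value - (dec$trend + dec$seasonal + dec$residual))[ok]), 1e-9)
  expect_lt(abs(sum(dec$seasonal[1:52])), 1e-9)
  interior <- ok & t > 52 & t < 104
  expect_lt(max(abs(dec$residual[interior])), 1e-6)
})

test_that("monthly climatology pools calendar months across years", {
  d <- tibble::tibble(
    date = seq(as.Date("2019-01-01"), as.Date("2021-12-31"), by = "day")
  )
  d$value <- 5
  m <- aggregate_monthly(d)
  expect_equal(nrow(m), 12)
  expect_equal(m$mean, rep(5, 12))
  # winter-peaking series has its minimum in summer
  d$value <- cos(2 * pi * (lubridate::decimal_date(d$date) - 0.04))
  m2 <- aggregate_monthly(d)
  expect_true(m2$month[which.min(m2$mean)] %in% 6:8)
  # spring-peaking series peaks in spring
  d$value <- cos(2 * pi * (lubridate::decimal_date(d$date) - 0.28))
  m3 <- aggregate_monthly(d)
  expect_true(m3$month[which.max(m3$mean)] %in% 3:5)
})
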