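test_that("configs validate their invariants", {
  expect_error(world_config(lag_weeks = -1))
  expect_error(world_config(missing_frac = 1.5))
  expect_error(world_config(noise_sd = -0.1))
  expect_error(world_config(event_magnitude = 0))
  expect_error(generate_world(world_config(n_years = 1)), "2 full years")
})

test_that("generation is bit-identical under a fixed seed", {
  w1 <- small_world(seed = 11)
  w2 <- small_world(seed = 11)
  expect_identical(w1, w2)
  w3 <- small_world(seed = 12)
  expect_false(identical(w1$samples$total_copies, w3$samples$total_copies))
})

test_that("a noiseless, eventless world is an exact harmonic system", {
  w <- generate_world(
    world_config(noise_sd = 0, event_rate = 0, missing_frac = 0,
                 monsoon_offset_days = c(-2, -1)),
    seed = 1
  )
  cfg <- w$truth$config
  t <- lubridate::decimal_date(w$daily$date)
  # local series is an exact (lagged) linear map of the seasonal drivers
  f_local <- suppressWarnings(fit_harmonic(w$daily$local_pm10, t))
  expect_close(f_local$r2, 1, 1e-9)
  expect_close(f_local$amplitude,
    cfg$local_pm_sd * cfg$seasonal$la_pm_amp, 1e-6
  )
  expect_close(f_local$peak_time,
    (cfg$seasonal$rd_peak + cfg$lag_weeks / 52.18) %% 1, 1e-6
  )
  f_ab <- suppressWarnings(
    fit_harmonic(w$truth$latents$abund_log10, t)
  )
  expect_close(f_ab$r2, 1, 1e-9)
  expect_close(f_ab$amplitude,
    cfg$abundance_sd * cfg$seasonal$la_abundance_amp, 1e-6
  )
  f_des <- suppressWarnings(fit_harmonic(w$daily$desert_pm10_gobi, t))
  expect_close(f_des$peak_time, cfg$seasonal$rd_peak, 1e-6)
  # the realized phase lag equals the configured lag
  expect_close(phase_lag(f_ab, f_des), cfg$lag_weeks, 1e-6)
  # no missingness was applied
  expect_true(all(w$samples$has_sequencing))
})

test_that("realized sequencing missingness matches the configured fraction", {
  # use worlds without the monsoon block so the binomial rate is clean
  miss <- vapply(1:10, function(s) {
    w <- generate_world(
      world_config(missing_frac = 0.08, monsoon_offset_days = c(-2, -1)),
      seed = s
    )
    mean(!w$samples$has_sequencing)
  }, 0)
  n <- 315
  se <- sqrt(0.08 * 0.92 / (n * 10))
  expect_close(mean(miss), 0.08, 4 * se)
  # the monsoon block produces a contiguous gap of the configured width
  w <- generate_world(seed = 5)
  sm <- w$truth$sample_missing
  expect_gt(sum(sm$monsoon), 15)
  gap_dates <- sm$date[sm$monsoon]
  expect_lte(
    as.numeric(diff(range(gap_dates))),
    diff(w$truth$config$monsoon_offset_days)
  )
})

test_that("compositions show the spring chloroplast surge", {
  w <- generate_world(seed = 8)
  s <- w$samples[w$samples$has_sequencing, ]
  chl_frac <- s$reads_chloroplast /
    (s$reads_bacterial + s$reads_chloroplast + s$reads_mito + s$reads_other)
  mo <- lubridate::month(s$date)
  expect_gt(mean(chl_frac[mo == 4]), 0.5) # April dominated by chloroplast
  expect_lt(mean(chl_frac[mo %in% c(9:12, 1)]), 0.3)
  # bacterial fraction correspondingly collapses in April
  bf <- bacterial_fraction(
    s$reads_bacterial, s$reads_chloroplast, s$reads_mito, s$reads_other
  )
  expect_lt(mean(bf[mo == 4]), mean(bf[mo %in% 9:12]))
})

test_that("event episodes exceed the boosted level then decay to base", {
  ep <- generate_event_episode(34, 3.6, duration = 6)
  core <- ep[3:8]
  expect_true(all(core > 120))
  expect_equal(core, rep(34 * 3.6, 6))
  tail_part <- ep[9:length(ep)]
  expect_true(all(diff(tail_part) < 0))
  expect_close(tail_part[length(tail_part)], 34, 1)
  # magnitude 1 leaves the series at base
  expect_equal(generate_event_episode(34, 1, duration = 4), rep(34, 12))
  expect_error(generate_event_episode(34, 2, duration = 0))
})

test_that("realized events are recorded in truth and boost the series", {
  w <- generate_world(seed = 13)
  ev <- w$truth$events
  expect_gt(nrow(ev), 0)
  expect_true(all(lubridate::month(ev$onset) %in% 2:5))
  expect_true(all(ev$magnitude > 1))
  # desert PM10 at onset days is elevated against the month median
  d <- w$daily
  for (i in seq_len(nrow(ev))) {
    mo_med <- stats::median(
      d$desert_pm10_gobi[lubridate::month(d$date) == lubridate::month(ev$onset[i])]
    )
    expect_gt(d$desert_pm10_gobi[d$date == ev$onset[i]], mo_med)
  }
})

test_that("world tables share the configured calendar span and write to disk", {
  w <- small_world(seed = 14)
  span <- range(w$daily$date)
  expect_equal(
    as.numeric(diff(span)) + 1,
    round(w$truth$config$n_years * 365.25)
  )
  hourly_dates <- lubridate::as_date(w$hourly_pm10$datetime)
  expect_true(all(hourly_dates >= span[1] & hourly_dates <= span[2]))
  expect_equal(nrow(w$hourly_pm10), nrow(w$daily) * 24)
  dir <- tempfile()
  write_world(w, dir)
  expect_true(all(file.exists(file.path(
    dir, c("samples.csv", "daily.csv", "hourly_pm10.csv",
           "pathway_labels.csv", "truth_latents.csv", "truth.yaml")
  ))))
  truth <- yaml::read_yaml(file.path(dir, "truth.yaml"))
  expect_equal(truth$seed, 14)
  expect_equal(truth$config$lag_weeks, 4)
  expect_equal(length(truth$events), nrow(w$truth$events))
})

test_that("Monte-Carlo phase lag across worlds recovers the configured lag", {
  lags <- vapply(1:25, function(s) {
    w <- small_world(seed = s)
    ab <- abundance_series(w$samples)
    wk_ab <- aggregate_weekly(ab, value = "log10_bacterial")
    wk_ab <- fill_missing_composition(wk_ab)
    wk_ab$value <- as.numeric(correct_outliers(impute_wma(wk_ab$value), k = 3))
    wk_des <- weekly_log10(
      dplyr::mutate(w$daily,
        comp = (desert_pm10_horqin + desert_pm10_gobi + desert_pm10_taklimakan) / 3
      ),
      "comp"
    )
    phase_lag(
      fit_harmonic(wk_ab, value = "value", date = "week_start"),
      fit_harmonic(wk_des, value = "value", date = "week_start")
    )
  }, 0)
  expect_close(mean(lags), 4, 0.75)
})
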