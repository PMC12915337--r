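# small worlds reused across tests (2 years keeps generation fast while
# still allowing annual fits)
small_world <- function(seed = 1, ...) {
  generate_world(world_config(n_years = 2, ...), seed = seed)
}

# weekly log10 series of a daily column, pipeline-style (binning, WMA
# imputation of empty bins, WMA outlier correction)
weekly_log10 <- function(data, col) {
  d <- data
  d$value <- log10(d[[col]])
  w <- aggregate_weekly(d, value = "value")
  w$value <- as.numeric(correct_outliers(impute_wma(w$value), k = 3))
  w
}

# brute-force Spearman oracle: average ranks, then Pearson on the ranks
spearman_oracle <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# abundance-vs-desert phase lag for one world, using the pipeline's
# weekly preparation (binning, gap fill, WMA imputation + outlier
# correction, log10 PM, desert regional composite)
world_lag <- function(seed, config = world_config()) {
  w <- generate_world(config, seed = seed)
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
}

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
    label = sprintf("|%g - %g| <= %g", actual, expected, tol)
  )
}
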