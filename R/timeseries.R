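#' Weighted-moving-average imputation
#'
#' Fills missing values in a regular-cadence series with the weighted
#' moving average of the three preceding values,
#' `x_t = 1/6 x_{t-3} + 1/3 x_{t-2} + 1/2 x_{t-1}`, sweeping forward so
#' that earlier imputations feed later ones. Observed points are never
#' modified. Leading missing values are back-filled from the first
#' observed value before the sweep (the formula has no predecessors
#' there); if fewer than three points precede an interior gap the first
#' observed value is recycled the same way.
#'
#' @param x a numeric vector with `NA`s marking missing points, or a
#'   data frame containing such a column.
#' @param ... passed to methods.
#' @return For numeric input, a numeric vector with all `NA`s filled and
#'   an `"imputed"` attribute holding the filled indices. For data-frame
#'   input, a tibble with the value column filled and a logical
#'   `imputed` column.
#' @examples
#' impute_wma(c(6, 3, 2, NA))      # 1 + 1 + 1 = 3
#' impute_wma(c(5, 5, 5, NA, NA))  # constant series stays constant
#' @export
impute_wma <- function(x, ...) UseMethod("impute_wma")

wma_weights <- c(1 / 6, 1 / 3, 1 / 2) # x_{t-3}, x_{t-2}, x_{t-1}

#' @export
impute_wma.default <- function(x, ...) {
  x <- as.numeric(x)
  if (all(is.na(x))) {
    stop("cannot impute a series with no observed values", call. = FALSE)
  }
  missing_idx <- which(is.na(x))
  first_obs <- which(!is.na(x))[1]
  if (first_obs > 1) x[seq_len(first_obs - 1)] <- x[first_obs]
  for (t in which(is.na(x))) {
    idx <- t - (3:1)
    # gaps opening before index 4: recycle the earliest available value
    pred <- ifelse(idx >= 1, x[pmax(idx, 1)], x[1])
    if (anyNA(pred)) {
      stop("predecessors unavailable for imputation at index ", t,
        call. = FALSE
      )
    }
    x[t] <- sum(wma_weights * pred)
  }
  attr(x, "imputed") <- missing_idx
  x
}

#' @param value column holding the series values (default `value`).
#' @rdname impute_wma
#' @export
impute_wma.data.frame <- function(x, value = "value", ...) {
  value <- tidyselect_one(x, rlang::enquo(value), "value")
  v <- impute_wma.default(x[[value]])
  out <- as_tibble(x)
  out$imputed <- seq_len(nrow(out)) %in% attr(v, "imputed")
  out[[value]] <- as.numeric(v)
  out
}

# resolve a column given either a bare name, a string, or a default
tidyselect_one <- function(data, quo, default) {
  expr <- rlang::quo_get_expr(quo)
  nm <- if (rlang::quo_is_missing(quo)) {
    default
  } else if (rlang::is_string(expr) || rlang::is_character(expr)) {
    rlang::eval_tidy(quo)
  } else {
    rlang::as_name(quo)
  }
  if (!nm %in% names(data)) {
    stop("column `", nm, "` not found in data", call. = FALSE)
  }
  nm
}

#' Robust outlier correction by rolling median and MAD
#'
#' Flags points whose distance from a rolling median exceeds `k` times
#' the MAD of those distances, and replaces each flagged point with the
#' weighted moving average of its three predecessors (the same formula
#' as [impute_wma()]), sweeping forward.
#'
#' @inheritParams impute_wma
#' @param k robust-z threshold (default 4).
#' @param window rolling-median window width, odd (default 9).
#' @return as [impute_wma()], with attribute/column `replaced`.
#' @export
correct_outliers <- function(x, k = 4, window = 9, ...) {
  UseMethod("correct_outliers")
}

#' @export
correct_outliers.default <- function(x, k = 4, window = 9, ...) {
  x <- as.numeric(x)
  if (length(x) < 12) stop("need at least 12 points", call. = FALSE)
  if (anyNA(x)) stop("impute missing values before outlier correction",
    call. = FALSE
  )
  med <- stats::runmed(x, k = window, endrule = "median")
  resid <- x - med
  scale <- stats::mad(resid)
  # smooth series: the rolling median reproduces most points exactly and
  # the MAD degenerates to zero; fall back to the residual sd
  if (scale <= 0) scale <- stats::sd(resid)
  flagged <- if (scale > 0) which(abs(resid) > k * scale) else integer()
  flagged <- flagged[flagged > 3] # first points lack predecessors
  for (t in flagged) {
    x[t] <- sum(wma_weights * x[t - (3:1)])
  }
  attr(x, "replaced") <- flagged
  x
}

#' @param value column holding the series values (default `value`).
#' @rdname correct_outliers
#' @export
correct_outliers.data.frame <- function(x, k = 4, window = 9,
                                        value = "value", ...) {
  value <- tidyselect_one(x, rlang::enquo(value), "value")
  v <- correct_outliers.default(x[[value]], k = k, window = window)
  out <- as_tibble(x)
  out$replaced <- seq_len(nrow(out)) %in% attr(v, "replaced")
  out[[value]] <- as.numeric(v)
  out
}

#' Fit an annual sine/cosine harmonic
#'
#' Ordinary least squares of `Y` on `sin(2*pi*t)` and `cos(2*pi*t)` with
#' an intercept, `t` in years, capturing the predominant annual cycle.
#' The intercept is included because environmental series have large
#' positive means; R-squared is reported against the intercept-only
#' model, so it measures the share of variance carried by the annual
#' harmonic.
#'
#' @param data a data frame, or a numeric response vector.
#' @param value response column (data-frame method).
#' @param time column of times in years; if absent, `date` is used.
#' @param date column of `Date`s, converted to decimal years.
#' @param t numeric times in years (default method).
#' @param ... unused.
#' @return an object of class `harmonic_fit` with elements `a` (sine
#'   coefficient), `b` (cosine coefficient), `intercept`, `amplitude`
#'   (`sqrt(a^2 + b^2)`), `phase_rad` (`atan2(b, a)`), `peak_time`
#'   (fractional year of the fitted annual peak), `r2`, `pvalue`
#'   (model F-test), `n`, and the underlying `lm` fit.
#' @seealso [phase_lag()], [tidy.harmonic_fit()], [autoplot.harmonic_fit()]
#' @export
fit_harmonic <- function(data, ...) UseMethod("fit_harmonic")

#' @rdname fit_harmonic
#' @export
fit_harmonic.default <- function(data, t, ...) {
  y <- as.numeric(data)
  t <- as.numeric(t)
  stopifnot(length(y) == length(t))
  keep <- stats::complete.cases(y, t)
  y <- y[keep]
  t <- t[keep]
  if (length(y) < 4) stop("need at least 4 observations", call. = FALSE)
  if (diff(range(t)) < .Machine$double.eps) {
    stop("degenerate design: all times identical", call. = FALSE)
  }
  s <- sin(2 * pi * t)
  c_ <- cos(2 * pi * t)
  fit <- stats::lm(y ~ s + c_)
  cf <- stats::coef(fit)
  a <- unname(cf["s"])
  b <- unname(cf["c_"])
  sm <- summary(fit)
  fstat <- sm$fstatistic
  pvalue <- if (is.null(fstat)) {
    NA_real_
  } else {
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  }
  structure(
    list(
      a = a, b = b, intercept = unname(cf["(Intercept)"]),
      amplitude = sqrt(a^2 + b^2),
      phase_rad = atan2(b, a),
      peak_time = (atan2(a, b) / (2 * pi)) %% 1,
      r2 = sm$r.squared, pvalue = pvalue, n = length(y),
      t = t, y = y,
      fitted = unname(stats::fitted(fit)),
      residuals = unname(stats::residuals(fit)),
      lm = fit
    ),
    class = "harmonic_fit"
  )
}

#' @rdname fit_harmonic
#' @export
fit_harmonic.data.frame <- function(data, value = "value", time = NULL,
                                    date = "date", ...) {
  value <- tidyselect_one(data, rlang::enquo(value), "value")
  time_quo <- rlang::enquo(time)
  if (!rlang::quo_is_null(time_quo)) {
    t <- data[[tidyselect_one(data, time_quo, "time")]]
  } else {
    dcol <- tidyselect_one(data, rlang::enquo(date), "date")
    t <- lubridate::decimal_date(data[[dcol]])
  }
  fit_harmonic.default(data[[value]], t = t)
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat("Annual harmonic fit (Y ~ a sin(2 pi t) + b cos(2 pi t) + c)\n")
  cat(sprintf(
    "  a = %.4f, b = %.4f, intercept = %.4f\n", x$a, x$b, x$intercept
  ))
  cat(sprintf(
    "  amplitude = %.4f, peak at %.3f yr, R2 = %.3f, p = %.3g, n = %d\n",
    x$amplitude, x$peak_time, x$r2, x$pvalue, x$n
  ))
  invisible(x)
}

#' Phase lag between two fitted annual harmonics
#'
#' Computes `phase(y) - phase(x)` wrapped to `(-pi, pi]`, scaled to
#' weeks of an annual cycle. With `phase_rad = atan2(b, a)`, a positive
#' value means `x`'s annual peak falls later in the year than `y`'s
#' (equivalently, `x` lags `y`); `phase_lag(local, desert)` therefore
#' returns a positive number of weeks when the local series peaks after
#' the desert series.
#'
#' @param fit_x,fit_y `harmonic_fit` objects on the same annual period.
#' @param weeks_per_year weeks per annual cycle (default 52.18).
#' @param tol minimum amplitude below which phase is undefined.
#' @return lag in weeks, in `(-weeks_per_year/2, weeks_per_year/2]`.
#' @examples
#' t <- seq(0, 3, by = 1 / 52)
#' fx <- fit_harmonic(sin(2 * pi * t), t)
#' fy <- fit_harmonic(cos(2 * pi * t), t)
#' phase_lag(fx, fy) # quarter period, about 13 weeks
#' @export
phase_lag <- function(fit_x, fit_y, weeks_per_year = 52.18, tol = 1e-8) {
  stopifnot(inherits(fit_x, "harmonic_fit"), inherits(fit_y, "harmonic_fit"))
  if (fit_x$amplitude < tol || fit_y$amplitude < tol) {
    stop("amplitude below tolerance: phase undefined", call. = FALSE)
  }
  dphi <- wrap_pi(fit_y$phase_rad - fit_x$phase_rad)
  dphi / (2 * pi) * weeks_per_year
}

wrap_pi <- function(x) {
  out <- (x + pi) %% (2 * pi) - pi
  # map -pi to +pi so the interval is (-pi, pi]
  ifelse(out <= -pi + 1e-15, out + 2 * pi, out)
}

#' Discrete Fourier periodogram
#'
#' Raw periodogram of a mean-removed, regular-cadence series. Power is
#' scaled so that the sum over all returned frequencies equals the
#' (biased) series variance, a discrete Parseval identity.
#'
#' @param data data frame or numeric vector (no missing values).
#' @param value value column (data-frame method).
#' @param cadence_days sampling interval in days (default 7).
#' @param ... unused.
#' @return object of class `periodogram_ts`: a list with `spectrum`
#'   (tibble of `frequency` in cycles/year and `power`),
#'   `dominant_period` in years, and `total_power`.
#' @export
periodogram <- function(data, ...) UseMethod("periodogram")

#' @rdname periodogram
#' @export
periodogram.default <- function(data, cadence_days = 7, ...) {
  x <- as.numeric(data)
  if (anyNA(x)) stop("series has missing values; impute first", call. = FALSE)
  n <- length(x)
  if (n < 8) stop("series too short for a periodogram", call. = FALSE)
  x <- x - mean(x)
  dt_years <- cadence_days / 365.25
  xk <- stats::fft(x)
  half <- floor(n / 2)
  k <- seq_len(half)
  power <- Mod(xk[k + 1])^2 / n^2
  # fold negative frequencies onto positive ones (Nyquist unpaired if n even)
  two_sided <- ifelse(n %% 2 == 0 & k == half, 1, 2)
  power <- power * two_sided
  freq <- k / (n * dt_years)
  structure(
    list(
      spectrum = tibble(frequency = freq, power = power),
      dominant_period = 1 / freq[which.max(power)],
      total_power = sum(power)
    ),
    class = "periodogram_ts"
  )
}

#' @rdname periodogram
#' @export
periodogram.data.frame <- function(data, value = "value", cadence_days = 7,
                                   ...) {
  value <- tidyselect_one(data, rlang::enquo(value), "value")
  periodogram.default(data[[value]], cadence_days = cadence_days)
}

#' @export
print.periodogram_ts <- function(x, ...) {
  cat(sprintf(
    "Periodogram: %d frequencies, dominant period %.3f yr\n",
    nrow(x$spectrum), x$dominant_period
  ))
  invisible(x)
}

#' Classical additive decomposition
#'
#' Splits a regular series into trend (centered moving average),
#' seasonal (period-position means of the detrended series, re-centred
#' to sum to zero over one period) and residual components, via
#' [stats::decompose()].
#'
#' @param data data frame or numeric vector, no missing values.
#' @param value value column (data-frame method).
#' @param period samples per cycle (e.g. 52 for weekly data).
#' @param ... unused.
#' @return tibble with columns `index`, `value`, `trend`, `seasonal`,
#'   `residual` (`trend`/`residual` are `NA` within half a window of the
#'   edges, where the centered moving average is undefined).
#' @export
decompose_ts <- function(data, ...) UseMethod("decompose_ts")

#' @rdname decompose_ts
#' @export
decompose_ts.default <- function(data, period, ...) {
  x <- as.numeric(data)
  if (anyNA(x)) stop("series has missing values; impute first", call. = FALSE)
  if (length(x) < 2 * period) {
    stop("need at least two full periods", call. = FALSE)
  }
  dec <- stats::decompose(stats::ts(x, frequency = period), type = "additive")
  tibble(
    index = seq_along(x),
    value = x,
    trend = as.numeric(dec$trend),
    seasonal = as.numeric(dec$seasonal),
    residual = as.numeric(dec$random)
  )
}

#' @rdname decompose_ts
#' @export
decompose_ts.data.frame <- function(data, period, value = "value", ...) {
  value <- tidyselect_one(data, rlang::enquo(value), "value")
  decompose_ts.default(data[[value]], period = period)
}

#' Monthly climatology
#'
#' Pools a dated series by calendar month across years and returns the
#' per-month mean, standard deviation and count.
#'
#' @param data data frame with a date column and a value column.
#' @param value value column (default `value`).
#' @param date date column (default `date`).
#' @return tibble with one row per calendar month: `month` (1-12),
#'   `mean`, `sd`, `n`.
#' @export
aggregate_monthly <- function(data, value = "value", date = "date") {
  value <- tidyselect_one(data, rlang::enquo(value), "value")
  date <- tidyselect_one(data, rlang::enquo(date), "date")
  data %>%
    transmute(month = lubridate::month(.data[[date]]),
              .val = .data[[value]]) %>%
    filter(!is.na(.data$.val)) %>%
    group_by(month) %>%
    summarise(
      mean = mean(.data$.val),
      sd = stats::sd(.data$.val),
      n = dplyr::n(),
      .groups = "drop"
    ) %>%
    arrange(month)
}
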