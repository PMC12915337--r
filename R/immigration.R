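#' AQI breakpoint table
#'
#' Loads a piecewise-linear AQI-to-concentration breakpoint table. The
#' packaged default is the US EPA PM10 table; any YAML file with the
#' same structure (contiguous, non-overlapping `aqi_lo`/`aqi_hi` ranges
#' and non-decreasing `conc_lo`/`conc_hi`) can be supplied instead,
#' since the exact table is configuration, not code.
#'
#' @param path YAML file; `NULL` for the packaged default.
#' @return tibble with columns `aqi_lo`, `aqi_hi`, `conc_lo`, `conc_hi`.
#' @export
aqi_breakpoints <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aqi_breakpoints_pm10.yaml",
      package = "aerodyn"
    )
  }
  raw <- yaml::read_yaml(path)
  tab <- dplyr::bind_rows(lapply(raw$breakpoints, as_tibble))
  validate_breakpoints(tab)
  tab
}

validate_breakpoints <- function(tab) {
  stopifnot(all(c("aqi_lo", "aqi_hi", "conc_lo", "conc_hi") %in% names(tab)))
  tab <- arrange(tab, .data$aqi_lo)
  if (any(tab$aqi_hi < tab$aqi_lo) || any(tab$conc_hi < tab$conc_lo)) {
    stop("breakpoint rows must have hi >= lo", call. = FALSE)
  }
  if (nrow(tab) > 1 && any(diff(tab$conc_lo) < 0)) {
    stop("concentration breakpoints must be non-decreasing", call. = FALSE)
  }
  invisible(tab)
}

#' Convert AQI values to PM10 concentration
#'
#' Piecewise-linear inversion of the AQI transform: within the
#' bracketing breakpoint row,
#' `conc = conc_lo + (aqi - aqi_lo) * (conc_hi - conc_lo) / (aqi_hi - aqi_lo)`.
#'
#' @param aqi numeric AQI values (vectorized); must lie within the
#'   table's AQI span.
#' @param table breakpoint table (default [aqi_breakpoints()]).
#' @return PM10 concentration in ug/m3.
#' @export
aqi_to_pm10 <- function(aqi, table = aqi_breakpoints()) {
  table <- arrange(as_tibble(table), .data$aqi_lo)
  lo <- min(table$aqi_lo)
  hi <- max(table$aqi_hi)
  bad <- !is.na(aqi) & (aqi < lo | aqi > hi)
  if (any(bad)) {
    stop(sprintf("AQI outside table span [%g, %g]", lo, hi), call. = FALSE)
  }
  # piecewise-linear through every breakpoint knot: inside a row this is
  # conc_lo + (aqi - aqi_lo) * (conc_hi - conc_lo) / (aqi_hi - aqi_lo);
  # the short spans between consecutive rows are bridged linearly.
  knots_x <- as.numeric(rbind(table$aqi_lo, table$aqi_hi))
  knots_y <- as.numeric(rbind(table$conc_lo, table$conc_hi))
  stats::approx(knots_x, knots_y, xout = aqi, method = "linear",
    ties = "ordered"
  )$y
}

#' Convert PM10 concentration to AQI (forward map)
#'
#' Forward companion of [aqi_to_pm10()], mapping concentration onto the
#' index scale within the bracketing breakpoint row.
#'
#' @param pm10 concentration in ug/m3, within the table's span.
#' @inheritParams aqi_to_pm10
#' @return AQI values.
#' @export
pm10_to_aqi <- function(pm10, table = aqi_breakpoints()) {
  table <- arrange(as_tibble(table), .data$conc_lo)
  lo <- min(table$conc_lo)
  hi <- max(table$conc_hi)
  bad <- !is.na(pm10) & (pm10 < lo | pm10 > hi)
  if (any(bad)) {
    stop(sprintf("PM10 outside table span [%g, %g]", lo, hi), call. = FALSE)
  }
  knots_x <- as.numeric(rbind(table$conc_lo, table$conc_hi))
  knots_y <- as.numeric(rbind(table$aqi_lo, table$aqi_hi))
  stats::approx(knots_x, knots_y, xout = pm10, method = "linear",
    ties = "ordered"
  )$y
}

#' Daily frequency of an air-mass pathway
#'
#' Fraction of back-trajectory labels within each day equal to the
#' target pathway. Trajectories arrive at sub-daily intervals (12 labels
#' per day at a 2-hour cadence), so the frequency takes values in
#' `[0, 1]` at multiples of `1/n`. Days with no trajectory labels are
#' missing.
#'
#' @param labels data frame with a `datetime` (or `date`) column and a
#'   `pathway` column of single-letter labels.
#' @param pathway the pathway of interest (default `"A"`, the
#'   desert-origin route).
#' @return tibble with `date`, `freq`, `n` (labels counted that day).
#' @export
pathway_frequency <- function(labels, pathway = "A") {
  stopifnot("pathway" %in% names(labels))
  dt <- if ("datetime" %in% names(labels)) {
    lubridate::as_date(labels$datetime)
  } else if ("date" %in% names(labels)) {
    lubridate::as_date(labels$date)
  } else {
    stop("labels needs a `datetime` or `date` column", call. = FALSE)
  }
  tibble(date = dt, pathway = labels$pathway) %>%
    group_by(date) %>%
    summarise(
      freq = mean(.data$pathway == .env$pathway),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Dust-immigration index
#'
#' Frequency-weighted desert dust influx: desert PM10 multiplied by the
#' daily frequency of the desert-origin air-mass pathway, then smoothed
#' with a trailing (causal) moving average so the index can serve as a
#' same-day indicator. At the start of the series, where fewer than
#' `smooth_days` values exist, the mean of the available values is used.
#'
#' @param data data frame with aligned daily columns given by `pm10`
#'   and `freq`.
#' @param pm10 desert PM10 column (default `pm10`).
#' @param freq pathway-frequency column (default `freq`).
#' @param smooth_days moving-average window in days (default 4).
#' @param centered use a centered window instead of trailing.
#' @return the input tibble with an added `index` column (ug/m3,
#'   frequency-weighted).
#' @export
immigration_index <- function(data, pm10 = "pm10", freq = "freq",
                              smooth_days = 4, centered = FALSE) {
  pm10 <- tidyselect_one(data, rlang::enquo(pm10), "pm10")
  freq <- tidyselect_one(data, rlang::enquo(freq), "freq")
  if ("date" %in% names(data)) {
    dd <- diff(as.numeric(as.Date(data$date)))
    if (length(dd) && any(dd != 1)) {
      stop("calendars misaligned: `date` must be consecutive days",
        call. = FALSE
      )
    }
  }
  f <- data[[freq]]
  if (any(f < 0 | f > 1, na.rm = TRUE)) {
    stop("pathway frequency must lie in [0, 1]", call. = FALSE)
  }
  raw <- data[[pm10]] * f
  out <- as_tibble(data)
  align <- if (centered) "center" else "right"
  out$index <- zoo::rollapply(raw, width = smooth_days, FUN = mean,
    align = align, partial = TRUE
  )
  out
}
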