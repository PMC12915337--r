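#' Bacterial fraction of an amplicon library
#'
#' Share of reads that are bacterial after excluding chloroplast,
#' mitochondrial and other non-bacterial sequences:
#' `bacterial / (bacterial + chloroplast + mito + other)`. Universal 16S
#' primers co-amplify plant organelle sequences, which surge during the
#' spring pollination season and would otherwise inflate abundance
#' estimates.
#'
#' @param reads_bacterial,reads_chloroplast,reads_mito,reads_other
#'   non-negative read counts (vectorized).
#' @return proportion in `[0, 1]`.
#' @examples
#' bacterial_fraction(100, 0, 0, 0) # 1
#' bacterial_fraction(50, 50)       # 0.5
#' @export
bacterial_fraction <- function(reads_bacterial, reads_chloroplast = 0,
                               reads_mito = 0, reads_other = 0) {
  total <- reads_bacterial + reads_chloroplast + reads_mito + reads_other
  if (any(c(reads_bacterial, reads_chloroplast, reads_mito, reads_other) < 0,
    na.rm = TRUE
  )) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  if (any(total == 0, na.rm = TRUE)) {
    stop("zero total reads: bacterial fraction undefined", call. = FALSE)
  }
  reads_bacterial / total
}

#' Scale qPCR totals by the bacterial fraction
#'
#' Converts total 16S rRNA gene copies per cubic metre and a bacterial
#' read fraction into log10 bacterial copies per cubic metre,
#' `log10(total_copies * fraction)`. A zero fraction is returned as `NA`
#' (flagged missing) rather than `-Inf`.
#'
#' @param total_copies total gene copies per m3, linear scale, `> 0`.
#' @param fraction bacterial proportion in `(0, 1]`.
#' @return log10 copies per m3 (vectorized).
#' @examples
#' adjust_abundance(1000, 0.5) # log10(500)
#' @export
adjust_abundance <- function(total_copies, fraction) {
  if (any(total_copies <= 0, na.rm = TRUE)) {
    stop("total_copies must be positive", call. = FALSE)
  }
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE)) {
    stop("fraction must be in [0, 1]", call. = FALSE)
  }
  out <- log10(total_copies * fraction)
  out[!is.na(fraction) & fraction == 0] <- NA_real_
  out
}

#' Build an absolute bacterial abundance series from sample records
#'
#' Takes a per-sample table with qPCR totals and read-category counts
#' and returns the adjusted abundance series: total and bacterial log10
#' copies per m3 plus the bacterial read fraction. Samples without
#' sequencing data get `NA` bacterial abundance with provenance
#' `"missing"`, to be filled by [fill_missing_composition()].
#'
#' @param samples data frame with columns `date`, `total_copies`,
#'   `reads_bacterial`, `reads_chloroplast`, `reads_mito`, `reads_other`
#'   and optionally `has_sequencing` (otherwise inferred from a positive
#'   read total).
#' @return tibble with `date`, `log10_total`, `bacterial_fraction`,
#'   `log10_bacterial`, `provenance` (`"measured"` or `"missing"`).
#' @export
abundance_series <- function(samples) {
  req <- c(
    "date", "total_copies", "reads_bacterial", "reads_chloroplast",
    "reads_mito", "reads_other"
  )
  miss <- setdiff(req, names(samples))
  if (length(miss)) {
    stop("samples lacks columns: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  samples <- as_tibble(samples)
  total_reads <- samples$reads_bacterial + samples$reads_chloroplast +
    samples$reads_mito + samples$reads_other
  has_seq <- if ("has_sequencing" %in% names(samples)) {
    samples$has_sequencing & total_reads > 0
  } else {
    total_reads > 0
  }
  frac <- rep(NA_real_, nrow(samples))
  frac[has_seq] <- bacterial_fraction(
    samples$reads_bacterial[has_seq], samples$reads_chloroplast[has_seq],
    samples$reads_mito[has_seq], samples$reads_other[has_seq]
  )
  tibble(
    date = samples$date,
    log10_total = log10(samples$total_copies),
    bacterial_fraction = frac,
    log10_bacterial = ifelse(has_seq,
      adjust_abundance(samples$total_copies, ifelse(has_seq, frac, 1)),
      NA_real_
    ),
    provenance = if_else(has_seq & !is.na(frac), "measured", "missing")
  )
}

#' Aggregate samples into a weekly time series
#'
#' Bins dated values into ISO calendar weeks; the bin value is the mean
#' of member samples (log scale for abundance, so within-week averaging
#' happens on the same scale as the downstream statistics). Weeks inside
#' the span with no samples are kept as missing bins.
#'
#' @param data data frame with a date column and a value column.
#' @param value value column (default `value`).
#' @param date date column (default `date`).
#' @return tibble with `week_start` (Monday of the ISO week), `value`
#'   (`NA` for empty bins) and `n_obs`.
#' @export
aggregate_weekly <- function(data, value = "value", date = "date") {
  value <- tidyselect_one(data, rlang::enquo(value), "value")
  date <- tidyselect_one(data, rlang::enquo(date), "date")
  d <- tibble(
    week_start = lubridate::floor_date(data[[date]], "week",
      week_start = 1
    ),
    .val = data[[value]]
  )
  grid <- tibble(
    week_start = seq(min(d$week_start), max(d$week_start), by = "7 days")
  )
  binned <- d %>%
    group_by(week_start) %>%
    summarise(
      value = if (all(is.na(.data$.val))) NA_real_ else {
        mean(.data$.val, na.rm = TRUE)
      },
      n_obs = sum(!is.na(.data$.val)),
      .groups = "drop"
    )
  grid %>%
    left_join(binned, by = "week_start") %>%
    mutate(n_obs = if_else(is.na(n_obs), 0L, as.integer(n_obs)))
}

#' Fill missing stretches of a weekly abundance series
#'
#' Long contiguous gaps (at least `gap_threshold` consecutive missing
#' weeks, e.g. a monsoon interruption) are filled with the mean of
#' same-ISO-week values from the other years of the record, reflecting
#' the consistent seasonal pattern; shorter, isolated gaps are filled by
#' linear interpolation between the flanking observations. Provenance is
#' recorded per point.
#'
#' @param weekly tibble from [aggregate_weekly()] (columns `week_start`,
#'   `value`), or any data frame with those columns.
#' @param gap_threshold run length (weeks) at or above which seasonal
#'   averaging is used instead of linear interpolation (default 3).
#' @return the input with `value` filled where possible and a
#'   `provenance` column in `{"measured", "seasonal_average",
#'   "linear_interpolated", "missing"}`.
#' @export
fill_missing_composition <- function(weekly, gap_threshold = 3) {
  stopifnot(all(c("week_start", "value") %in% names(weekly)))
  out <- as_tibble(weekly)
  span_years <- as.numeric(diff(range(out$week_start))) / 365.25
  if (span_years < 1 && anyNA(out$value)) {
    stop("need at least one full annual cycle for seasonal averaging",
      call. = FALSE
    )
  }
  v <- out$value
  prov <- if_else(is.na(v), "missing", "measured")
  iso_wk <- lubridate::isoweek(out$week_start)
  iso_yr <- lubridate::isoyear(out$week_start)
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in seq_along(r$lengths)) {
    if (!r$values[j]) next
    idx <- starts[j]:ends[j]
    if (r$lengths[j] >= gap_threshold) {
      for (i in idx) {
        donors <- which(iso_wk == iso_wk[i] & iso_yr != iso_yr[i] & !is.na(v))
        if (length(donors)) {
          v[i] <- mean(v[donors])
          prov[i] <- "seasonal_average"
        } else {
          warning("no same-week donor year for week starting ",
            out$week_start[i],
            call. = FALSE
          )
        }
      }
    }
  }
  # remaining short gaps: linear interpolation between flanking values
  still <- is.na(v)
  if (any(still) && sum(!still) >= 2) {
    interp <- stats::approx(
      x = which(!still), y = v[!still], xout = which(still),
      method = "linear", rule = 1
    )$y
    filled <- which(still)[!is.na(interp)]
    v[filled] <- interp[!is.na(interp)]
    prov[filled] <- "linear_interpolated"
  }
  out$value <- v
  out$provenance <- prov
  out
}
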