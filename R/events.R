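#' Detect official dust events in hourly PM10
#'
#' An official Asian-dust event is a period in which hourly PM10
#' exceeds the threshold (strictly) for more than `min_hours`
#' consecutive hours. Exceedance runs separated by less than
#' `merge_gap_hours` are first merged into one candidate episode (a
#' brief dip below threshold does not split an event); merged episodes
#' are kept when their exceedance hours total strictly more than
#' `min_hours`.
#'
#' @param data data frame with `datetime` (POSIXct, hourly cadence) and
#'   `pm10` columns.
#' @param threshold exceedance threshold in ug/m3 (default 150).
#' @param min_hours events must exceed for strictly more than this many
#'   hours (default 2).
#' @param merge_gap_hours runs closer than this are merged (default 12).
#' @return tibble of events: `kind` (`"official"`), `start`, `end`
#'   (first and last exceedance hour), `peak_pm10`, `n_hours`.
#' @export
detect_official_events <- function(data, threshold = 150, min_hours = 2,
                                   merge_gap_hours = 12) {
  stopifnot(all(c("datetime", "pm10") %in% names(data)))
  data <- arrange(as_tibble(data), .data$datetime)
  dt <- diff(as.numeric(data$datetime))
  if (length(dt) && any(abs(dt - 3600) > 1)) {
    stop("PM10 series must have hourly cadence", call. = FALSE)
  }
  above <- !is.na(data$pm10) & data$pm10 > threshold
  empty <- tibble(
    kind = character(), start = data$datetime[0], end = data$datetime[0],
    peak_pm10 = numeric(), n_hours = integer()
  )
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- tibble(start = starts[r$values], end = ends[r$values])
  # merge runs separated by short sub-threshold gaps
  merged <- list(runs[1, ])
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      lastr <- merged[[length(merged)]]
      if (runs$start[i] - lastr$end < merge_gap_hours) {
        merged[[length(merged)]]$end <- runs$end[i]
      } else {
        merged[[length(merged) + 1]] <- runs[i, ]
      }
    }
  }
  merged <- bind_rows(merged)
  out <- purrr::pmap_dfr(merged, function(start, end) {
    idx <- start:end
    idx_above <- idx[above[idx]]
    tibble(
      kind = "official",
      start = data$datetime[min(idx_above)],
      end = data$datetime[max(idx_above)],
      peak_pm10 = max(data$pm10[idx_above]),
      n_hours = length(idx_above)
    )
  })
  out[out$n_hours > min_hours, ]
}

#' Detect desert-origin PM10 spikes in daily PM10
#'
#' A spike day has daily PM10 strictly above the threshold and a
#' desert-origin air-mass pathway label. Consecutive spike days merge
#' into one episode. Days falling inside official dust events are
#' excluded, so spikes capture the moderate influx outside declared
#' events.
#'
#' @param data data frame with daily `date` and `pm10` columns.
#' @param pathways data frame with daily `date` and `pathway` label.
#' @param threshold spike threshold in ug/m3 (default 45.0, roughly
#'   150 percent of a typical study-mean PM10).
#' @param pathway qualifying pathway label (default `"A"`).
#' @param exclude optional tibble of official events (columns
#'   `start`, `end`, as from [detect_official_events()]); days
#'   overlapping them are skipped.
#' @return tibble of episodes: `kind` (`"spike"`), `start`, `end`
#'   (dates), `peak_pm10`, `n_days`, `pathway`.
#' @export
detect_spikes <- function(data, pathways, threshold = 45.0, pathway = "A",
                          exclude = NULL) {
  stopifnot(
    all(c("date", "pm10") %in% names(data)),
    all(c("date", "pathway") %in% names(pathways))
  )
  target <- pathway
  d <- as_tibble(data) %>%
    left_join(dplyr::select(pathways, date, pathway), by = "date") %>%
    arrange(date)
  is_spike <- !is.na(d$pm10) & d$pm10 > threshold &
    !is.na(d$pathway) & d$pathway == target
  if (!is.null(exclude) && nrow(exclude)) {
    ev_days <- unique(do.call(c, purrr::map2(
      lubridate::as_date(exclude$start), lubridate::as_date(exclude$end),
      ~ seq(.x, .y, by = "1 day")
    )))
    is_spike <- is_spike & !(d$date %in% ev_days)
  }
  empty <- tibble(
    kind = character(), start = d$date[0], end = d$date[0],
    peak_pm10 = numeric(), n_days = integer(), pathway = character()
  )
  if (!any(is_spike)) return(empty)
  grp <- cumsum(c(TRUE, diff(as.numeric(d$date[is_spike])) > 1))
  split(which(is_spike), grp) %>%
    purrr::map_dfr(function(idx) {
      tibble(
        kind = "spike",
        start = min(d$date[idx]),
        end = max(d$date[idx]),
        peak_pm10 = max(d$pm10[idx]),
        n_days = length(idx),
        pathway = pathway
      )
    })
}

#' Before/during/after event effect on bacterial abundance
#'
#' For each event, compares mean linear-scale abundance in the during
#' window (the event days) against the `window_days` immediately before
#' it, as a percentage ratio `(during / before) * 100`; the after-window
#' drop is `(1 - after / during) * 100`. Aggregates over events as mean,
#' sample sd and range, and tests before-vs-during on the log10 scale
#' with a paired test. Note the ratio convention: a ratio of 545 percent
#' means during levels were 5.45 times the pre-event level (the mean of
#' per-event during/before ratios, times 100), not a 545-point increase
#' over 100.
#'
#' @param abundance data frame with `date` and a log10 abundance column.
#' @param events tibble of events with `start` and `end` (dates or
#'   datetimes).
#' @param window_days width of the before and after windows, adjacent
#'   to and excluding the event days (default 7).
#' @param value abundance column (default `log10_bacterial`).
#' @param scale `"log10"` if the column is log10 abundance (linearized
#'   before averaging), `"linear"` otherwise.
#' @return object of class `event_effect`: list with `per_event`
#'   (tibble of windows means and ratios), `summary` (mean, sd, min,
#'   max of `ratio_percent` and of `post_drop_percent`), `p_value`
#'   (paired t on log10 before vs during means; `NA` when fewer than 3
#'   usable events) and `n_events`.
#' @export
event_effect <- function(abundance, events, window_days = 7,
                         value = "log10_bacterial", scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  value <- tidyselect_one(abundance, rlang::enquo(value), "log10_bacterial")
  if (nrow(events) == 0) stop("no events supplied", call. = FALSE)
  ab_date <- lubridate::as_date(abundance$date)
  lin <- if (scale == "log10") 10^abundance[[value]] else abundance[[value]]
  win_mean <- function(from, to) {
    sel <- !is.na(lin) & ab_date >= from & ab_date <= to
    if (!any(sel)) NA_real_ else mean(lin[sel])
  }
  per_event <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    s <- lubridate::as_date(events$start[i])
    e <- lubridate::as_date(events$end[i])
    before <- win_mean(s - window_days, s - 1)
    during <- win_mean(s, e)
    after <- win_mean(e + 1, e + window_days)
    tibble(
      event = i, start = s, end = e,
      before = before, during = during, after = after,
      ratio_percent = during / before * 100,
      post_drop_percent = (1 - after / during) * 100
    )
  })
  usable <- per_event[!is.na(per_event$ratio_percent), ]
  skipped <- nrow(per_event) - nrow(usable)
  if (skipped > 0) {
    warning(skipped, " event(s) skipped: empty before or during window",
      call. = FALSE
    )
  }
  if (nrow(usable) < 1) stop("no event has usable windows", call. = FALSE)
  summ <- tibble(
    statistic = c("ratio_percent", "post_drop_percent"),
    mean = c(
      mean(usable$ratio_percent),
      mean(usable$post_drop_percent, na.rm = TRUE)
    ),
    sd = c(
      stats::sd(usable$ratio_percent),
      stats::sd(usable$post_drop_percent, na.rm = TRUE)
    ),
    min = c(
      min(usable$ratio_percent),
      suppressWarnings(min(usable$post_drop_percent, na.rm = TRUE))
    ),
    max = c(
      max(usable$ratio_percent),
      suppressWarnings(max(usable$post_drop_percent, na.rm = TRUE))
    )
  )
  p_value <- if (nrow(usable) >= 3) {
    event_test(log10(usable$before), log10(usable$during))
  } else {
    NA_real_
  }
  structure(
    list(
      per_event = per_event, summary = summ,
      p_value = p_value, n_events = nrow(usable),
      window_days = window_days
    ),
    class = "event_effect"
  )
}

#' @export
print.event_effect <- function(x, ...) {
  r <- x$summary[x$summary$statistic == "ratio_percent", ]
  cat(sprintf(
    "Event effect over %d event(s): during/before = %.0f%% +/- %.0f%% (range %.0f-%.0f%%), p = %.3g\n",
    x$n_events, r$mean, r$sd, r$min, r$max, x$p_value
  ))
  invisible(x)
}

#' Paired before-vs-during comparison
#'
#' Two-sided paired test on log10 abundance, pairing by event. The
#' default paired t-test is well calibrated for these small-n designs
#' (checked against the exact sign-flip permutation distribution); a
#' Wilcoxon signed-rank alternative is available.
#'
#' @param before,during numeric vectors (log10 scale), paired by event.
#' @param method `"t"` (default) or `"wilcoxon"`.
#' @return two-sided p-value.
#' @export
event_test <- function(before, during, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  stopifnot(length(before) == length(during))
  if (length(before) < 3) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  d <- during - before
  if (all(abs(d) < .Machine$double.eps^0.5)) return(1) # t statistic 0
  if (stats::sd(d) < .Machine$double.eps^0.5) return(0) # exact constant shift
  if (method == "t") {
    stats::t.test(during, before, paired = TRUE)$p.value
  } else {
    suppressWarnings(
      stats::wilcox.test(during, before, paired = TRUE)$p.value
    )
  }
}
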