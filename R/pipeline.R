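#' Analysis configuration
#'
#' Bundles every tunable of the end-to-end analysis: the synthetic
#' world settings (used when no observed world is supplied), the
#' significance and collinearity cutoffs, event thresholds, window
#' widths, smoothing span and the SEM specification.
#'
#' @param world a [world_config()].
#' @param alpha edge significance cutoff (default 0.05).
#' @param collinearity_threshold absolute-rho pruning cutoff (0.8).
#' @param event_threshold official-event hourly PM10 threshold,
#'   ug/m3 (150).
#' @param spike_threshold daily PM10 spike threshold, ug/m3 (45.0).
#' @param window_days before/after event window width (7).
#' @param smooth_days immigration-index moving average span (4).
#' @param gap_threshold weeks of contiguous missingness at which
#'   seasonal averaging replaces linear interpolation (3).
#' @param outlier_k robust-z cutoff for dropping dust-event outlier
#'   days before the SEM fit (3.5).
#' @param sem SEM specification (default [airborne_sem_spec()]).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(world = world_config(),
                            alpha = 0.05,
                            collinearity_threshold = 0.8,
                            event_threshold = 150,
                            spike_threshold = 45.0,
                            window_days = 7,
                            smooth_days = 4,
                            gap_threshold = 3,
                            outlier_k = 3.5,
                            sem = airborne_sem_spec()) {
  stopifnot(
    alpha > 0, collinearity_threshold > 0, event_threshold > 0,
    spike_threshold > 0, window_days > 0, smooth_days > 0
  )
  structure(
    list(
      world = world, alpha = alpha,
      collinearity_threshold = collinearity_threshold,
      event_threshold = event_threshold,
      spike_threshold = spike_threshold,
      window_days = window_days, smooth_days = smooth_days,
      gap_threshold = gap_threshold, outlier_k = outlier_k, sem = sem
    ),
    class = "analysis_config"
  )
}

# weekly bin -> WMA imputation of empty bins -> WMA outlier correction
# (episodic dust spikes are replaced by the weighted moving average so
# the harmonic fits track the seasonal cycle, not single events)
weekly_imputed <- function(data, value, date = "date", outlier_k = 3) {
  w <- aggregate_weekly(data, value = {{ value }}, date = {{ date }})
  w$value <- impute_wma(w$value)
  w$value <- as.numeric(correct_outliers(w$value, k = outlier_k))
  w
}

modal_pathway <- function(pathway_labels) {
  pathway_labels %>%
    mutate(date = lubridate::as_date(datetime)) %>%
    group_by(date) %>%
    summarise(
      pathway = names(sort(table(pathway), decreasing = TRUE))[1],
      .groups = "drop"
    )
}

#' Run the full analysis end-to-end
#'
#' Orchestrates every stage on a (synthetic or supplied) world:
#' absolute-abundance integration and gap filling, weekly aggregation
#' and WMA imputation, annual harmonic fits with phase lags for
#' bacterial abundance, local PM10 and desert PM10, periodograms,
#' monthly climatologies, the pruned Spearman network with modules and
#' the focal subnetwork, official-event and spike detection with
#' before/during/after effects, the desert dust-immigration indices,
#' and the LG/RD structural equation model. Fully reproducible from
#' the configuration and seed.
#'
#' @param config an [analysis_config()].
#' @param seed integer seed (drives world generation and SEM restarts).
#' @param world optional pre-generated `synthetic_world` (or a list
#'   with the same components); when `NULL` one is generated from
#'   `config$world` under `seed`.
#' @return object of class `analysis_report`, a named list of result
#'   sections; see [write_report()] and [validate_report()].
#' @export
run_full_analysis <- function(config = analysis_config(), seed = 1,
                              world = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(world)) world <- generate_world(config$world, seed = seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage `%s` failed: %s", name, conditionMessage(e)),
        call. = FALSE
      )
    })
  }

  # -- abundance ---------------------------------------------------------
  ab <- stage("abundance", abundance_series(world$samples))
  weekly_ab <- stage("abundance", {
    w <- aggregate_weekly(ab, value = "log10_bacterial")
    w <- fill_missing_composition(w, gap_threshold = config$gap_threshold)
    w$value <- impute_wma(w$value)
    w$value <- as.numeric(correct_outliers(w$value, k = 3))
    w
  })

  # -- desert PM10 via AQI conversion, regional composite ---------------
  daily <- world$daily
  bp <- aqi_breakpoints()
  desert <- stage("immigration", {
    tibble(
      date = daily$date,
      horqin = aqi_to_pm10(daily$desert_aqi_horqin, bp),
      gobi = aqi_to_pm10(daily$desert_aqi_gobi, bp),
      taklimakan = aqi_to_pm10(daily$desert_aqi_taklimakan, bp)
    ) %>%
      mutate(composite = (horqin + gobi + taklimakan) / 3)
  })

  # PM series are analysed on the log10 scale, like abundance, so that
  # episodic dust spikes do not dominate the least-squares harmonics
  weekly_local <- stage("timeseries", weekly_imputed(
    mutate(daily, log10_local_pm10 = log10(local_pm10)), log10_local_pm10
  ))
  weekly_desert <- stage("timeseries", weekly_imputed(
    mutate(desert, log10_desert_pm10 = log10(composite)), log10_desert_pm10
  ))

  # -- harmonics, lags, spectra, decomposition --------------------------
  fits <- stage("timeseries", list(
    abundance = fit_harmonic(weekly_ab, value = "value", date = "week_start"),
    local_pm10 = fit_harmonic(weekly_local, value = "value", date = "week_start"),
    desert_pm10 = fit_harmonic(weekly_desert, value = "value", date = "week_start")
  ))
  lags <- stage("timeseries", list(
    abundance_behind_desert = phase_lag(fits$abundance, fits$desert_pm10),
    local_behind_desert = phase_lag(fits$local_pm10, fits$desert_pm10),
    abundance_behind_local = phase_lag(fits$abundance, fits$local_pm10)
  ))
  spectra <- stage("timeseries", purrr::map(
    list(
      abundance = weekly_ab, local_pm10 = weekly_local,
      desert_pm10 = weekly_desert
    ),
    ~ periodogram(.x, value = "value", cadence_days = 7)
  ))
  decomposition <- stage("timeseries", purrr::map(
    list(
      abundance = weekly_ab, local_pm10 = weekly_local,
      desert_pm10 = weekly_desert
    ),
    ~ decompose_ts(.x, period = 52, value = "value")
  ))

  # -- pathway frequencies and immigration indices ----------------------
  freq_a <- stage("immigration", pathway_frequency(world$pathway_labels, "A"))
  immigration <- stage("immigration", {
    purrr::map(c(
      rd_horqin = "horqin", rd_gobi = "gobi",
      rd_taklimakan = "taklimakan"
    ), function(region) {
      desert %>%
        select(date, pm10 = dplyr::all_of(region)) %>%
        left_join(freq_a, by = "date") %>%
        mutate(freq = if_else(is.na(freq), 0, freq)) %>%
        immigration_index(smooth_days = config$smooth_days) %>%
        select(date, index)
    })
  })

  # -- monthly climatologies --------------------------------------------
  monthly <- stage("timeseries", list(
    abundance = aggregate_monthly(ab, value = "log10_bacterial"),
    local_pm10 = aggregate_monthly(daily, value = "local_pm10"),
    desert_pm10 = aggregate_monthly(desert, value = "composite"),
    pathway_a = aggregate_monthly(freq_a, value = "freq"),
    temperature = aggregate_monthly(daily, value = "temperature"),
    humidity = aggregate_monthly(daily, value = "humidity"),
    precipitation = aggregate_monthly(daily, value = "precipitation")
  ))

  # -- correlation network ----------------------------------------------
  network <- stage("network", {
    month_key <- function(d) format(d, "%Y-%m")
    ab_m <- ab %>%
      filter(!is.na(log10_bacterial)) %>%
      group_by(ym = month_key(date)) %>%
      summarise(abundance = mean(log10_bacterial), .groups = "drop")
    freq_m <- purrr::reduce(
      lapply(c("A", "B", "C", "D", "E"), function(pp) {
        pathway_frequency(world$pathway_labels, pp) %>%
          group_by(ym = month_key(date)) %>%
          summarise("pathway_{pp}" := mean(freq), .groups = "drop")
      }),
      ~ left_join(.x, .y, by = "ym")
    )
    met_m <- daily %>%
      mutate(ym = month_key(date)) %>%
      group_by(ym) %>%
      summarise(
        across(
          c(temperature, humidity, pressure, cloud, precipitation,
            local_pm10),
          mean
        ),
        .groups = "drop"
      )
    des_m <- desert %>%
      mutate(ym = month_key(date)) %>%
      group_by(ym) %>%
      summarise(desert_pm10 = mean(composite), .groups = "drop")
    tab <- ab_m %>%
      left_join(met_m, by = "ym") %>%
      left_join(des_m, by = "ym") %>%
      left_join(freq_m, by = "ym") %>%
      select(-ym)
    pruned <- prune_collinear(tab,
      threshold = config$collinearity_threshold,
      keep = c("abundance", "local_pm10", "desert_pm10")
    )
    tab <- tab[, pruned$kept]
    sm <- spearman_matrix(tab)
    classes <- c(
      abundance = "population", local_pm10 = "PM", desert_pm10 = "PM",
      temperature = "meteorology", humidity = "meteorology",
      pressure = "meteorology", cloud = "meteorology",
      precipitation = "meteorology",
      pathway_A = "pathway", pathway_B = "pathway", pathway_C = "pathway",
      pathway_D = "pathway", pathway_E = "pathway"
    )
    net <- build_network(sm$rho, sm$p, alpha = config$alpha,
      classes = classes
    )
    modules <- find_modules(net)
    focal <- intersect(
      c("abundance", "local_pm10", "desert_pm10"), pruned$kept
    )
    list(
      table = tab, pruned = pruned, net = net, modules = modules,
      ego = ego_subnetwork(net, focal), focal = focal
    )
  })

  # -- events ------------------------------------------------------------
  events <- stage("events", {
    official <- detect_official_events(world$hourly_pm10,
      threshold = config$event_threshold
    )
    daily_path <- modal_pathway(world$pathway_labels)
    spikes <- detect_spikes(
      daily %>% select(date, pm10 = local_pm10),
      daily_path,
      threshold = config$spike_threshold,
      exclude = official
    )
    try_effect <- function(ev) {
      if (nrow(ev) == 0) return(NULL)
      tryCatch(
        event_effect(ab, ev, window_days = config$window_days),
        error = function(e) NULL
      )
    }
    effect <- try_effect(official)
    spike_effect <- try_effect(spikes)
    list(
      official = official, spikes = spikes,
      effect = effect, spike_effect = spike_effect
    )
  })

  # -- structural equation model ----------------------------------------
  # The SEM quantifies the day-to-day covariance structure linking the
  # latents to their indicators. Two preparation steps: the annual
  # harmonic is removed from every indicator, so structural paths
  # reflect short-term covariation rather than the mutual alignment of
  # seasonal cycles (desert dust and the local aerosol share a spring
  # season, which would otherwise be attributed wholesale to the
  # dispersal path); and dust-event outliers are dropped before
  # fitting — days inside or shortly after a detected official event
  # (the smoothed immigration indices carry the spike for a few days)
  # plus any remaining day with robust z beyond `outlier_k` on any
  # indicator. The event analysis quantifies those episodes separately.
  sem <- stage("sem", {
    z <- function(x) (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
    deseason <- function(x, dates) {
      ok <- !is.na(x)
      fit <- fit_harmonic(x[ok], lubridate::decimal_date(dates[ok]))
      out <- x
      out[ok] <- fit$residuals
      out
    }
    sem_tab <- daily %>%
      transmute(
        date,
        humidity,
        pressure,
        cloud,
        local_pm10 = log10(.data$local_pm10)
      ) %>%
      left_join(immigration$rd_horqin %>% rename(rd_horqin = index),
        by = "date"
      ) %>%
      left_join(immigration$rd_gobi %>% rename(rd_gobi = index),
        by = "date"
      ) %>%
      left_join(immigration$rd_taklimakan %>% rename(rd_taklimakan = index),
        by = "date"
      ) %>%
      left_join(
        ab %>% filter(provenance == "measured") %>%
          select(date, log10_bacterial),
        by = "date"
      )
    event_days <- if (nrow(events$official)) {
      unique(do.call(c, purrr::map2(
        lubridate::as_date(events$official$start) - 1,
        lubridate::as_date(events$official$end) + config$smooth_days + 2,
        ~ seq(.x, .y, by = "1 day")
      )))
    } else {
      as.Date(character())
    }
    sem_tab <- sem_tab %>%
      filter(!(date %in% event_days)) %>%
      mutate(across(-date, ~ deseason(.x, date))) %>%
      mutate(across(-date, z))
    # flag residual spikes the event windows missed; sd-based so the
    # skewed immigration indices (long low-influx stretches) are not
    # over-flagged the way a MAD rule would
    flagged <- purrr::map(
      select(sem_tab, -date),
      function(x) !is.na(x) & abs(x) > config$outlier_k
    ) %>%
      purrr::reduce(`|`)
    # trailing smoothing carries a spike forward: extend each flag
    base_flags <- flagged
    for (k in seq_len(config$smooth_days + 1)) {
      flagged <- flagged | dplyr::lag(base_flags, k, default = FALSE)
    }
    fit_sem(sem_tab[!flagged, ], spec = config$sem, seed = seed)
  })

  report <- structure(
    list(
      seed = seed,
      config_hash = rlang::hash(config),
      abundance = list(
        series = ab,
        weekly = weekly_ab,
        summary = list(
          mean = mean(ab$log10_bacterial, na.rm = TRUE),
          sd = stats::sd(ab$log10_bacterial, na.rm = TRUE),
          min = min(ab$log10_bacterial, na.rm = TRUE),
          max = max(ab$log10_bacterial, na.rm = TRUE),
          n_samples = nrow(ab),
          n_measured = sum(ab$provenance == "measured")
        )
      ),
      monthly = monthly,
      harmonics = fits,
      lags = lags,
      spectra = spectra,
      decomposition = decomposition,
      network = network,
      events = events,
      immigration = immigration,
      sem = sem,
      world_truth = world$truth
    ),
    class = "analysis_report"
  )
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Airborne-bacteria analysis report\n")
  cat(sprintf(
    "  abundance: %.2f +/- %.2f log10 copies/m3 (n = %d)\n",
    x$abundance$summary$mean, x$abundance$summary$sd,
    x$abundance$summary$n_samples
  ))
  cat(sprintf(
    "  harmonic R2: abundance %.2f, local PM10 %.2f, desert PM10 %.2f\n",
    x$harmonics$abundance$r2, x$harmonics$local_pm10$r2,
    x$harmonics$desert_pm10$r2
  ))
  cat(sprintf(
    "  abundance lags desert PM10 by %.1f weeks\n",
    x$lags$abundance_behind_desert
  ))
  cat(sprintf(
    "  events: %d official, %d spikes\n",
    nrow(x$events$official), nrow(x$events$spikes)
  ))
  print(x$sem)
  invisible(x)
}

harmonic_record <- function(fit) {
  list(
    a = fit$a, b = fit$b, c = fit$intercept, amplitude = fit$amplitude,
    phase_rad = fit$phase_rad, peak_time = fit$peak_time,
    r2 = fit$r2, p = fit$pvalue, n = fit$n
  )
}

#' Serializable payload of an analysis report
#'
#' The deterministic, JSON-ready core of a report (no file paths, no
#' timestamps): identical seeds and configurations give byte-identical
#' payloads.
#'
#' @param report an `analysis_report`.
#' @return a named list.
#' @export
report_payload <- function(report) {
  ev_sum <- function(eff) {
    if (is.null(eff)) return(NULL)
    r <- eff$summary[eff$summary$statistic == "ratio_percent", ]
    d <- eff$summary[eff$summary$statistic == "post_drop_percent", ]
    list(
      n_events = eff$n_events,
      ratio_mean = r$mean, ratio_sd = r$sd,
      ratio_min = r$min, ratio_max = r$max,
      post_drop_mean = d$mean,
      p_value = eff$p_value
    )
  }
  modules <- report$network$modules
  focal_mods <- modules$module[match(report$network$focal, modules$node)]
  list(
    seed = report$seed,
    config_hash = report$config_hash,
    abundance_summary = report$abundance$summary,
    monthly = purrr::map(report$monthly, ~ as.list(.x)),
    harmonics = purrr::map(report$harmonics, harmonic_record),
    lags = report$lags,
    spectra = purrr::map(report$spectra, ~ list(
      dominant_period = .x$dominant_period, total_power = .x$total_power
    )),
    network = list(
      n_nodes = nrow(report$network$net$nodes),
      n_edges = nrow(report$network$net$edges),
      kept = report$network$pruned$kept,
      dropped = as.list(report$network$pruned$dropped),
      modules = as.list(modules),
      focal = report$network$focal,
      focal_same_module = length(unique(focal_mods)) == 1
    ),
    events = list(
      n_official = nrow(report$events$official),
      n_spikes = nrow(report$events$spikes),
      official_effect = ev_sum(report$events$effect),
      spike_effect = ev_sum(report$events$spike_effect)
    ),
    sem = list(
      standardized = as.list(report$sem$standardized),
      chi2 = report$sem$chi2, df = report$sem$df, n = report$sem$n,
      indices = report$sem$indices[c("tli", "rmsea", "srmr")]
    )
  )
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (the deterministic payload), CSVs of the
#' abundance and weekly series, the network in SIF/GraphML/CSV form,
#' and the per-event effect table.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    report_payload(report),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  utils::write.csv(report$abundance$series,
    file.path(dir, "abundance_series.csv"),
    row.names = FALSE
  )
  utils::write.csv(report$abundance$weekly,
    file.path(dir, "abundance_weekly.csv"),
    row.names = FALSE
  )
  write_sif(report$network$net, file.path(dir, "network.sif"))
  write_graphml(report$network$net, file.path(dir, "network.graphml"))
  write_edge_csv(report$network$net, file.path(dir, "network_edges.csv"))
  write_graphml(report$network$ego, file.path(dir, "subnetwork.graphml"))
  if (!is.null(report$events$effect)) {
    utils::write.csv(report$events$effect$per_event,
      file.path(dir, "event_effects.csv"),
      row.names = FALSE
    )
  }
  invisible(dir)
}

#' Validate a report payload against the shipped schema
#'
#' Structural validation (required keys and primitive types) of
#' [report_payload()] output against
#' `inst/extdata/report_schema.json`.
#'
#' @param payload a list as from [report_payload()], or an
#'   `analysis_report`.
#' @return `TRUE` invisibly; errors describe the first violation.
#' @export
validate_report <- function(payload) {
  if (inherits(payload, "analysis_report")) {
    payload <- report_payload(payload)
  }
  schema <- jsonlite::read_json(
    system.file("extdata", "report_schema.json", package = "aerodyn")
  )
  check_node <- function(node, sch, path) {
    if (!is.null(sch$required)) {
      miss <- setdiff(unlist(sch$required), names(node))
      if (length(miss)) {
        stop(sprintf(
          "report payload invalid at %s: missing %s",
          path, paste(miss, collapse = ", ")
        ), call. = FALSE)
      }
    }
    if (!is.null(sch$properties)) {
      for (key in names(sch$properties)) {
        if (!key %in% names(node)) next
        sub <- sch$properties[[key]]
        val <- node[[key]]
        type <- sub$type
        ok <- switch(type %||% "any",
          number = is.numeric(val),
          integer = is.numeric(val),
          string = is.character(val),
          boolean = is.logical(val),
          object = is.list(val),
          array = TRUE,
          any = TRUE
        )
        if (!isTRUE(ok)) {
          stop(sprintf(
            "report payload invalid at %s.%s: expected %s",
            path, key, type
          ), call. = FALSE)
        }
        if (identical(type, "object")) {
          check_node(val, sub, paste0(path, ".", key))
        }
      }
    }
    invisible(TRUE)
  }
  check_node(payload, schema, "payload")
  invisible(TRUE)
}
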