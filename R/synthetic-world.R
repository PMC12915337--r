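#' Configuration for the synthetic monitoring world
#'
#' Describes a multi-year airborne monitoring campaign with the
#' statistical structure the analysis pipeline assumes: a local
#' generation (LG) latent and a regional dispersal (RD) latent coupled
#' through correlated AR(1) noise, per-series annual harmonics (desert
#' dust peaking in spring, the local series peaking `lag_weeks` later,
#' meteorology with winter/summer cycles), episodic dust events drawn
#' in the February-May dust season that multiply desert and local PM10
#' and linear bacterial abundance, a spring chloroplast surge in the
#' amplicon compositions, and realistic missingness (a monsoon block
#' plus isolated failures).
#'
#' The latent noise drives the indicators with the loadings, structural
#' paths and covariance of `sem_truth`; the configured `lag_weeks`
#' applies to the annual harmonic of the local series relative to the
#' desert harmonic, while day-to-day dust transport acts with the short
#' `transit_days` delay (long-range transit is a matter of days; the
#' multi-week offset is a property of the seasonal cycles).
#'
#' @param n_years campaign length in years (default 3; at least 2).
#' @param start_date first day.
#' @param sample_cycle_days alternating gaps between consecutive
#'   samples (default `c(3, 4)`: two samples a week, roughly 315 over
#'   three years).
#' @param lag_weeks seasonal delay of the local annual cycle behind the
#'   desert cycle, in weeks (default 4).
#' @param transit_days dust transport delay for day-to-day covariation
#'   and event arrival (default 2).
#' @param ar_phi daily AR(1) coefficient of the latent noise.
#' @param sem_truth standardized SEM truth (default
#'   [sem_truth_airborne()]).
#' @param seasonal list of harmonic settings: `lg_peak`, `rd_peak`
#'   (fraction of year), `met_amp`, `rd_amp`, `la_abundance_amp`,
#'   `la_pm_amp` (z-score amplitudes).
#' @param event_rate expected dust events per year (February-May).
#' @param event_magnitude multiplicative PM10/abundance boost of a
#'   typical event (lognormal median).
#' @param event_magnitude_sdlog lognormal spread of event magnitudes.
#' @param event_duration_days length of each event.
#' @param chloroplast list: `center_doy`, `width_days`, `peak`, `base`
#'   chloroplast read fraction (Gaussian bump over the year), plus
#'   `mito` and `other` fractions.
#' @param abundance_mean,abundance_sd log10 bacterial abundance scale.
#' @param local_pm_mean,local_pm_sd,desert_pm_mean,desert_pm_sd linear
#'   PM10 scales (ug/m3 per z-score unit).
#' @param reads_meanlog,reads_sdlog lognormal sequencing depth.
#' @param qpcr_noise_sd log10-scale qPCR measurement noise.
#' @param missing_frac fraction of samples with random sequencing
#'   failure.
#' @param monsoon_offset_days day-offset window (from `start_date`, in
#'   the first year) of the monsoon sequencing gap.
#' @param pathway list: `pA_base`, `pA_amp` (U-shaped desert pathway,
#'   minimal in July), `pC_base`, `pC_amp` (maritime pathway, peaking
#'   in August), `per_day` trajectory labels per day.
#' @param noise_sd global multiplier on all stochastic components
#'   (0 gives a deterministic world of pure harmonics).
#' @return object of class `world_config`.
#' @export
world_config <- function(n_years = 3,
                         start_date = as.Date("2019-03-01"),
                         sample_cycle_days = c(3, 4),
                         lag_weeks = 4,
                         transit_days = 1,
                         ar_phi = 0.7,
                         sem_truth = sem_truth_airborne(),
                         seasonal = list(),
                         event_rate = 2,
                         event_magnitude = 5,
                         event_magnitude_sdlog = 0.25,
                         event_duration_days = 2,
                         chloroplast = list(),
                         abundance_mean = 4.3,
                         abundance_sd = 0.33,
                         local_pm_mean = 33,
                         local_pm_sd = 11,
                         desert_pm_mean = 42,
                         desert_pm_sd = 14,
                         reads_meanlog = log(18000),
                         reads_sdlog = 0.6,
                         qpcr_noise_sd = 0.1,
                         missing_frac = 0.01,
                         monsoon_offset_days = c(90, 163),
                         pathway = list(),
                         noise_sd = 1) {
  seasonal <- utils::modifyList(
    list(
      lg_peak = 0.04, rd_peak = 0.22,
      met_amp = 0.9, rd_amp = 1.8,
      la_abundance_amp = 1.7, la_pm_amp = 1.6
    ),
    seasonal
  )
  chloroplast <- utils::modifyList(
    list(
      center_doy = 105, width_days = 22, peak = 0.78, base = 0.13,
      mito = 0.01, other = 0.01
    ),
    chloroplast
  )
  pathway <- utils::modifyList(
    list(
      pA_base = 0.32, pA_amp = 1.0, pC_base = 0.25, pC_amp = 1.0,
      per_day = 12
    ),
    pathway
  )
  cfg <- structure(
    list(
      n_years = n_years, start_date = as.Date(start_date),
      sample_cycle_days = sample_cycle_days,
      lag_weeks = lag_weeks, transit_days = transit_days,
      ar_phi = ar_phi, sem_truth = sem_truth, seasonal = seasonal,
      event_rate = event_rate, event_magnitude = event_magnitude,
      event_magnitude_sdlog = event_magnitude_sdlog,
      event_duration_days = event_duration_days,
      chloroplast = chloroplast,
      abundance_mean = abundance_mean, abundance_sd = abundance_sd,
      local_pm_mean = local_pm_mean, local_pm_sd = local_pm_sd,
      desert_pm_mean = desert_pm_mean, desert_pm_sd = desert_pm_sd,
      reads_meanlog = reads_meanlog, reads_sdlog = reads_sdlog,
      qpcr_noise_sd = qpcr_noise_sd,
      missing_frac = missing_frac,
      monsoon_offset_days = monsoon_offset_days,
      pathway = pathway,
      noise_sd = noise_sd
    ),
    class = "world_config"
  )
  validate_world_config(cfg)
  cfg
}

validate_world_config <- function(cfg) {
  stopifnot(
    cfg$lag_weeks >= 0, cfg$transit_days >= 0,
    cfg$noise_sd >= 0, cfg$abundance_sd >= 0,
    cfg$missing_frac >= 0, cfg$missing_frac <= 1,
    cfg$event_rate >= 0, cfg$event_magnitude > 0,
    abs(cfg$ar_phi) < 1,
    cfg$chloroplast$peak >= 0, cfg$chloroplast$peak <= 1,
    cfg$chloroplast$base >= 0, cfg$chloroplast$base <= 1
  )
  invisible(cfg)
}

# bivariate AR(1) noise with stationary unit variances and the given
# stationary cross-correlation, scaled by `scale`
ar1_pair <- function(n, phi, rho, scale) {
  if (scale == 0) return(list(x = numeric(n), y = numeric(n)))
  innov_sd <- sqrt(1 - phi^2)
  e1 <- stats::rnorm(n)
  e2 <- rho * e1 + sqrt(1 - rho^2) * stats::rnorm(n)
  x <- as.numeric(stats::filter(e1 * innov_sd, phi, "recursive"))
  y <- as.numeric(stats::filter(e2 * innov_sd, phi, "recursive"))
  list(x = x * scale, y = y * scale)
}

ar1_one <- function(n, phi, sd) {
  if (sd == 0) return(numeric(n))
  as.numeric(stats::filter(
    stats::rnorm(n, sd = sqrt(1 - phi^2)), phi, "recursive"
  )) * sd
}

lag_series <- function(x, k) {
  if (k <= 0) return(x)
  c(rep(x[1], k), utils::head(x, -k))
}

#' Generate a synthetic monitoring world
#'
#' Realizes a [world_config()] under a seed: daily latents and
#' meteorology, daily local and desert PM10 (with desert AQI), hourly
#' local PM10 for event detection, two-hourly air-mass pathway labels,
#' and the per-sample qPCR / amplicon records, together with the ground
#' truth needed for recovery tests. The same seed always yields an
#' identical world.
#'
#' @param config a [world_config()].
#' @param seed integer seed.
#' @return object of class `synthetic_world`: list with `samples`,
#'   `daily`, `hourly_pm10`, `pathway_labels` tibbles and a `truth`
#'   list (config, realized events, latent series, seasonal phases).
#' @export
generate_world <- function(config = world_config(), seed = 1) {
  validate_world_config(config)
  if (config$n_years < 2) {
    stop("span shorter than 2 full years: annual fitting undefined",
      call. = FALSE
    )
  }
  set.seed(seed)
  cfg <- config
  ns <- cfg$noise_sd
  truth_sem <- cfg$sem_truth
  n_days <- round(cfg$n_years * 365.25)
  dates <- cfg$start_date + seq_len(n_days) - 1
  t_yr <- lubridate::decimal_date(dates)

  # --- latent processes -------------------------------------------------
  g_lg <- truth_sem[["beta_LA~LG"]]
  g_rd <- truth_sem[["beta_LA~RD"]]
  psi <- truth_sem[["psi_LG~RD"]]
  zeta_var <- truth_sem[["zeta_LA"]]
  lat <- ar1_pair(n_days, cfg$ar_phi, psi, ns)
  lg_n <- lat$x
  rd_n <- lat$y
  zeta <- ar1_one(n_days, cfg$ar_phi, sqrt(zeta_var) * ns)

  # --- seasonal harmonics ----------------------------------------------
  sea <- cfg$seasonal
  local_peak <- sea$rd_peak + cfg$lag_weeks / 52.18
  s_winter <- cos(2 * pi * (t_yr - sea$lg_peak))
  s_rd <- cos(2 * pi * (t_yr - sea$rd_peak))
  s_local <- cos(2 * pi * (t_yr - local_peak))

  # --- dust events ------------------------------------------------------
  season_ok <- lubridate::month(dates) %in% 2:5
  n_ev <- if (cfg$event_rate > 0) {
    stats::rpois(1, cfg$event_rate * cfg$n_years)
  } else {
    0L
  }
  desert_factor <- rep(1, n_days)
  local_factor <- rep(1, n_days)
  events <- tibble(
    onset = dates[0], local_start = dates[0], local_end = dates[0],
    magnitude = numeric(), duration_days = integer()
  )
  if (n_ev > 0) {
    onsets <- sort(sample(which(season_ok), n_ev))
    mags <- stats::rlnorm(n_ev,
      meanlog = log(cfg$event_magnitude),
      sdlog = cfg$event_magnitude_sdlog * ifelse(ns > 0, 1, 0)
    )
    dur <- cfg$event_duration_days
    keep <- rep(TRUE, n_ev)
    last_end <- -Inf
    for (j in seq_len(n_ev)) { # drop overlapping onsets
      if (onsets[j] <= last_end + cfg$transit_days + 7) {
        keep[j] <- FALSE
      } else {
        last_end <- onsets[j] + dur - 1
      }
    }
    onsets <- onsets[keep]
    mags <- mags[keep]
    for (j in seq_along(onsets)) {
      d_idx <- onsets[j]:min(onsets[j] + dur - 1, n_days)
      desert_factor[d_idx] <- desert_factor[d_idx] * mags[j]
      l_idx <- (onsets[j] + cfg$transit_days):
        min(onsets[j] + cfg$transit_days + dur - 1, n_days)
      l_idx <- l_idx[l_idx <= n_days]
      local_factor[l_idx] <- local_factor[l_idx] * mags[j]
    }
    events <- tibble(
      onset = dates[onsets],
      local_start = dates[pmin(onsets + cfg$transit_days, n_days)],
      local_end = dates[pmin(onsets + cfg$transit_days + dur - 1, n_days)],
      magnitude = mags,
      duration_days = dur
    )
  }

  # --- pathway labels ---------------------------------------------------
  pw <- cfg$pathway
  p_a <- stats::plogis(stats::qlogis(pw$pA_base) + pw$pA_amp * s_winter)
  p_c <- stats::plogis(
    stats::qlogis(pw$pC_base) + pw$pC_amp * cos(2 * pi * (t_yr - 0.60))
  )
  # dust-laden days arrive along the desert pathway
  dusty <- local_factor > 1 | desert_factor > 1
  p_a[dusty] <- pmax(p_a[dusty], 0.85)
  rest <- pmax(1 - p_a - p_c, 0.01)
  probs <- cbind(A = p_a, B = rest / 3, C = p_c, D = rest / 3, E = rest / 3)
  probs <- probs / rowSums(probs)
  per_day <- pw$per_day
  labels_mat <- vapply(seq_len(n_days), function(i) {
    if (ns > 0) {
      sample(colnames(probs), per_day, replace = TRUE, prob = probs[i, ])
    } else {
      rep(colnames(probs)[which.max(probs[i, ])], per_day)
    }
  }, character(per_day))
  pathway_labels <- tibble(
    datetime = as.POSIXct(rep(dates, each = per_day), tz = "UTC") +
      3600 * rep(seq(0, 23, length.out = per_day), n_days),
    pathway = as.character(labels_mat)
  )
  freq_a_daily <- colMeans(labels_mat == "A")

  # --- local aerosol latent --------------------------------------------
  # The dispersal input to the local aerosol is the same functional the
  # immigration indices measure: desert dust load weighted by the
  # frequency of the desert pathway, accumulated over a trailing
  # window, arriving after the transit time; rescaled to unit variance
  # so the structural coefficients keep their configured meaning.
  rd_influx <- zoo::rollapply(rd_n * freq_a_daily, 4, mean,
    align = "right", partial = TRUE
  )
  if (ns > 0 && stats::sd(rd_influx) > 0) {
    rd_influx <- (rd_influx - mean(rd_influx)) / stats::sd(rd_influx)
  }
  rd_influx <- lag_series(rd_influx, cfg$transit_days)
  la_n <- g_lg * lg_n + g_rd * rd_influx + zeta

  # --- observed daily series -------------------------------------------
  lam <- function(ind) truth_sem[[paste0("lambda_", ind)]]
  th <- function(ind) sqrt(truth_sem[[paste0("theta_", ind)]]) * ns
  idio <- function(ind) stats::rnorm(n_days, sd = th(ind))

  humidity_z <- lam("humidity") * lg_n - sea$met_amp * s_winter +
    idio("humidity")
  pressure_z <- lam("pressure") * lg_n + sea$met_amp * s_winter +
    idio("pressure")
  cloud_z <- lam("cloud") * lg_n - sea$met_amp * s_winter + idio("cloud")
  regions <- c("rd_horqin", "rd_gobi", "rd_taklimakan")
  desert_z <- lapply(regions, function(r) {
    lam(r) * rd_n + sea$rd_amp * s_rd + idio(r)
  })
  names(desert_z) <- regions
  abund_z <- lam("log10_bacterial") * la_n + sea$la_abundance_amp * s_local +
    idio("log10_bacterial")
  localpm_z <- lam("local_pm10") * la_n + sea$la_pm_amp * s_local +
    idio("local_pm10")

  humidity <- pmin(pmax(65 + 12 * humidity_z, 2), 100)
  pressure <- 1013 + 6 * pressure_z
  cloud <- pmin(pmax(5 + 2.2 * cloud_z, 0), 10)
  temperature <- 15 + 9 * cos(2 * pi * (t_yr - 0.60)) +
    ar1_one(n_days, cfg$ar_phi, 1.5 * ns)
  precipitation <- pmax(
    (4 + 5 * cos(2 * pi * (t_yr - 0.55))) *
      stats::rbinom(n_days, 1, 0.3) *
      exp(stats::rnorm(n_days, sd = 0.8 * ns)),
    0
  )
  if (ns == 0) precipitation <- pmax(4 + 5 * cos(2 * pi * (t_yr - 0.55)), 0)

  local_pm10 <- pmax(cfg$local_pm_mean + cfg$local_pm_sd * localpm_z, 1) *
    local_factor
  desert_pm10 <- lapply(desert_z, function(z) {
    pmax(cfg$desert_pm_mean + cfg$desert_pm_sd * z, 1) * desert_factor
  })
  abund_log10 <- cfg$abundance_mean + cfg$abundance_sd * abund_z +
    log10(local_factor)

  bp <- aqi_breakpoints()
  conc_hi <- max(bp$conc_hi)
  desert_aqi <- lapply(desert_pm10, function(x) {
    pm10_to_aqi(pmin(x, conc_hi), bp)
  })

  daily <- tibble(
    date = dates,
    temperature = temperature,
    humidity = humidity,
    pressure = pressure,
    cloud = cloud,
    precipitation = precipitation,
    local_pm10 = local_pm10,
    desert_pm10_horqin = desert_pm10$rd_horqin,
    desert_pm10_gobi = desert_pm10$rd_gobi,
    desert_pm10_taklimakan = desert_pm10$rd_taklimakan,
    desert_aqi_horqin = desert_aqi$rd_horqin,
    desert_aqi_gobi = desert_aqi$rd_gobi,
    desert_aqi_taklimakan = desert_aqi$rd_taklimakan
  )

  # --- hourly local PM10 (event-detection stream) ----------------------
  diurnal <- 1 + 0.10 * sin(2 * pi * (0:23 - 8) / 24)
  hourly_mult <- if (ns > 0) {
    exp(stats::rnorm(n_days * 24, sd = 0.08 * ns))
  } else {
    rep(1, n_days * 24)
  }
  hourly_pm10 <- tibble(
    datetime = as.POSIXct(rep(dates, each = 24), tz = "UTC") +
      3600 * rep(0:23, n_days),
    pm10 = rep(local_pm10, each = 24) *
      (if (ns > 0) rep(diurnal, n_days) else 1) * hourly_mult
  )

  # --- samples ----------------------------------------------------------
  gaps <- rep_len(cfg$sample_cycle_days, ceiling(n_days / min(cfg$sample_cycle_days)))
  offsets <- cumsum(c(1, gaps))
  offsets <- offsets[offsets <= n_days]
  sample_dates <- dates[offsets]
  ni <- length(sample_dates)
  doy <- lubridate::yday(sample_dates)
  chl <- cfg$chloroplast
  bump <- exp(-0.5 * ((doy - chl$center_doy) / chl$width_days)^2)
  p_chl <- chl$base + (chl$peak - chl$base) * bump
  if (ns > 0) {
    p_chl <- stats::plogis(
      stats::qlogis(pmin(pmax(p_chl, 1e-4), 1 - 1e-4)) +
        stats::rnorm(ni, sd = 0.5 * ns)
    )
  }
  p_mito <- chl$mito * (1 - p_chl) / (1 - chl$base)
  p_other <- chl$other * (1 - p_chl) / (1 - chl$base)
  p_bact <- pmax(1 - p_chl - p_mito - p_other, 1e-4)
  depth <- if (ns > 0) {
    round(stats::rlnorm(ni, cfg$reads_meanlog, cfg$reads_sdlog))
  } else {
    rep(round(exp(cfg$reads_meanlog)), ni)
  }
  reads <- matrix(0L, ni, 4)
  for (i in seq_len(ni)) {
    pr <- c(p_bact[i], p_chl[i], p_mito[i], p_other[i])
    pr <- pr / sum(pr)
    reads[i, ] <- if (ns > 0) {
      as.integer(stats::rmultinom(1, depth[i], pr))
    } else {
      as.integer(round(depth[i] * pr))
    }
  }
  ab_lin <- 10^abund_log10[offsets]
  frac_true <- p_bact / (p_bact + p_chl + p_mito + p_other)
  total_copies <- ab_lin / frac_true *
    10^(stats::rnorm(ni, sd = cfg$qpcr_noise_sd * ns))
  monsoon <- offsets >= cfg$monsoon_offset_days[1] &
    offsets <= cfg$monsoon_offset_days[2]
  random_miss <- if (ns > 0) {
    stats::rbinom(ni, 1, cfg$missing_frac) == 1
  } else {
    rep(FALSE, ni)
  }
  has_seq <- !(monsoon | random_miss)
  samples <- tibble(
    date = sample_dates,
    total_copies = total_copies,
    reads_bacterial = ifelse(has_seq, reads[, 1], NA_integer_),
    reads_chloroplast = ifelse(has_seq, reads[, 2], NA_integer_),
    reads_mito = ifelse(has_seq, reads[, 3], NA_integer_),
    reads_other = ifelse(has_seq, reads[, 4], NA_integer_),
    has_sequencing = has_seq
  )

  structure(
    list(
      samples = samples,
      daily = daily,
      hourly_pm10 = hourly_pm10,
      pathway_labels = pathway_labels,
      truth = list(
        config = cfg,
        seed = seed,
        events = events,
        phases = list(
          lg_peak = sea$lg_peak, rd_peak = sea$rd_peak,
          local_peak = local_peak, lag_weeks = cfg$lag_weeks
        ),
        latents = tibble(
          date = dates, lg = lg_n, rd = rd_n, la = la_n,
          abund_log10 = abund_log10
        ),
        sample_missing = tibble(
          date = sample_dates, monsoon = monsoon, random = random_miss
        )
      )
    ),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "Synthetic world: %d samples over %s to %s, %d dust event(s), seed %d\n",
    nrow(x$samples), format(min(x$daily$date)), format(max(x$daily$date)),
    nrow(x$truth$events), x$truth$seed
  ))
  invisible(x)
}

#' Construct an hourly PM10 event episode
#'
#' A plateau at `base * magnitude` lasting `duration` hours followed by
#' an exponential decay back towards the base level; prepended and
#' appended base-level hours make the segment drop-in ready for an
#' hourly PM10 stream.
#'
#' @param base_pm10 background PM10 in ug/m3.
#' @param magnitude multiplicative boost (1 leaves the series at base).
#' @param duration plateau length in hours (at least 1).
#' @param decay_hours length of the decay tail (default 6).
#' @return numeric vector of hourly PM10 values.
#' @export
generate_event_episode <- function(base_pm10, magnitude, duration,
                                   decay_hours = 6) {
  stopifnot(duration >= 1, magnitude > 0, base_pm10 >= 0)
  peak <- base_pm10 * magnitude
  decay <- base_pm10 + (peak - base_pm10) * exp(-(seq_len(decay_hours)))
  c(rep(base_pm10, 2), rep(peak, duration), decay)
}

#' Write a synthetic world to disk
#'
#' CSV tables for samples, daily series, hourly PM10 and pathway
#' labels; the latent series as CSV; configuration, phases and realized
#' events as YAML, with the seed recorded.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(world$samples, file.path(dir, "samples.csv"),
    row.names = FALSE
  )
  utils::write.csv(world$daily, file.path(dir, "daily.csv"),
    row.names = FALSE
  )
  utils::write.csv(world$hourly_pm10, file.path(dir, "hourly_pm10.csv"),
    row.names = FALSE
  )
  utils::write.csv(world$pathway_labels, file.path(dir, "pathway_labels.csv"),
    row.names = FALSE
  )
  utils::write.csv(world$truth$latents, file.path(dir, "truth_latents.csv"),
    row.names = FALSE
  )
  cfg <- world$truth$config
  cfg$start_date <- format(cfg$start_date)
  cfg$sem_truth <- as.list(cfg$sem_truth)
  yaml::write_yaml(
    list(
      seed = world$truth$seed,
      config = unclass(cfg),
      phases = world$truth$phases,
      events = lapply(seq_len(nrow(world$truth$events)), function(i) {
        e <- world$truth$events[i, ]
        list(
          onset = format(e$onset), local_start = format(e$local_start),
          local_end = format(e$local_end), magnitude = e$magnitude,
          duration_days = e$duration_days
        )
      })
    ),
    file.path(dir, "truth.yaml")
  )
  invisible(dir)
}
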