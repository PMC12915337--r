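#' Specify a latent-variable structural equation model
#'
#' Defines a measurement model (each indicator loads on exactly one
#' latent), structural regressions among latents, and free latent
#' covariances, in the RAM formulation. Identification fixes every
#' exogenous latent variance to 1 and every endogenous latent
#' disturbance variance to 1, so raw estimates are close to the
#' standardized solution and no marker indicator is singled out.
#'
#' @param loadings data frame with columns `indicator`, `latent`.
#' @param structural data frame with columns `from`, `to` (latent
#'   regressions `to ~ from`).
#' @param lv_cov data frame with columns `lv1`, `lv2`: free covariances
#'   among exogenous latents.
#' @param first_sign optional named numeric (`+1`/`-1`) per latent: the
#'   expected sign of the latent's first indicator loading, used to
#'   resolve the sign indeterminacy after fitting.
#' @return object of class `sem_spec`.
#' @export
sem_spec <- function(loadings, structural = NULL, lv_cov = NULL,
                     first_sign = NULL) {
  loadings <- as_tibble(loadings)
  stopifnot(all(c("indicator", "latent") %in% names(loadings)))
  if (anyDuplicated(loadings$indicator)) {
    stop("every indicator must load on exactly one latent", call. = FALSE)
  }
  latents <- unique(loadings$latent)
  structural <- if (is.null(structural)) {
    tibble(from = character(), to = character())
  } else {
    as_tibble(structural)
  }
  lv_cov <- if (is.null(lv_cov)) {
    tibble(lv1 = character(), lv2 = character())
  } else {
    as_tibble(lv_cov)
  }
  endo <- unique(structural$to)
  spec <- structure(
    list(
      loadings = loadings,
      structural = structural,
      lv_cov = lv_cov,
      latents = latents,
      endogenous = endo,
      exogenous = setdiff(latents, endo),
      observed = loadings$indicator,
      first_sign = first_sign
    ),
    class = "sem_spec"
  )
  spec
}

#' @export
print.sem_spec <- function(x, ...) {
  cat(sprintf(
    "SEM spec: %d observed, %d latents (%s), %d free parameters, df = %d\n",
    length(x$observed), length(x$latents),
    paste(x$latents, collapse = ", "),
    length(sem_par_names(x)), sem_df(x)
  ))
  invisible(x)
}

# free-parameter layout: loadings, structural paths, latent covariances,
# residual variances (in this order, names fixed)
sem_par_names <- function(spec) {
  c(
    paste0("lambda_", spec$loadings$indicator),
    if (nrow(spec$structural)) {
      paste0("beta_", spec$structural$to, "~", spec$structural$from)
    },
    if (nrow(spec$lv_cov)) {
      paste0("psi_", spec$lv_cov$lv1, "~", spec$lv_cov$lv2)
    },
    paste0("theta_", spec$loadings$indicator)
  )
}

sem_df <- function(spec) {
  p <- length(spec$observed)
  p * (p + 1) / 2 - length(sem_par_names(spec))
}

#' Latent-model spec for airborne bacterial dynamics
#'
#' The three-latent measurement and structural model used throughout
#' the package: local generation (LG) indicated by relative humidity
#' (negative), atmospheric pressure and cloud cover; regional dispersal
#' (RD) indicated by the three desert-region dust-immigration indices;
#' and the local aerosol outcome (LA) indicated by log10 bacterial
#' abundance and local PM10, with structural paths `LA ~ LG + RD` and a
#' free LG-RD covariance.
#'
#' @return a `sem_spec`.
#' @export
airborne_sem_spec <- function() {
  sem_spec(
    loadings = tibble(
      indicator = c(
        "humidity", "pressure", "cloud",
        "rd_horqin", "rd_gobi", "rd_taklimakan",
        "log10_bacterial", "local_pm10"
      ),
      latent = c(rep("LG", 3), rep("RD", 3), rep("LA", 2))
    ),
    structural = tibble(from = c("LG", "RD"), to = c("LA", "LA")),
    lv_cov = tibble(lv1 = "LG", lv2 = "RD"),
    first_sign = c(LG = -1, RD = 1, LA = 1)
  )
}

#' Reference standardized parameter values for the airborne model
#'
#' A fully standardized parameter set for [airborne_sem_spec()] (all
#' latent and observed variances 1): measurement loadings
#' `(-0.99, 0.59, -0.55)` for LG, `(0.92, 0.93, 0.95)` for RD,
#' `(0.45, 0.43)` for LA; structural paths `LA ~ 0.51 LG + 0.35 RD`;
#' LG-RD covariance 0.64. Residual variances are `1 - loading^2` and
#' the LA disturbance is set so LA has unit variance. Used as the
#' generator's ground truth and in parameter-recovery simulations.
#'
#' @return named numeric parameter vector (includes `zeta_LA`, the
#'   disturbance variance, used for simulation; ignored by fitting,
#'   which fixes the disturbance scale for identification).
#' @export
sem_truth_airborne <- function() {
  lam <- c(
    humidity = -0.99, pressure = 0.59, cloud = -0.55,
    rd_horqin = 0.92, rd_gobi = 0.93, rd_taklimakan = 0.95,
    log10_bacterial = 0.45, local_pm10 = 0.43
  )
  g_lg <- 0.51
  g_rd <- 0.35
  psi <- 0.64
  zeta <- 1 - (g_lg^2 + g_rd^2 + 2 * g_lg * g_rd * psi)
  c(
    stats::setNames(lam, paste0("lambda_", names(lam))),
    "beta_LA~LG" = g_lg, "beta_LA~RD" = g_rd,
    "psi_LG~RD" = psi,
    stats::setNames(1 - lam^2, paste0("theta_", names(lam))),
    zeta_LA = zeta
  )
}

# compile the spec into a fast theta -> Sigma evaluator with
# precomputed matrix indices (used in the optimizer's inner loop)
sem_compile <- function(spec) {
  obs <- spec$observed
  lat <- spec$latents
  vars <- c(obs, lat)
  k <- length(vars)
  p <- length(obs)
  pos <- function(v) match(v, vars)
  par_names <- sem_par_names(spec)
  a_idx <- rbind(
    cbind(pos(spec$loadings$indicator), pos(spec$loadings$latent)),
    if (nrow(spec$structural)) {
      cbind(pos(spec$structural$to), pos(spec$structural$from))
    }
  )
  a_par <- match(
    c(
      paste0("lambda_", spec$loadings$indicator),
      if (nrow(spec$structural)) {
        paste0("beta_", spec$structural$to, "~", spec$structural$from)
      }
    ),
    par_names
  )
  th_par <- match(paste0("theta_", obs), par_names)
  psi_idx <- if (nrow(spec$lv_cov)) {
    cbind(pos(spec$lv_cov$lv1), pos(spec$lv_cov$lv2))
  }
  psi_par <- if (nrow(spec$lv_cov)) {
    match(paste0("psi_", spec$lv_cov$lv1, "~", spec$lv_cov$lv2), par_names)
  }
  s_base <- matrix(0, k, k)
  for (l in c(spec$exogenous, spec$endogenous)) {
    s_base[pos(l), pos(l)] <- 1 # fixed latent (disturbance) variances
  }
  imat <- diag(k)
  obs_idx <- seq_len(p)
  function(theta) {
    a_mat <- matrix(0, k, k)
    a_mat[a_idx] <- theta[a_par]
    s_mat <- s_base
    diag(s_mat)[obs_idx] <- theta[th_par]
    if (!is.null(psi_idx)) {
      s_mat[psi_idx] <- theta[psi_par]
      s_mat[psi_idx[, 2:1, drop = FALSE]] <- theta[psi_par]
    }
    inv <- solve(imat - a_mat)
    total <- inv %*% s_mat %*% t(inv)
    total[obs_idx, obs_idx, drop = FALSE]
  }
}

# RAM matrices for a parameter vector. Variable order: observed (spec
# order) then latents. Returns list(A, S, F, vars).
sem_ram <- function(params, spec) {
  obs <- spec$observed
  lat <- spec$latents
  vars <- c(obs, lat)
  k <- length(vars)
  p <- length(obs)
  a_mat <- matrix(0, k, k, dimnames = list(vars, vars))
  s_mat <- matrix(0, k, k, dimnames = list(vars, vars))
  for (i in seq_len(nrow(spec$loadings))) {
    ind <- spec$loadings$indicator[i]
    a_mat[ind, spec$loadings$latent[i]] <- params[[paste0("lambda_", ind)]]
  }
  if (nrow(spec$structural)) {
    for (i in seq_len(nrow(spec$structural))) {
      fr <- spec$structural$from[i]
      to <- spec$structural$to[i]
      a_mat[to, fr] <- params[[paste0("beta_", to, "~", fr)]]
    }
  }
  diag(s_mat)[obs] <- params[paste0("theta_", obs)]
  for (l in spec$exogenous) s_mat[l, l] <- 1
  for (l in spec$endogenous) {
    z <- paste0("zeta_", l)
    s_mat[l, l] <- if (z %in% names(params)) params[[z]] else 1
  }
  if (nrow(spec$lv_cov)) {
    for (i in seq_len(nrow(spec$lv_cov))) {
      a <- spec$lv_cov$lv1[i]
      b <- spec$lv_cov$lv2[i]
      s_mat[a, b] <- s_mat[b, a] <- params[[paste0("psi_", a, "~", b)]]
    }
  }
  f_mat <- diag(k)[seq_len(p), , drop = FALSE]
  dimnames(f_mat) <- list(obs, vars)
  list(A = a_mat, S = s_mat, F = f_mat, vars = vars)
}

#' Model-implied covariance matrix
#'
#' RAM formulation: `Sigma(theta) = F (I - A)^-1 S (I - A)^-T F^T`,
#' where `A` holds loadings and structural paths, `S` holds exogenous
#' (co)variances and residual variances, and `F` selects the observed
#' variables.
#'
#' @param params named parameter vector (layout as produced by the
#'   fitter; disturbance variances may be supplied as `zeta_<latent>`,
#'   otherwise they are fixed at 1).
#' @param spec a `sem_spec`.
#' @return implied covariance matrix of the observed variables.
#' @export
implied_covariance <- function(params, spec) {
  ram <- sem_ram(params, spec)
  k <- nrow(ram$A)
  imat <- diag(k)
  inv <- tryCatch(solve(imat - ram$A), error = function(e) {
    stop("(I - A) is singular", call. = FALSE)
  })
  total <- inv %*% ram$S %*% t(inv)
  sigma <- ram$F %*% total %*% t(ram$F)
  dimnames(sigma) <- list(spec$observed, spec$observed)
  sigma
}

#' Maximum-likelihood discrepancy between covariance matrices
#'
#' `F_ML = ln|Sigma| + tr(S Sigma^-1) - ln|S| - p`, the discrepancy
#' minimized in covariance-structure ML estimation; zero iff
#' `Sigma = S`, strictly positive otherwise.
#'
#' @param S sample covariance matrix (symmetric positive definite).
#' @param Sigma model-implied covariance, same order.
#' @return non-negative scalar.
#' @export
fml <- function(S, Sigma) {
  p <- nrow(S)
  stopifnot(nrow(Sigma) == p, ncol(S) == p, ncol(Sigma) == p)
  ch_s <- tryCatch(chol(S), error = function(e) {
    stop("S is not positive definite", call. = FALSE)
  })
  ch_sig <- tryCatch(chol(Sigma), error = function(e) {
    stop("Sigma is not positive definite", call. = FALSE)
  })
  logdet_s <- 2 * sum(log(diag(ch_s)))
  logdet_sig <- 2 * sum(log(diag(ch_sig)))
  tr <- sum(diag(chol2inv(ch_sig) %*% S))
  logdet_sig + tr - logdet_s - p
}

# quietly returns Inf-like penalty for non-PD Sigma during optimization
fml_safe <- function(S, Sigma) {
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  val <- 2 * sum(log(diag(ch))) + sum(diag(chol2inv(ch) %*% S))
  if (!is.finite(val)) return(1e10)
  val
}

sem_start_values <- function(spec, S) {
  obs <- spec$observed
  start <- stats::setNames(
    numeric(length(sem_par_names(spec))), sem_par_names(spec)
  )
  signs <- sem_start_signs(spec, S)
  start[paste0("lambda_", obs)] <- 0.5 * sqrt(diag(S)[obs]) * signs
  if (nrow(spec$structural)) {
    start[paste0("beta_", spec$structural$to, "~", spec$structural$from)] <- 0.3
  }
  if (nrow(spec$lv_cov)) {
    start[paste0("psi_", spec$lv_cov$lv1, "~", spec$lv_cov$lv2)] <- 0.2
  }
  start[paste0("theta_", obs)] <- diag(S)[obs] / 2
  start
}

# heuristic loading signs: each indicator's sign is the sign of its
# covariance with the latent's first indicator, anchored by first_sign
sem_start_signs <- function(spec, S) {
  obs <- spec$observed
  signs <- stats::setNames(rep(1, length(obs)), obs)
  for (l in spec$latents) {
    ind <- spec$loadings$indicator[spec$loadings$latent == l]
    anchor <- ind[1]
    anchor_sign <- 1
    if (!is.null(spec$first_sign) && l %in% names(spec$first_sign)) {
      anchor_sign <- spec$first_sign[[l]]
    }
    s <- sign(S[ind, anchor])
    s[s == 0] <- 1
    signs[ind] <- s * anchor_sign
  }
  signs
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes the ML discrepancy between the sample covariance and the
#' model-implied covariance with L-BFGS-B, from documented start values
#' plus jittered restarts, keeping the best converged solution. The
#' model chi-square is `(n - 1) * F_min`. Residual variances are
#' box-constrained below at `1e-6`; a solution on that bound (Heywood
#' case) triggers a warning. The standardized solution and TLI / RMSEA /
#' SRMR fit indices are attached.
#'
#' @param data data frame containing the spec's indicator columns
#'   (rows with missing values dropped listwise), or `NULL` if `S` is
#'   given.
#' @param spec a `sem_spec`.
#' @param S sample covariance matrix (used with `n` when `data` is
#'   `NULL`).
#' @param n number of observations behind `S`.
#' @param start optional named start vector (replaces the documented
#'   defaults; restarts still jitter around it).
#' @param n_starts number of optimizer starts (default 5: the default
#'   start plus 4 jittered ones).
#' @param jitter_sd standard deviation of the Gaussian jitter applied
#'   to restarts (default 0.1).
#' @param seed seed controlling the jitter (default 1, so fits are
#'   reproducible by default).
#' @param maxit maximum L-BFGS-B iterations per start.
#' @return object of class `sem_fit`: estimates, implied covariance,
#'   `fml`, `chi2`, `df`, `n`, convergence record, `standardized`
#'   tibble and `indices` list.
#' @export
fit_sem <- function(data = NULL, spec, S = NULL, n = NULL, start = NULL,
                    n_starts = 5, jitter_sd = 0.1, seed = 1, maxit = 500) {
  stopifnot(inherits(spec, "sem_spec"))
  obs <- spec$observed
  if (!is.null(data)) {
    miss <- setdiff(obs, names(data))
    if (length(miss)) {
      stop("data lacks indicator(s): ", paste(miss, collapse = ", "),
        call. = FALSE
      )
    }
    x <- as.matrix(as.data.frame(data)[, obs])
    x <- x[stats::complete.cases(x), , drop = FALSE]
    n <- nrow(x)
    S <- stats::cov(x)
  }
  if (is.null(S) || is.null(n)) {
    stop("supply either `data` or both `S` and `n`", call. = FALSE)
  }
  S <- as.matrix(S)[obs, obs]
  if (n <= length(obs)) {
    stop("need more observations than observed variables", call. = FALSE)
  }
  if (sem_df(spec) < 0) {
    stop("model has negative degrees of freedom", call. = FALSE)
  }
  # optimize in the correlation metric: well-conditioned, and exactly
  # invariant to rescaling any observed column (ML chi-square is too)
  d_sd <- sqrt(diag(S))
  s_std <- S / outer(d_sd, d_sd)
  par_names <- sem_par_names(spec)
  lower <- stats::setNames(rep(-Inf, length(par_names)), par_names)
  upper <- stats::setNames(rep(Inf, length(par_names)), par_names)
  lower[grepl("^theta_", par_names)] <- 1e-6
  lower[grepl("^psi_", par_names)] <- -0.999
  upper[grepl("^psi_", par_names)] <- 0.999
  # map a parameter vector between the raw and correlation metrics
  rescale_pars <- function(theta, sds) {
    theta[paste0("lambda_", obs)] <- theta[paste0("lambda_", obs)] * sds
    theta[paste0("theta_", obs)] <- theta[paste0("theta_", obs)] * sds^2
    theta
  }
  base_start <- if (is.null(start)) {
    sem_start_values(spec, s_std)
  } else {
    rescale_pars(start[par_names], 1 / d_sd)
  }
  sigma_of <- sem_compile(spec)
  objective <- function(theta) fml_safe(s_std, sigma_of(theta))
  runs <- vector("list", n_starts)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(n_starts)) {
    st <- base_start
    if (i > 1) {
      st <- st + stats::rnorm(length(st), sd = jitter_sd)
      st <- pmin(pmax(st, lower + 1e-4), upper - 1e-4)
    }
    fit <- tryCatch(
      stats::optim(st, objective,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(maxit = maxit, factr = 1e7)
      ),
      error = function(e) NULL
    )
    runs[[i]] <- fit
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  ok <- !vapply(runs, is.null, logical(1))
  if (!any(ok)) {
    stop("SEM did not converge in any start", call. = FALSE)
  }
  values <- vapply(runs, function(r) if (is.null(r)) Inf else r$value, 0)
  best <- runs[[which.min(values)]]
  if (best$value >= 1e9) {
    stop("SEM did not reach a positive-definite solution; starts: ",
      paste(signif(values, 4), collapse = ", "),
      call. = FALSE
    )
  }
  est <- best$par
  names(est) <- par_names
  est <- rescale_pars(est, d_sd) # back to the raw metric
  # Heywood check: residual variance pinned at the lower bound
  heywood <- par_names[grepl("^theta_", par_names) & est <= 1e-6 + 1e-10]
  if (length(heywood)) {
    warning(
      "Heywood case: residual variance floored at 1e-6 for ",
      paste(sub("^theta_", "", heywood), collapse = ", "),
      call. = FALSE
    )
  }
  est <- sem_fix_signs(est, spec)
  sigma <- implied_covariance(est, spec)
  f_min <- fml(S, sigma)
  fit <- structure(
    list(
      spec = spec,
      estimates = est,
      S = S,
      n = n,
      Sigma = sigma,
      fml = f_min,
      chi2 = (n - 1) * f_min,
      df = sem_df(spec),
      convergence = list(
        codes = vapply(runs, function(r) {
          if (is.null(r)) NA_integer_ else as.integer(r$convergence)
        }, 0L),
        values = values,
        best_start = which.min(values),
        counts = best$counts
      ),
      heywood = sub("^theta_", "", heywood)
    ),
    class = "sem_fit"
  )
  fit <- standardize(fit)
  fit$indices <- fit_indices(fit)
  fit
}

# resolve sign indeterminacy: flip each latent so its first indicator's
# loading carries the expected sign (implied covariance is unchanged)
sem_fix_signs <- function(est, spec) {
  if (is.null(spec$first_sign)) return(est)
  for (l in names(spec$first_sign)) {
    if (!l %in% spec$latents) next
    ind <- spec$loadings$indicator[spec$loadings$latent == l]
    lam1 <- est[[paste0("lambda_", ind[1])]]
    if (sign(lam1) == sign(spec$first_sign[[l]]) || lam1 == 0) next
    est[paste0("lambda_", ind)] <- -est[paste0("lambda_", ind)]
    if (nrow(spec$structural)) {
      hit <- spec$structural$from == l | spec$structural$to == l
      nm <- paste0(
        "beta_", spec$structural$to[hit], "~", spec$structural$from[hit]
      )
      est[nm] <- -est[nm]
    }
    if (nrow(spec$lv_cov)) {
      hit <- xor(spec$lv_cov$lv1 == l, spec$lv_cov$lv2 == l)
      nm <- paste0("psi_", spec$lv_cov$lv1[hit], "~", spec$lv_cov$lv2[hit])
      est[nm] <- -est[nm]
    }
  }
  est
}

#' Standardized SEM solution
#'
#' Rescales a fitted model so every latent and observed variable has
#' unit variance, reporting standardized loadings, structural paths,
#' latent covariances (correlations) and per-indicator explained
#' variance (the squared standardized loading, for this single-loading
#' structure). Re-standardizing an already standardized fit is a
#' no-op.
#'
#' @param fit a `sem_fit`.
#' @return the fit with its `standardized` tibble (columns `term`,
#'   `op`, `estimate`) refreshed.
#' @export
standardize <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  spec <- fit$spec
  ram <- sem_ram(fit$estimates, spec)
  k <- nrow(ram$A)
  inv <- solve(diag(k) - ram$A)
  total <- inv %*% ram$S %*% t(inv) # covariance of observed + latents
  sds <- sqrt(diag(total))
  rows <- list()
  for (i in seq_len(nrow(spec$loadings))) {
    ind <- spec$loadings$indicator[i]
    l <- spec$loadings$latent[i]
    lam_std <- fit$estimates[[paste0("lambda_", ind)]] * sds[l] / sds[ind]
    rows[[length(rows) + 1]] <- tibble(
      term = paste0(ind, " =~ ", l), op = "loading", estimate = lam_std
    )
    rows[[length(rows) + 1]] <- tibble(
      term = paste0(ind, " r2"), op = "explained_variance",
      estimate = lam_std^2
    )
  }
  if (nrow(spec$structural)) {
    for (i in seq_len(nrow(spec$structural))) {
      fr <- spec$structural$from[i]
      to <- spec$structural$to[i]
      b_std <- fit$estimates[[paste0("beta_", to, "~", fr)]] *
        sds[fr] / sds[to]
      rows[[length(rows) + 1]] <- tibble(
        term = paste0(to, " ~ ", fr), op = "path", estimate = b_std
      )
    }
  }
  if (nrow(spec$lv_cov)) {
    for (i in seq_len(nrow(spec$lv_cov))) {
      a <- spec$lv_cov$lv1[i]
      b <- spec$lv_cov$lv2[i]
      rows[[length(rows) + 1]] <- tibble(
        term = paste0(a, " ~~ ", b), op = "lv_covariance",
        estimate = total[a, b] / (sds[a] * sds[b])
      )
    }
  }
  fit$standardized <- bind_rows(rows)
  fit$latent_sds <- sds
  fit
}

#' SEM fit indices
#'
#' Computes the Tucker-Lewis index against the independence baseline
#' (diagonal implied covariance, its ML solution being `diag(S)`), the
#' root mean square error of approximation with the `(n - 1)`
#' denominator, and the standardized root mean square residual over the
#' unique elements of `S - Sigma` in correlation metric (diagonal
#' included).
#'
#' @param fit a `sem_fit`.
#' @return list with `tli`, `rmsea`, `srmr`, plus the baseline
#'   chi-square and degrees of freedom.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  S <- fit$S
  p <- nrow(S)
  n <- fit$n
  sigma_b <- diag(diag(S))
  f_b <- fml(S, sigma_b)
  chi2_b <- (n - 1) * f_b
  df_b <- p * (p - 1) / 2
  chi2_m <- fit$chi2
  df_m <- fit$df
  tli <- if (df_m > 0) {
    ((chi2_b / df_b) - (chi2_m / df_m)) / ((chi2_b / df_b) - 1)
  } else {
    NA_real_
  }
  rmsea <- if (df_m > 0) {
    sqrt(max(chi2_m - df_m, 0) / (df_m * (n - 1)))
  } else {
    NA_real_
  }
  d <- diag(S)
  scale <- sqrt(outer(d, d))
  resid <- (S - fit$Sigma) / scale
  srmr <- sqrt(mean(resid[upper.tri(resid, diag = TRUE)]^2))
  list(
    tli = tli, rmsea = rmsea, srmr = srmr,
    chi2_baseline = chi2_b, df_baseline = df_b
  )
}

#' Simulate indicator data from a SEM
#'
#' Draws multivariate-normal indicator data from the model-implied
#' covariance of a parameter vector (supply `zeta_<latent>` entries to
#' control endogenous disturbance variances, e.g. a fully standardized
#' truth).
#'
#' @param spec a `sem_spec`.
#' @param params named truth vector (default [sem_truth_airborne()]
#'   when the spec is the airborne model).
#' @param n number of rows.
#' @param seed optional seed.
#' @return tibble with one column per observed indicator.
#' @export
simulate_sem <- function(spec, params, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sigma <- implied_covariance(params, spec)
  x <- MASS::mvrnorm(n, mu = rep(0, nrow(sigma)), Sigma = sigma)
  colnames(x) <- spec$observed
  as_tibble(as.data.frame(x))
}

#' @export
print.sem_fit <- function(x, ...) {
  cat(sprintf(
    "SEM fit: chi2(%d) = %.2f (n = %d), F_ML = %.4f\n",
    x$df, x$chi2, x$n, x$fml
  ))
  idx <- x$indices
  if (!is.null(idx)) {
    cat(sprintf(
      "  TLI = %.3f, RMSEA = %.3f, SRMR = %.3f\n",
      idx$tli, idx$rmsea, idx$srmr
    ))
  }
  paths <- x$standardized[x$standardized$op == "path", ]
  if (nrow(paths)) {
    cat("  standardized paths:\n")
    for (i in seq_len(nrow(paths))) {
      cat(sprintf("    %s = %.3f\n", paths$term[i], paths$estimate[i]))
    }
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted SEM
#'
#' @param x a `sem_fit`.
#' @param ... unused.
#' @return tibble with `term`, `op`, `estimate` (raw) and
#'   `std_estimate`.
#' @export
tidy.sem_fit <- function(x, ...) {
  spec <- x$spec
  raw <- list()
  for (i in seq_len(nrow(spec$loadings))) {
    ind <- spec$loadings$indicator[i]
    raw[[paste0(ind, " =~ ", spec$loadings$latent[i])]] <-
      x$estimates[[paste0("lambda_", ind)]]
  }
  if (nrow(spec$structural)) {
    for (i in seq_len(nrow(spec$structural))) {
      fr <- spec$structural$from[i]
      to <- spec$structural$to[i]
      raw[[paste0(to, " ~ ", fr)]] <- x$estimates[[paste0("beta_", to, "~", fr)]]
    }
  }
  if (nrow(spec$lv_cov)) {
    for (i in seq_len(nrow(spec$lv_cov))) {
      a <- spec$lv_cov$lv1[i]
      b <- spec$lv_cov$lv2[i]
      raw[[paste0(a, " ~~ ", b)]] <- x$estimates[[paste0("psi_", a, "~", b)]]
    }
  }
  raw_tbl <- tibble(term = names(raw), estimate = unlist(raw))
  std <- x$standardized[x$standardized$op != "explained_variance", ]
  std <- dplyr::rename(std, std_estimate = estimate)
  left_join(raw_tbl, std[, c("term", "op", "std_estimate")], by = "term") %>%
    select(term, op, estimate, std_estimate)
}

#' Glance at a fitted SEM
#'
#' @param x a `sem_fit`.
#' @param ... unused.
#' @return one-row tibble with `chi2`, `df`, `n`, `fml`, `tli`,
#'   `rmsea`, `srmr`, `converged`.
#' @export
glance.sem_fit <- function(x, ...) {
  tibble(
    chi2 = x$chi2, df = x$df, n = x$n, fml = x$fml,
    tli = x$indices$tli, rmsea = x$indices$rmsea, srmr = x$indices$srmr,
    converged = any(x$convergence$codes == 0, na.rm = TRUE)
  )
}
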