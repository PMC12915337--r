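# one-factor toy spec used in several blocks
toy_spec <- function(p = 3) {
  sem_spec(loadings = tibble::tibble(
    indicator = paste0("x", seq_len(p)), latent = "F"
  ))
}

toy_params <- function(lam, theta) {
  c(
    stats::setNames(lam, paste0("lambda_x", seq_along(lam))),
    stats::setNames(theta, paste0("theta_x", seq_along(theta)))
  )
}

test_that("implied covariance matches the hand-expanded factor structure", {
  spec <- toy_spec(3)
  lam <- c(0.8, 0.6, -0.4)
  th <- c(0.36, 0.64, 0.84)
  sigma <- implied_covariance(toy_params(lam, th), spec)
  # hand expansion: sigma_ij = lambda_i lambda_j phi + delta_ij theta_i
  for (i in 1:3) {
    for (j in 1:3) {
      expect_close(sigma[i, j], lam[i] * lam[j] + (i == j) * th[i], 1e-12)
    }
  }
  # all loadings zero -> diagonal of residual variances
  sigma0 <- implied_covariance(toy_params(c(0, 0, 0), th), spec)
  expect_equal(unname(sigma0), diag(th))
  # one latent, one indicator, loading 1, zero residual -> latent variance
  s1 <- implied_covariance(toy_params(1, 1e-12), toy_spec(1))
  expect_close(s1[1, 1], 1, 1e-9)
})

test_that("F_ML is zero at equality, positive otherwise, and matches 2x2 closed form", {
  S <- matrix(c(2, 0.5, 0.5, 1), 2, 2)
  expect_equal(fml(S, S), 0)
  set.seed(4)
  for (i in 1:5) {
    a <- matrix(rnorm(9), 3)
    Sp <- crossprod(a) + diag(3)
    b <- matrix(rnorm(9), 3)
    Sg <- crossprod(b) + diag(3)
    expect_gt(fml(Sp, Sg), 0)
  }
  # closed-form expansion for 2x2 matrices
  Sg2 <- matrix(c(1.5, 0.2, 0.2, 0.9), 2, 2)
  hand <- log(det(Sg2)) + sum(diag(S %*% solve(Sg2))) - log(det(S)) - 2
  expect_close(fml(S, Sg2), hand, 1e-12)
  expect_error(fml(matrix(c(1, 2, 2, 1), 2), diag(2)), "positive definite")
})

test_that("saturated single-factor toy recovers the closed-form loadings", {
  # equal loadings lambda: off-diagonals are lambda^2, so the analytic
  # solution is lambda = sqrt(common covariance)
  lam <- 0.7
  S <- matrix(lam^2, 3, 3)
  diag(S) <- 1
  dimnames(S) <- list(paste0("x", 1:3), paste0("x", 1:3))
  fit <- fit_sem(S = S, n = 500, spec = toy_spec(3))
  expect_lt(fit$fml, 1e-8) # saturated: perfect fit
  expect_true(all(abs(abs(fit$estimates[1:3]) - lam) < 1e-4))
})

test_that("parameters of the airborne model are recovered from simulated data", {
  spec <- airborne_sem_spec()
  truth <- sem_truth_airborne()
  d <- simulate_sem(spec, truth, n = 10000, seed = 101)
  fit <- fit_sem(d, spec)
  std <- fit$standardized
  ref <- c(
    "humidity =~ LG" = -0.99, "pressure =~ LG" = 0.59, "cloud =~ LG" = -0.55,
    "rd_horqin =~ RD" = 0.92, "rd_gobi =~ RD" = 0.93,
    "rd_taklimakan =~ RD" = 0.95,
    "log10_bacterial =~ LA" = 0.45, "local_pm10 =~ LA" = 0.43,
    "LA ~ LG" = 0.51, "LA ~ RD" = 0.35, "LG ~~ RD" = 0.64
  )
  for (term in names(ref)) {
    est <- std$estimate[std$term == term]
    expect_close(est, ref[[term]], 0.05)
  }
  # explained variance equals the squared standardized loading
  lam_h <- std$estimate[std$term == "humidity =~ LG"]
  expect_close(std$estimate[std$term == "humidity r2"], lam_h^2, 1e-12)
})

test_that("standardization is idempotent and sign-flip invariant", {
  spec <- airborne_sem_spec()
  truth <- sem_truth_airborne()
  d <- simulate_sem(spec, truth, n = 2000, seed = 55)
  fit <- fit_sem(d, spec)
  again <- standardize(fit)
  expect_equal(again$standardized, fit$standardized)
  # flipping a latent's sign leaves |standardized| and the fit identical
  flipped <- fit$estimates
  lg_ind <- paste0("lambda_", c("humidity", "pressure", "cloud"))
  flipped[lg_ind] <- -flipped[lg_ind]
  flipped["beta_LA~LG"] <- -flipped["beta_LA~LG"]
  flipped["psi_LG~RD"] <- -flipped["psi_LG~RD"]
  expect_close(
    fml(fit$S, implied_covariance(flipped, spec)),
    fml(fit$S, fit$Sigma), 1e-10
  )
})

test_that("fit is invariant to rescaling observed columns", {
  spec <- airborne_sem_spec()
  d <- simulate_sem(spec, sem_truth_airborne(), n = 3000, seed = 77)
  fit1 <- fit_sem(d, spec)
  d2 <- d
  d2$local_pm10 <- d2$local_pm10 * 13.7
  d2$humidity <- d2$humidity * 0.2
  fit2 <- fit_sem(d2, spec)
  expect_close(fit2$chi2, fit1$chi2, 1e-3 * max(1, fit1$chi2))
  expect_close(fit2$indices$srmr, fit1$indices$srmr, 1e-6)
  merged <- dplyr::left_join(
    fit1$standardized, fit2$standardized,
    by = c("term", "op"), suffix = c("_1", "_2")
  )
  expect_lt(max(abs(merged$estimate_1 - merged$estimate_2)), 1e-4)
})

test_that("fit indices hit their perfect-fit limits and SRMR matches hand computation", {
  spec <- toy_spec(4) # 10 moments, 8 free parameters: 2 df
  lam <- c(0.8, 0.7, 0.6, 0.5)
  th <- 1 - lam^2
  params <- c(
    stats::setNames(lam, paste0("lambda_x", 1:4)),
    stats::setNames(th, paste0("theta_x", 1:4))
  )
  sigma <- implied_covariance(params, spec)
  # S = Sigma: the model reproduces the data covariance
  fit <- fit_sem(S = sigma, n = 400, spec = spec)
  expect_lt(fit$chi2, 1e-5)
  expect_equal(fit$indices$rmsea, 0) # chi2 < df floors at zero
  expect_lt(fit$indices$srmr, 1e-3)
  # exact limit chi2_m = df_m: TLI = 1 and RMSEA = 0 by the formulas
  at_limit <- fit
  at_limit$chi2 <- at_limit$df
  idx <- fit_indices(at_limit)
  expect_equal(idx$tli, 1)
  expect_equal(idx$rmsea, 0)
  # perturbed S: SRMR equals the hand-computed residual mean square
  S2 <- sigma
  S2[1, 2] <- S2[2, 1] <- sigma[1, 2] + 0.1
  fit2 <- fit_sem(S = S2, n = 400, spec = spec)
  dvec <- sqrt(diag(S2))
  resid <- (S2 - fit2$Sigma) / outer(dvec, dvec)
  hand <- sqrt(mean(resid[upper.tri(resid, diag = TRUE)]^2))
  expect_close(fit2$indices$srmr, hand, 1e-10)
  # saturated model: TLI and RMSEA are undefined and reported as NA
  sat <- fit_sem(S = sigma[1:3, 1:3], n = 400, spec = toy_spec(3))
  expect_true(is.na(sat$indices$tli))
  expect_true(is.na(sat$indices$rmsea))
})

test_that("objective decreases from start to solution and records convergence", {
  spec <- airborne_sem_spec()
  d <- simulate_sem(spec, sem_truth_airborne(), n = 1000, seed = 31)
  x <- as.matrix(as.data.frame(d))
  S <- stats::cov(x)
  start <- aerodyn:::sem_start_values(spec, S)
  f_start <- aerodyn:::fml_safe(S, implied_covariance(start, spec))
  fit <- fit_sem(S = S, n = 1000, spec = spec)
  expect_lt(fit$fml, f_start)
  expect_true(any(fit$convergence$codes == 0, na.rm = TRUE))
  expect_equal(fit$df, 17)
  g <- glance(fit)
  expect_true(g$converged)
  td <- tidy(fit)
  expect_equal(nrow(td), 11)
  expect_true(all(c("estimate", "std_estimate") %in% names(td)))
})

test_that("Heywood residuals are floored with a warning", {
  # a correlation structure demanding a negative residual variance
  S <- matrix(0.98, 3, 3)
  diag(S) <- 1
  S[1, 2] <- S[2, 1] <- 0.999
  dimnames(S) <- list(paste0("x", 1:3), paste0("x", 1:3))
  expect_warning(
    fit_sem(S = S, n = 200, spec = toy_spec(3)),
    "Heywood"
  )
})
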