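# Errors-in-variables SEM: exactness of the latent-Gaussian marginal
# likelihood, degenerate-error delegation, and attenuation/recovery.

# Brute-force Monte-Carlo oracle for the DYN_SEM+ marginal likelihood of a
# single subject: simulate latent paths forward from the model that
# fit_dyn_sem_plus specifies (stationary initial condition for the
# trade-off structure, free N(m1, s1) initial condition with intercept
# loadings otherwise) and average the measurement density of the observed
# values. Returns c(est, se) on the log scale.
semplus_mc_loglik_subject <- function(obs_y, obs_x, obs_z, params, structure,
                                      tau_x, tau_y, n_draws) {
  Tn <- length(obs_y)
  p <- params
  om <- if (is.null(p$omega)) matrix(0, 2, 2) else p$omega
  re <- matrix(rnorm(2 * n_draws), n_draws, 2) %*% chol(om + diag(1e-12, 2))
  mu <- re[, 1]
  nu <- re[, 2]
  if (structure == "tradeoff") {
    bd <- p$b * p$d
    m1 <- (p$c + p$d * p$a + p$d * mu + nu) / (1 - bd)
    v0 <- (p$d^2 * p$sigma_eps^2 + p$sigma_kappa^2) / (1 - bd^2)
    xp <- m1 + sqrt(v0) * rnorm(n_draws)
  } else {
    xp <- p$m1 + p$q_mu * mu + p$q_nu * nu + p$s1 * rnorm(n_draws)
  }
  lw <- numeric(n_draws)
  yp <- p$a + p$b * xp + mu + p$sigma_eps * rnorm(n_draws)
  lw <- lw + dnorm(obs_x[1], xp, sqrt(tau_x), log = TRUE) +
    dnorm(obs_y[1], yp, sqrt(tau_y), log = TRUE)
  for (t in 2:Tn) {
    xnew <- p$c + p$d * yp + p$sigma_kappa * rnorm(n_draws)
    if (structure != "tradeoff") xnew <- xnew + p$f * obs_z[t - 1] * xp
    if (structure == "tradeoff") xnew <- xnew + nu
    ynew <- p$a + p$b * xnew + mu + p$sigma_eps * rnorm(n_draws)
    lw <- lw + dnorm(obs_x[t], xnew, sqrt(tau_x), log = TRUE) +
      dnorm(obs_y[t], ynew, sqrt(tau_y), log = TRUE)
    xp <- xnew
    yp <- ynew
  }
  if (!is.null(obs_z)) {
    nz <- if (structure == "grouplive") nu else rep(0, n_draws)
    for (t in seq_len(Tn)) {
      lw <- lw + dnorm(obs_z[t], p$g + nz, p$sigma_lambda, log = TRUE)
    }
  }
  log_mean_exp(lw)
}

test_that("latent-model likelihood matches brute-force latent simulation", {
  for (structure in c("tradeoff", "grouplive")) {
    kind <- if (structure == "tradeoff") "tradeoff_multi" else
      "grouplive_multi"
    spec <- process_spec(kind, n_subjects = 2, n_time = 3, seed = 71)
    panel <- simulate_panel(spec)
    panel <- add_measurement_error(panel,
                                   measurement_error_spec(0.3, 0.3,
                                                          seed = 72))
    ev <- attr(panel, "error_variances")
    params <- list(a = spec$a, b = spec$b, c = spec$c, d = spec$d,
                   f = spec$f, g = spec$g,
                   sigma_eps = 1, sigma_kappa = 1,
                   sigma_lambda = max(spec$sigma_lambda, 0.2),
                   omega = matrix(c(0.4, 0.1, 0.1, 0.3), 2),
                   m1 = 1, s1 = 1.2, q_mu = 0.3, q_nu = -0.2)
    ll_impl <- dyn_sem_plus_loglik(panel, structure, params,
                                   error_variances = ev)
    set.seed(73)
    ll_mc <- 0
    mc_var <- 0
    for (s in unique(panel$subject)) {
      d <- panel[panel$subject == s, ]
      d <- d[order(d$time), ]
      r <- semplus_mc_loglik_subject(d$Y_obs, d$X_obs,
                                     if (structure == "tradeoff") NULL
                                     else d$Z,
                                     params, structure,
                                     tau_x = ev[["x"]], tau_y = ev[["y"]],
                                     n_draws = 1e6)
      ll_mc <- ll_mc + r[["est"]]
      mc_var <- mc_var + r[["se"]]^2
    }
    expect_lt(abs(ll_mc - ll_impl), 3 * sqrt(mc_var) + 0.01)
    expect_lt(sqrt(mc_var), 0.05)
  }
})

test_that("zero error variances reproduce the error-free SEM exactly", {
  p <- simulate_panel(process_spec("tradeoff_multi", n_subjects = 50,
                                   n_time = 8, seed = 81))
  p0 <- add_measurement_error(p, measurement_error_spec(0, 0, seed = 1))
  f_sem <- fit_dyn_sem(p0, "tradeoff")
  f_plus <- fit_dyn_sem_plus(p0, "tradeoff")
  expect_identical(f_plus$model, "DYN_SEM_PLUS")
  expect_equal(f_plus$b_hat, f_sem$b_hat, tolerance = 1e-10)
  expect_equal(f_plus$estimates, f_sem$estimates, tolerance = 1e-10)
})

test_that("overlarge error variances are rejected", {
  p <- simulate_panel(process_spec("tradeoff_multi", n_subjects = 20,
                                   n_time = 6, seed = 82))
  p <- add_measurement_error(p, measurement_error_spec(0.25, 0, seed = 1))
  expect_error(
    fit_dyn_sem_plus(p, "tradeoff",
                     error_variances = c(x = 10 * var(p$X_obs), y = 0)),
    "observed variance")
  expect_error(fit_dyn_sem_plus(p, "tradeoff", error_variances = NULL,
                                se = FALSE), NA)
})

test_that("predictor error attenuates the naive SEM; the latent model recovers b", {
  spec <- process_spec("tradeoff_multi", n_subjects = 500, n_time = 10,
                       seed = 91)
  p <- add_measurement_error(simulate_panel(spec),
                             measurement_error_spec(0.25, 0, seed = 92))
  naive <- fit_dyn_sem(p, "tradeoff", x = "X_obs", y = "Y_obs")
  latent <- fit_dyn_sem_plus(p, "tradeoff", se = FALSE)
  expect_lt(naive$b_hat, spec$b - 0.06)          # regression dilution
  expect_lt(abs(latent$b_hat - spec$b), 0.04)    # recovered
})
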