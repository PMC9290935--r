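# Simulator: fixed points, stationary moments, determinism, validation,
# measurement-error overlay, serialization.

test_that("noiseless process sits at its deterministic fixed point", {
  s <- process_spec("tradeoff_single", a = 0, b = 1, c = 2, d = 0,
                    sigma_eps = 0, sigma_kappa = 0, n_time = 6,
                    burn_in = 20, seed = 1)
  p <- simulate_panel(s)
  expect_equal(p$X, rep(2, 6))
  expect_equal(p$Y, rep(2, 6))
})

test_that("trade-off X is AR(1) with the analytic stationary moments", {
  # X_t = (c + d a) + (b d) X_{t-1} + d eps_{t-1} + kap_t
  s <- process_spec("tradeoff_single", a = 0, b = 0.5, c = 0, d = -0.5,
                    sigma_eps = 1, sigma_kappa = 1, n_time = 2000,
                    burn_in = 200, seed = 2)
  p <- simulate_panel(s)
  v_theory <- (s$d^2 * s$sigma_eps^2 + s$sigma_kappa^2) / (1 - (s$b * s$d)^2)
  expect_equal(var(p$X), v_theory, tolerance = 0.08)
  expect_equal(mean(p$X), (s$c + s$d * s$a) / (1 - s$b * s$d),
               tolerance = 0.1)
  a1 <- stats::acf(p$X, plot = FALSE)$acf[2]
  expect_equal(a1, s$b * s$d, tolerance = 0.12)
})

test_that("identical seeds give bit-identical panels", {
  s <- process_spec("grouplive_multi", n_subjects = 20, n_time = 8, seed = 7)
  expect_identical(simulate_panel(s), simulate_panel(s))
  s2 <- s
  s2$seed <- 8L
  expect_false(identical(simulate_panel(s)$X, simulate_panel(s2)$X))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  r1 <- runif(1)
  set.seed(99)
  invisible(simulate_panel(process_spec("tradeoff_single", seed = 3)))
  expect_identical(runif(1), r1)
})

test_that("invalid specifications are rejected by name", {
  expect_error(process_spec("tradeoff_single", b = 2, d = 0.6),
               "\\|b\\*d\\| < 1")
  expect_error(process_spec("density_single", b = 1.2, d = 0.5, f = 1, g = 1),
               "persistence")
  expect_error(process_spec("tradeoff_single", sigma_eps = -1), "sigma_eps")
  expect_error(process_spec("tradeoff_single", n_time = 1), "n_time")
  expect_error(process_spec("tradeoff_multi",
                            omega = matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")
  expect_error(process_spec("tradeoff_multi",
                            omega = matrix(c(1, 0.2, 0.4, 1), 2)),
               "symmetric")
})

test_that("explosive trajectories abort with an explosion error", {
  # passes the linearized guard but the Z-noise makes |phi_t| > 1 often
  s <- process_spec("density_single", b = -0.3, d = 0.5, f = 1, g = 0.5,
                    sigma_lambda = 8, n_time = 400, burn_in = 0, seed = 11)
  expect_error(simulate_panel(s), "explosion")
})

test_that("realized random intercepts match Omega across many subjects", {
  om <- matrix(c(0.8, -0.3, -0.3, 0.5), 2)
  s <- process_spec("tradeoff_multi", omega = om, n_subjects = 10000,
                    n_time = 2, burn_in = 0, seed = 5)
  re <- attr(simulate_panel(s), "intercepts")
  expect_equal(cov(cbind(re$mu, re$nu)), om, tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("no cross-lag means no step-correlation; d < 0 means negative lag correlation", {
  s0 <- process_spec("tradeoff_single", b = 0, d = 0, n_time = 3000,
                     seed = 6)
  p0 <- simulate_panel(s0)
  dx <- diff(p0$X)
  dy <- diff(p0$Y)
  expect_lt(abs(cor(dx, dy)), 0.06)
  sneg <- process_spec("tradeoff_single", b = 0, d = -0.5, n_time = 3000,
                       seed = 6)
  pn <- simulate_panel(sneg)
  expect_lt(cor(pn$X[-1], pn$Y[-nrow(pn)]), -0.2)
})

test_that("measurement-error overlay has the stated variance decomposition", {
  p <- simulate_panel(process_spec("tradeoff_multi", n_subjects = 200,
                                   n_time = 25, seed = 8))
  p0 <- add_measurement_error(p, measurement_error_spec(0, 0, seed = 1))
  expect_identical(p0$X_obs, p0$X)
  expect_identical(p0$Y_obs, p0$Y)
  pe <- add_measurement_error(p, measurement_error_spec(0.25, 0.25, seed = 1))
  expect_equal(var(pe$X_obs) / var(pe$X), 1 / 0.75, tolerance = 0.03)
  expect_equal(var(pe$Y_obs) / var(pe$Y), 1 / 0.75, tolerance = 0.03)
  # true columns retained, stored error variances match the fractions
  expect_identical(pe$X, p$X)
  ev <- attr(pe, "error_variances")
  expect_equal(ev[["x"]], 0.25 / 0.75 * var(p$X))
  expect_error(measurement_error_spec(1, 0), "\\[0, 1\\)")
})

test_that("panels round-trip through long-format CSV", {
  p <- simulate_panel(process_spec("grouplive_multi", n_subjects = 5,
                                   n_time = 4, seed = 9))
  f <- tempfile(fileext = ".csv")
  write_panel_csv(p, f)
  q <- read_panel_csv(f)
  expect_equal(as.data.frame(q)[c("subject", "time", "X", "Y", "Z")],
               as.data.frame(p)[c("subject", "time", "X", "Y", "Z")],
               tolerance = 1e-12)
  expect_identical(attr(q, "spec"), "empirical")
  # malformed panels are rejected
  bad <- as.data.frame(p)
  bad$time[2] <- 9L
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_panel_csv(f), "contiguous")
})

test_that("process specs round-trip through YAML and JSON", {
  s <- process_spec("grouplive_multi", n_subjects = 12, n_time = 7,
                    seed = 42)
  for (ext in c(".yml", ".json")) {
    f <- tempfile(fileext = ext)
    write_process_spec(s, f)
    expect_equal(read_process_spec(f), s)
  }
  f <- tempfile(fileext = ".yml")
  yaml::write_yaml(list(kind = "tradeoff_single", bogus = 1), f)
  expect_error(read_process_spec(f), "unknown")
})
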