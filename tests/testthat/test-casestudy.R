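# Group-panel pipeline: validation, the synthetic generator, the percent
# transformation, and short-chain smoke runs of the Bayesian models.
# (Parameter-recovery and the static-vs-dynamic contrast at full MCMC
# length live in the acceptance suite.)

test_that("group panels read, validate and round-trip", {
  gp <- data.frame(group = c("a", "a", "b"), year = c(1, 2, 1),
                   group_size = c(3L, 4L, 2L), productivity = c(2L, 1L, 0L),
                   survivors = c(2L, 3L, 2L))
  f <- tempfile(fileext = ".csv")
  write.csv(gp, f, row.names = FALSE)
  parsed <- read_group_panel(f)
  expect_s3_class(parsed, "group_panel")
  expect_equal(nrow(parsed), 3L)
  write_group_panel(parsed, f)
  expect_equal(as.data.frame(read_group_panel(f)), as.data.frame(parsed))
  # invariant violations are reported with row indices
  bad <- gp
  bad$survivors[2] <- 9L
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_group_panel(f), "survivors > group_size in row\\(s\\) 2")
  bad2 <- gp
  bad2$productivity[3] <- -1
  write.csv(bad2, f, row.names = FALSE)
  expect_error(read_group_panel(f), "non-negative integer in row\\(s\\) 3")
  gap <- rbind(gp, data.frame(group = "a", year = 5, group_size = 2L,
                              productivity = 1L, survivors = 1L))
  write.csv(gap, f, row.names = FALSE)
  expect_warning(read_group_panel(f), "non-contiguous")
  # custom column mapping
  renamed <- gp
  names(renamed) <- c("terr", "season", "n_adults", "fledged", "alive")
  write.csv(renamed, f, row.names = FALSE)
  parsed2 <- read_group_panel(f, columns = c(group = "terr", year = "season",
                                             group_size = "n_adults",
                                             productivity = "fledged",
                                             survivors = "alive"))
  expect_equal(parsed2$group_size, gp$group_size)
})

test_that("the synthetic generator respects its structural constraints", {
  gp <- simulate_wren_like(n_groups = 80, n_years = 8, seed = 5)
  expect_true(all(gp$survivors <= gp$group_size))
  expect_true(all(gp$group_size >= 2))
  expect_true(all(gp$productivity >= 0))
  expect_equal(nrow(gp), 80 * 8)
  expect_identical(gp, simulate_wren_like(n_groups = 80, n_years = 8,
                                          seed = 5))
  expect_error(simulate_wren_like(philopatry = 2), "philopatry")
  # philopatry induces a positive cross-lag from productivity to size
  cc <- crosslag_correlation(gp, x = "group_size", y = "productivity")
  expect_gt(cc$estimate, 0.15)
})

test_that("without effect or heterogeneity, group means of size and productivity decouple", {
  gp <- simulate_wren_like(n_groups = 150, n_years = 8, b = 0, sd_mu = 0,
                           sd_nu = 0, philopatry = 0.2, seed = 6)
  ms <- tapply(gp$group_size, gp$group, mean)
  mp <- tapply(gp$productivity, gp$group, mean)
  expect_lt(abs(cor(ms, mp)), 0.2)
})

test_that("percent-effect transformation is monotone, anchored and invertible", {
  expect_equal(percent_effect(0), 0)
  expect_equal(percent_effect(log(1.12)), 12, tolerance = 1e-10)
  b <- seq(-0.5, 0.5, 0.1)
  expect_true(all(diff(percent_effect(b)) > 0))
  expect_equal(percent_effect_inverse(percent_effect(b)), b,
               tolerance = 1e-12)
})

test_that("the Bayesian static model centres near zero on null data", {
  gp <- simulate_wren_like(n_groups = 60, n_years = 7, b = 0, sd_mu = 0.1,
                           sd_nu = 0.1, philopatry = 0.2, seed = 7)
  fit <- suppressWarnings(
    fit_wren_stat_within(gp, mcmc = list(n_chains = 2, n_adapt = 300,
                                         n_warmup = 300, n_iter = 500)))
  expect_s3_class(fit, "wren_posterior")
  pe <- fit$percent_effect
  expect_true(pe[["ci_lower"]] < 0 && 0 < pe[["ci_upper"]])
  expect_lt(abs(pe[["mean"]]), 5)
  expect_true(all(c("a", "b", "sd_mu") %in% fit$summary$parameter))
  expect_true(all(is.finite(fit$summary$rhat)))
})

test_that("the joint dynamical model runs, reports diagnostics and sees the planted effect", {
  gp <- simulate_wren_like(n_groups = 80, n_years = 9, seed = 8)
  fit <- suppressWarnings(
    fit_wren_dyn_sem(gp, mcmc = list(n_chains = 2, n_adapt = 300,
                                     n_warmup = 400, n_iter = 600)))
  expect_true(all(c("b", "d", "f", "rho") %in% fit$summary$parameter))
  expect_true(all(fit$summary$ess > 0))
  # planted +12%: posterior mass clearly on positive effects
  expect_gt(fit$percent_effect[["mean"]], 2)
  # recruitment cross-lag d near the philopatry probability scale
  d_hat <- fit$summary$mean[fit$summary$parameter == "d"]
  expect_gt(d_hat, 0.1)
  # posterior CSVs
  sfile <- tempfile(fileext = ".csv")
  dfile <- tempfile(fileext = ".csv")
  write_posterior(fit, sfile, dfile)
  expect_true(file.exists(sfile) && file.exists(dfile))
  draws <- read.csv(dfile)
  expect_equal(nrow(draws), 2 * 600)
})
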