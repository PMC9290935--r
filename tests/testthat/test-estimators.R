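# Static and lagged-dependent-variable estimators.

test_that("within-subject centring subtracts the subject's own mean", {
  d <- make_panel(1, list(c(1, 3)), list(c(0, 0)))
  expect_equal(within_subject_centre(d, "X")$X_within, c(-1, 1))
  d2 <- make_panel(1:2, list(c(1, 3), c(10, 14)), list(c(0, 0), c(0, 0)))
  expect_equal(within_subject_centre(d2, "X")$X_within, c(-1, 1, -2, 2))
  # idempotent
  d2 <- within_subject_centre(d2, "X")
  d2 <- within_subject_centre(d2, "X_within")
  expect_equal(d2$X_within_within, d2$X_within)
  expect_error(within_subject_centre(d2, "nope"), "unknown variable")
})

test_that("single-subject static fit reduces to ordinary least squares", {
  d <- make_panel(1, list(0:9), list(2 * (0:9)))
  f <- quietly(fit_stat_overall(d)) # noiseless fit: summary.lm chatters
  expect_equal(f$b_hat, 2, tolerance = 1e-10)
  expect_true(f$converged)
  # normal-equation oracle on the 4-point panel
  d4 <- make_panel(1, list(c(0, 1, 2, 3)), list(c(1, 3, 4, 7)))
  f4 <- fit_stat_overall(d4)
  expect_equal(f4$b_hat, 1.9, tolerance = 1e-10)
  expect_equal(unname(f4$estimates["a"]), 0.9, tolerance = 1e-10)
  expect_equal(f4$b_hat, unname(coef(lm(Y ~ X, d4))[2]))
})

test_that("for one subject the within and overall slopes coincide", {
  p <- simulate_panel(process_spec("tradeoff_single", n_time = 30, seed = 4))
  fo <- fit_stat_overall(p)
  fw <- fit_stat_within(p)
  expect_equal(fw$b_hat, fo$b_hat, tolerance = 1e-9)
})

test_that("within-subject slope approximates the mean per-subject slope on balanced panels", {
  p <- simulate_panel(process_spec("tradeoff_multi", n_subjects = 60,
                                   n_time = 12, seed = 10))
  fw <- quietly(fit_stat_within(p))
  per <- vapply(split(as.data.frame(p), p$subject),
                function(d) unname(coef(lm(Y ~ X, d))[2]), numeric(1))
  expect_equal(fw$b_hat, mean(per), tolerance = 0.05)
})

test_that("degenerate designs raise or warn as appropriate", {
  d <- make_panel(1, list(rep(1, 5)), list(1:5))
  expect_error(fit_stat_overall(d), "non-estimable")
  d2 <- make_panel(1:2, list(rep(1, 3), c(1, 2, 3)), list(1:3, 2:4))
  expect_warning(fit_stat_overall(d2), "constant X")
  # a subject left with nothing after lagging
  d3 <- rbind(make_panel(1, list(c(1, 2, 3)), list(c(1, 2, 3))),
              data.frame(subject = 2, time = 1, X = 5, Y = 5))
  expect_error(fit_dyn_ldvm(d3), "lagging")
})

test_that("the lagged response is superfluous without a cross-lag", {
  # d = 0, no heterogeneity: b unbiased; the auto-lag coefficient is zero in
  # the population, up to the O(1/T) shrinkage that centring the lagged
  # response with the subject's own short-series mean induces
  reps <- 40
  Tn <- 20
  est <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    s <- process_spec("tradeoff_multi", d = 0, omega = matrix(0, 2, 2),
                      n_subjects = 40, n_time = Tn, seed = 100 + r)
    f <- quietly(fit_dyn_ldvm(simulate_panel(s)))
    est[r, ] <- c(f$b_hat, f$estimates[["gamma"]])
  }
  expect_lt(abs(mean(est[, 1]) - 0.5), 2.5 * sd(est[, 1]) / sqrt(reps))
  expect_lt(abs(mean(est[, 2])), 2 / (Tn - 1))
})

test_that("among-subject covariance confounds only the overall model", {
  # b = 0, d = 0, positive Omega: overall slope picks up the among-subject
  # covariance, the within-subject slope does not
  reps <- 60
  est <- matrix(NA_real_, reps, 2)
  om <- matrix(c(0.49, 0.35, 0.35, 0.49), 2)
  for (r in seq_len(reps)) {
    s <- process_spec("tradeoff_multi", b = 0, d = 0, omega = om,
                      n_subjects = 50, n_time = 5, seed = 300 + r)
    p <- simulate_panel(s)
    est[r, 1] <- quietly(fit_stat_overall(p))$b_hat
    est[r, 2] <- quietly(fit_stat_within(p))$b_hat
  }
  se <- apply(est, 2, sd) / sqrt(reps)
  expect_gt(mean(est[, 1]), 4 * se[1])          # confounded upward
  expect_lt(abs(mean(est[, 2])), 3 * se[2])     # centred slope clean
})

test_that("fit results serialize to flat records", {
  p <- simulate_panel(process_spec("tradeoff_multi", n_subjects = 20,
                                   n_time = 6, seed = 2))
  f <- quietly(fit_stat_overall(p))
  rec <- fit_record(f)
  expect_equal(nrow(rec), 1L)
  expect_true(all(c("model", "b_hat", "se_b", "p_value_b", "loglik",
                    "est_b") %in% names(rec)))
  expect_equal(rec$est_b, f$b_hat)
  jf <- tempfile(fileext = ".json")
  fit_to_json(f, jf)
  back <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(back$b_hat, f$b_hat, tolerance = 1e-12)
  # Wald machinery is internally consistent
  expect_true(f$ci_b[1] <= f$b_hat && f$b_hat <= f$ci_b[2])
  expect_equal(f$p_value_b,
               2 * pnorm(-abs(f$b_hat / f$se_b)), tolerance = 1e-12)
  expect_equal(f$b_standardized, f$b_hat * sd(p$X) / sd(p$Y))
})

test_that("the front end dispatches to every estimator", {
  p <- simulate_panel(process_spec("tradeoff_multi", n_subjects = 25,
                                   n_time = 6, seed = 3))
  for (m in c("stat_overall", "stat_within", "dyn_ldvm", "dyn_sem")) {
    f <- quietly(crosslag_fit(p, m))
    expect_s3_class(f, "crosslag_fit")
    expect_true(is.finite(f$b_hat))
  }
  expect_error(crosslag_fit(p, "nope"))
})
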