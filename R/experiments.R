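# Replicate-level Monte-Carlo engine: bias and power surfaces over grids of
# subject number and series length, and one-parameter sweeps. Every model in
# a grid cell is fitted to the identical simulated panels (paired design);
# replicate r of a run seeded with `seed` always simulates from `seed + r`,
# so results are independent of evaluation order and bit-reproducible.

.experiment_models <- c("stat_overall", "stat_within", "dyn_ldvm",
                        "dyn_sem", "dyn_sem_plus")

# Fit one model to one panel, returning c(b_hat, p_value, converged).
# Failures are recorded as NA, never raised.
.fit_one <- function(model, panel, use_obs, se) {
  xy <- if (use_obs) list(x = "X_obs", y = "Y_obs") else list(x = "X", y = "Y")
  out <- tryCatch({
    fit <- switch(model,
      stat_overall = fit_stat_overall(panel, x = xy$x, y = xy$y),
      stat_within = fit_stat_within(panel, x = xy$x, y = xy$y),
      dyn_ldvm = fit_dyn_ldvm(panel, x = xy$x, y = xy$y),
      dyn_sem = fit_dyn_sem(panel, x = xy$x, y = xy$y, se = se),
      dyn_sem_plus = fit_dyn_sem_plus(panel, se = se)
    )
    c(fit$b_hat, fit$p_value_b, as.numeric(fit$converged))
  }, error = function(e) c(NA_real_, NA_real_, 0))
  out
}

.check_models <- function(models, me) {
  bad <- setdiff(models, .experiment_models)
  if (length(bad))
    stop("unknown model(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if ("dyn_sem_plus" %in% models && is.null(me))
    stop("model `dyn_sem_plus` requires a measurement-error overlay ",
         "(argument `me`)", call. = FALSE)
  models
}

# Shared cell runner: n_reps paired replicates of one (spec, models) cell.
.run_cell <- function(spec, models, n_reps, seed, me, alpha, se) {
  bh <- matrix(NA_real_, n_reps, length(models),
               dimnames = list(NULL, models))
  pv <- bh
  cv <- bh
  for (r in seq_len(n_reps)) {
    spec_r <- spec
    spec_r$seed <- as.integer(seed + r)
    panel <- simulate_panel(spec_r)
    if (!is.null(me)) {
      me_r <- me
      me_r$seed <- as.integer(seed + r + 1000003L)
      panel <- add_measurement_error(panel, me_r)
    }
    for (m in models) {
      res <- .fit_one(m, panel, use_obs = !is.null(me), se = se)
      bh[r, m] <- res[1]
      pv[r, m] <- res[2]
      cv[r, m] <- res[3]
    }
  }
  summ <- lapply(models, function(m) {
    ok <- is.finite(bh[, m]) & cv[, m] == 1
    bs <- bh[ok, m]
    data.frame(
      model = toupper(m),
      b_true = spec$b,
      n_reps = n_reps,
      n_used = sum(ok),
      mean_b = mean(bs),
      abs_bias = mean(bs) - spec$b,
      rel_bias_pct = if (abs(spec$b) > 1e-12)
        100 * (mean(bs) - spec$b) / spec$b else NA_real_,
      mc_se = stats::sd(bs) / sqrt(sum(ok)),
      power = mean(pv[ok, m] < alpha, na.rm = TRUE),
      convergence_rate = mean(cv[, m] == 1)
    )
  })
  list(summary = do.call(rbind, summ), b_hat = bh, p_value = pv)
}

#' Monte-Carlo bias and power over a subjects-by-length grid
#'
#' For every combination of subject number and series length, simulates
#' `n_reps` panels from `base` (with `n_subjects`/`n_time` overridden) and
#' fits every requested model to the identical panels. Summaries per cell and
#' model: mean estimate of `b`, absolute bias, relative bias in percent
#' (flagged `NA` when the true `b` is zero), the Monte-Carlo standard error
#' of the mean, power (fraction of replicates with `p < alpha`), and the
#' convergence rate. Non-converged or failed fits are excluded from the
#' summaries, with `n_used` reporting how many replicates remain.
#'
#' @param base A [process_spec()] providing the process parameters.
#' @param subjects,lengths Integer vectors of subject counts and series
#'   lengths to cross.
#' @param models Character vector among `"stat_overall"`, `"stat_within"`,
#'   `"dyn_ldvm"`, `"dyn_sem"`, `"dyn_sem_plus"`.
#' @param n_reps Replicates per cell (>= 2).
#' @param seed Base seed; replicate `r` simulates from `seed + r`.
#' @param me Optional [measurement_error_spec()]; when given, all models are
#'   fitted on the error-contaminated columns (required for
#'   `"dyn_sem_plus"`).
#' @param alpha Significance threshold used for power (default 0.05).
#' @param se Compute Wald standard errors inside the dynamical-SEM fits
#'   (needed for their power entries; can be disabled for bias-only runs).
#' @return A `crosslag_experiment`: a data.frame of one row per
#'   (subjects, length, model) with the summaries above; the per-replicate
#'   estimates are retained in the `"replicates"` attribute.
#' @examples
#' base <- process_spec("tradeoff_multi", seed = 1)
#' ex <- run_grid(base, subjects = 50, lengths = 5,
#'                models = c("stat_within", "dyn_sem"), n_reps = 20, seed = 10)
#' ex
#' @export
run_grid <- function(base, subjects, lengths, models, n_reps, seed = 1L,
                     me = NULL, alpha = 0.05, se = TRUE) {
  stopifnot(inherits(base, "process_spec"))
  if (n_reps < 2) stop("`n_reps` must be >= 2", call. = FALSE)
  .check_models(models, me)
  rows <- list()
  reps <- list()
  for (S in subjects) {
    for (Tn in lengths) {
      spec <- base
      spec$n_subjects <- as.integer(S)
      spec$n_time <- as.integer(Tn)
      validate_process_spec(spec)
      cell <- .run_cell(spec, models, n_reps, seed, me, alpha, se)
      cell$summary <- cbind(data.frame(kind = spec$kind, n_subjects = S,
                                       n_time = Tn), cell$summary)
      rows[[length(rows) + 1L]] <- cell$summary
      reps[[paste(S, Tn, sep = "x")]] <- cell[c("b_hat", "p_value")]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "replicates") <- reps
  attr(out, "base_spec") <- base
  class(out) <- c("crosslag_experiment", "data.frame")
  out
}

#' Monte-Carlo bias sweep over one process parameter
#'
#' As [run_grid()], but holds the design (`S` subjects, `T` steps) fixed and
#' varies one generating parameter: the cross-lag `d`, the among-subject
#' covariance `omega_cov` (the off-diagonal of `Omega`), or the true effect
#' size `b`. For the `b` sweep the absolute bias is the primary summary,
#' since relative bias does not exist at `b = 0`.
#'
#' @inheritParams run_grid
#' @param parameter One of `"d"`, `"omega_cov"`, `"b"`.
#' @param values Numeric vector of parameter values to sweep.
#' @param S,T_len Design size held fixed across the sweep.
#' @return A `crosslag_experiment` with a `value` column.
#' @export
run_sweep <- function(base, parameter = c("d", "omega_cov", "b"), values,
                      S = 100, T_len = 10, models, n_reps, seed = 1L,
                      me = NULL, alpha = 0.05, se = TRUE) {
  stopifnot(inherits(base, "process_spec"))
  parameter <- match.arg(parameter)
  if (n_reps < 2) stop("`n_reps` must be >= 2", call. = FALSE)
  .check_models(models, me)
  rows <- list()
  reps <- list()
  for (v in values) {
    spec <- base
    spec$n_subjects <- as.integer(S)
    spec$n_time <- as.integer(T_len)
    if (parameter == "omega_cov") {
      spec$omega[1, 2] <- spec$omega[2, 1] <- v
    } else {
      spec[[parameter]] <- v
    }
    validate_process_spec(spec)
    cell <- .run_cell(spec, models, n_reps, seed, me, alpha, se)
    cell$summary <- cbind(data.frame(kind = spec$kind, parameter = parameter,
                                     value = v, n_subjects = S,
                                     n_time = T_len), cell$summary)
    rows[[length(rows) + 1L]] <- cell$summary
    reps[[as.character(v)]] <- cell[c("b_hat", "p_value")]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "replicates") <- reps
  attr(out, "base_spec") <- base
  class(out) <- c("crosslag_experiment", "data.frame")
  out
}

#' Design-tailored power analysis
#'
#' Computes statistical power (and the accompanying bias) of one estimator
#' across candidate study designs — combinations of subject number and
#' series length — under the process in `base`, supporting "more subjects
#' versus more years" trade-off decisions. Note that high power and large
#' bias can coexist: power reflects the probability of rejecting `b = 0`,
#' not the accuracy of the estimate.
#'
#' @inheritParams run_grid
#' @param model A single model name.
#' @param alpha Significance threshold in (0, 1).
#' @return A `crosslag_experiment` with power and bias per design.
#' @export
power_analysis <- function(base, subjects, lengths, model = "stat_within",
                           alpha = 0.05, n_reps = 200, seed = 1L, me = NULL) {
  if (length(model) != 1L)
    stop("`model` must be a single model name", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  if (n_reps < 2) stop("`n_reps` must be >= 2 (got ", n_reps, ")",
                       call. = FALSE)
  run_grid(base, subjects, lengths, models = model, n_reps = n_reps,
           seed = seed, me = me, alpha = alpha)
}

#' @export
print.crosslag_experiment <- function(x, ...) {
  cat("Monte-Carlo experiment (", nrow(x), " cells)\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 4))
  print(df)
  invisible(x)
}

#' Plot bias curves of an experiment
#'
#' Mean estimate of `b` (with 2 Monte-Carlo-SE bars) against series length,
#' one line per model, with a horizontal reference at the true value.
#'
#' @param x A `crosslag_experiment` from [run_grid()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.crosslag_experiment <- function(x, ...) {
  xv <- if ("n_time" %in% names(x) && length(unique(x$n_time)) > 1)
    "n_time" else if ("value" %in% names(x)) "value" else "n_subjects"
  models <- unique(x$model)
  ylim <- range(c(x$mean_b - 2 * x$mc_se, x$mean_b + 2 * x$mc_se,
                  x$b_true), finite = TRUE)
  graphics::plot(range(x[[xv]]), ylim, type = "n", xlab = xv,
                 ylab = "mean estimate of b", ...)
  graphics::abline(h = unique(x$b_true), lty = 3)
  for (i in seq_along(models)) {
    d <- x[x$model == models[i], ]
    d <- d[order(d[[xv]]), ]
    graphics::lines(d[[xv]], d$mean_b, col = i, type = "o", pch = 16)
    graphics::arrows(d[[xv]], d$mean_b - 2 * d$mc_se,
                     d[[xv]], d$mean_b + 2 * d$mc_se,
                     angle = 90, code = 3, length = 0.03, col = i)
  }
  graphics::legend("topright", legend = models, col = seq_along(models),
                   lty = 1, pch = 16, bty = "n", cex = 0.8)
  invisible(x)
}
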