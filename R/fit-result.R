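# The common fitted-model container shared by all estimators, and the
# within-subject centring helper they build on.

#' Within-subject centring
#'
#' Adds a column `<variable>_within` equal to the value minus that subject's
#' own mean, the standard device for isolating within-subject effects from
#' among-subject heterogeneity in longitudinal data. The per-subject mean of
#' the new column is zero to numerical tolerance, and the operation is
#' idempotent on an already-centred column.
#'
#' @param panel A panel data.frame with a `subject` column.
#' @param variable Name of the column to centre.
#' @return The panel with the centred column appended.
#' @examples
#' d <- data.frame(subject = c(1, 1, 2, 2), time = c(1, 2, 1, 2),
#'                 X = c(1, 3, 10, 14), Y = 0)
#' within_subject_centre(d, "X")$X_within
#' @export
within_subject_centre <- function(panel, variable) {
  if (!variable %in% names(panel))
    stop("unknown variable: `", variable, "`", call. = FALSE)
  v <- panel[[variable]]
  panel[[paste0(variable, "_within")]] <-
    v - stats::ave(v, panel$subject, FUN = mean)
  panel
}

# Construct a crosslag_fit object. `estimates` is a named numeric vector that
# must contain "b"; the standardized slope uses the SD ratio by default with
# the variance-ratio variant stored alongside.
new_crosslag_fit <- function(model, structure = NA_character_, estimates,
                             se_b, loglik, converged, n_subjects, n_obs,
                             sd_x, sd_y, extra = list()) {
  b <- unname(estimates[["b"]])
  se_b <- as.numeric(se_b)
  z <- if (is.finite(se_b) && se_b > 0) b / se_b else NA_real_
  fit <- c(list(
    model = model,
    structure = structure,
    estimates = estimates,
    b_hat = b,
    se_b = se_b,
    ci_b = b + c(-1, 1) * stats::qnorm(0.975) * se_b,
    p_value_b = if (is.finite(z)) 2 * stats::pnorm(-abs(z)) else NA_real_,
    loglik = loglik,
    converged = isTRUE(converged),
    b_standardized = b * sd_x / sd_y,
    b_standardized_var = b * sd_x^2 / sd_y^2,
    n_subjects = n_subjects,
    n_obs = n_obs
  ), extra)
  class(fit) <- "crosslag_fit"
  fit
}

#' @export
print.crosslag_fit <- function(x, ...) {
  cat(sprintf("%s fit%s (%d subject(s), %d observations)%s\n",
              x$model,
              if (!is.na(x$structure)) paste0(" [", x$structure, "]") else "",
              x$n_subjects, x$n_obs,
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  cat(sprintf("  b = %.4f  (SE %.4f, 95%% CI [%.4f, %.4f], p = %.3g)\n",
              x$b_hat, x$se_b, x$ci_b[1], x$ci_b[2], x$p_value_b))
  cat(sprintf("  standardized b (SD ratio): %.4f;  log-likelihood: %.3f\n",
              x$b_standardized, x$loglik))
  invisible(x)
}

#' @export
summary.crosslag_fit <- function(object, ...) {
  cat("Model:", object$model,
      if (!is.na(object$structure)) paste0("(", object$structure,
                                           " structure)") else "", "\n")
  cat("Parameter estimates:\n")
  print(round(object$estimates, 5))
  print(object)
  invisible(object)
}

#' @export
coef.crosslag_fit <- function(object, ...) object$estimates

#' @export
logLik.crosslag_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$estimates),
            nobs = object$n_obs, class = "logLik")
}

#' @export
confint.crosslag_fit <- function(object, parm = "b", level = 0.95, ...) {
  if (!identical(parm, "b"))
    stop("Wald intervals are reported for `b` only", call. = FALSE)
  q <- stats::qnorm(1 - (1 - level) / 2)
  ci <- object$b_hat + c(-1, 1) * q * object$se_b
  matrix(ci, 1, 2, dimnames = list("b", c("lower", "upper")))
}

#' Flatten a fitted model into a single-row record
#'
#' Serializes a `crosslag_fit` to a flat one-row data.frame with stable
#' column names (`est_<parameter>` for each estimate plus the summary
#' fields), so experiment tables are machine-joinable. `fit_to_json` writes
#' the same record as JSON.
#'
#' @param fit A `crosslag_fit`.
#' @param path Output path for `fit_to_json`.
#' @return A one-row data.frame (or, for `fit_to_json`, `path` invisibly).
#' @export
fit_record <- function(fit) {
  stopifnot(inherits(fit, "crosslag_fit"))
  est <- as.list(fit$estimates)
  names(est) <- paste0("est_", names(est))
  cbind(data.frame(model = fit$model, structure = fit$structure,
                   b_hat = fit$b_hat, se_b = fit$se_b,
                   ci_lower = fit$ci_b[1], ci_upper = fit$ci_b[2],
                   p_value_b = fit$p_value_b,
                   b_standardized = fit$b_standardized,
                   loglik = fit$loglik, converged = fit$converged,
                   n_subjects = fit$n_subjects, n_obs = fit$n_obs),
        as.data.frame(est))
}

#' @rdname fit_record
#' @export
fit_to_json <- function(fit, path) {
  jsonlite::write_json(as.list(fit_record(fit)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Fit an estimator of the contemporaneous effect to a panel
#'
#' Front end dispatching to the five estimators of the contemporaneous
#' effect `b` of `X_t` on `Y_t`:
#'
#' * `"stat_overall"` — conventional cross-sectional static (mixed) model;
#'   see [fit_stat_overall()].
#' * `"stat_within"` — static model on within-subject-centred `X`;
#'   see [fit_stat_within()].
#' * `"dyn_ldvm"` — lagged-dependent-variable mixed model;
#'   see [fit_dyn_ldvm()].
#' * `"dyn_sem"` — dynamical structural equation model with correlated
#'   random intercepts; see [fit_dyn_sem()].
#' * `"dyn_sem_plus"` — errors-in-variables extension with known
#'   measurement-error variances; see [fit_dyn_sem_plus()].
#'
#' @param panel A panel data.frame (`subject`, `time`, `X`, `Y`, optionally
#'   `Z`, `X_obs`, `Y_obs`).
#' @param model Which estimator to fit.
#' @param ... Passed to the corresponding `fit_*` function (e.g. `structure`
#'   for the SEM variants).
#' @return A `crosslag_fit`.
#' @examples
#' p <- simulate_panel(process_spec("tradeoff_multi", n_subjects = 50, seed = 1))
#' crosslag_fit(p, "dyn_sem", structure = "tradeoff")
#' @export
crosslag_fit <- function(panel,
                         model = c("stat_overall", "stat_within", "dyn_ldvm",
                                   "dyn_sem", "dyn_sem_plus"),
                         ...) {
  model <- match.arg(model)
  switch(model,
    stat_overall = fit_stat_overall(panel, ...),
    stat_within = fit_stat_within(panel, ...),
    dyn_ldvm = fit_dyn_ldvm(panel, ...),
    dyn_sem = fit_dyn_sem(panel, ...),
    dyn_sem_plus = fit_dyn_sem_plus(panel, ...)
  )
}
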