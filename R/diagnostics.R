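# Empirical checks for the presence and signature of a cross-lag in a panel.

#' Within-subject cross-lag correlation
#'
#' Estimates the correlation between `X_t` and `Y_{t-1}` on within-subject
#' centred values — the first exploratory check for a cross-lag in a dataset.
#' Pairs are formed strictly within subjects (never across), and per-subject
#' additive shifts of either variable cannot affect the statistic because
#' centring removes them. The confidence interval uses the Fisher
#' z-transformation with the number of within-subject pairs as effective
#' sample size.
#'
#' A significant correlation is a *necessary, not a sufficient* condition
#' for a causal cross-lag: measurement error or unmodelled confounders can
#' in principle produce such a correlation too, and the printed output says
#' so.
#'
#' @param panel Panel data.frame with `subject` and `time`.
#' @param x,y Column names of the covariate and response (defaults `"X"`,
#'   `"Y"`).
#' @param subject,time Column names of the subject identifier and time index
#'   (pass `"group"`, `"year"` for a [read_group_panel()] panel).
#' @param conf_level Confidence level for the Fisher-z interval.
#' @return An object of class `crosslag_correlation`: list with `estimate`,
#'   `n_pairs`, `conf_int`, `p_value`.
#' @examples
#' p <- simulate_panel(process_spec("tradeoff_multi", n_subjects = 60, seed = 2))
#' crosslag_correlation(p)
#' @export
crosslag_correlation <- function(panel, x = "X", y = "Y",
                                 subject = "subject", time = "time",
                                 conf_level = 0.95) {
  if (!subject %in% names(panel) && all(c("group", "year") %in% names(panel))) {
    subject <- "group"
    time <- "year"
  }
  for (v in c(subject, time, x, y)) {
    if (!v %in% names(panel))
      stop("panel lacks required column `", v, "`", call. = FALSE)
  }
  d <- as.data.frame(panel)
  d$subject <- d[[subject]]
  d$time <- d[[time]]
  d <- d[order(d$subject, d$time), ]
  d$ylag <- stats::ave(d[[y]], d$subject,
                       FUN = function(v) c(NA_real_, v[-length(v)]))
  d <- d[!is.na(d$ylag), , drop = FALSE]
  if (nrow(d) < 3L)
    stop("insufficient data: fewer than 3 usable within-subject pairs",
         call. = FALSE)
  d$xc <- d[[x]] - stats::ave(d[[x]], d$subject, FUN = mean)
  d$ylagc <- d$ylag - stats::ave(d$ylag, d$subject, FUN = mean)
  r <- stats::cor(d$xc, d$ylagc)
  n <- nrow(d)
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  zse <- 1 / sqrt(n - 3)
  ci <- tanh(atanh(r) + c(-1, 1) * zcrit * zse)
  p <- 2 * stats::pnorm(-abs(atanh(r)) / zse)
  structure(list(estimate = r, n_pairs = n, conf_int = ci, p_value = p,
                 conf_level = conf_level, x = x, y = y,
                 pairs = d[, c("subject", "time", "xc", "ylagc")]),
            class = "crosslag_correlation")
}

#' @export
print.crosslag_correlation <- function(x, ...) {
  cat(sprintf(
    "Within-subject cross-lag correlation cor(%s_t, %s_[t-1]) = %.3f\n",
    x$x, x$y, x$estimate))
  cat(sprintf("  %d pairs; %g%% CI [%.3f, %.3f]; p = %.3g\n",
              x$n_pairs, 100 * x$conf_level, x$conf_int[1], x$conf_int[2],
              x$p_value))
  cat("  Note: a cross-lag correlation is a necessary, not a sufficient,\n")
  cat("  condition for a causal cross-lag.\n")
  invisible(x)
}

#' Lag-scatter plot of the cross-lag correlation
#'
#' Scatter of within-subject centred `X_t` against centred `Y_{t-1}` with a
#' least-squares reference line.
#'
#' @param x A `crosslag_correlation`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.crosslag_correlation <- function(x, ...) {
  graphics::plot(x$pairs$ylagc, x$pairs$xc,
                 xlab = sprintf("%s[t-1] (within-subject centred)", x$y),
                 ylab = sprintf("%s[t] (within-subject centred)", x$x), ...)
  graphics::abline(stats::lm(xc ~ ylagc, data = x$pairs), col = 2)
  invisible(x)
}

#' Growth of the variance of X over time
#'
#' Simulates `n_reps` replicate panels from a degenerate start (every
#' subject at the deterministic stationary point, no burn-in) and reports
#' the across-replicate variance of `X` at each time step. For cross-lagged
#' processes this variance grows from zero and levels off at the stationary
#' value — the mechanism by which the endogeneity bias of static models
#' fades in long series.
#'
#' @param spec A [process_spec()]; `burn_in` is forced to 0 for this
#'   diagnostic.
#' @param n_reps Number of replicate panels.
#' @return A data.frame with columns `time` and `var_x` (variance across all
#'   replicates and subjects at that step).
#' @examples
#' vg <- variance_growth(process_spec("tradeoff_single", n_time = 30, seed = 1),
#'                       n_reps = 200)
#' head(vg)
#' @export
variance_growth <- function(spec, n_reps = 1000) {
  validate_process_spec(spec)
  if (n_reps < 2) stop("`n_reps` must be >= 2", call. = FALSE)
  spec$burn_in <- 0L
  out <- matrix(NA_real_, n_reps * spec$n_subjects, spec$n_time)
  for (r in seq_len(n_reps)) {
    spec_r <- spec
    spec_r$seed <- as.integer(spec$seed + r)
    p <- simulate_panel(spec_r)
    out[(r - 1L) * spec$n_subjects + seq_len(spec$n_subjects), ] <-
      t(matrix(p$X, nrow = spec$n_time))
  }
  data.frame(time = seq_len(spec$n_time),
             var_x = apply(out, 2, stats::var))
}
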