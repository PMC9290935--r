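# Static and lagged-dependent-variable estimators. These are ordinary
# (mixed) linear models and stand on stats::lm / lme4::lmer; the point of
# carrying them here is paired comparison against the dynamical estimators
# on identical panels.

# Shared checks for the regression estimators; returns the panel ordered by
# subject and time with x/y resolved to columns "X"/"Y".
.prep_regression_panel <- function(panel, x, y, min_rows = 2L) {
  for (v in c("subject", "time", x, y)) {
    if (!v %in% names(panel))
      stop("panel lacks required column `", v, "`", call. = FALSE)
  }
  if (nrow(panel) < min_rows)
    stop("panel has fewer than ", min_rows, " records", call. = FALSE)
  d <- as.data.frame(panel)[order(panel$subject, panel$time), ]
  d$X <- d[[x]]
  d$Y <- d[[y]]
  if (stats::var(d$X) < 1e-12)
    stop("non-estimable: X is constant across the panel", call. = FALSE)
  wv <- tapply(d$X, d$subject, stats::var)
  if (length(unique(d$subject)) > 1L && any(wv < 1e-12, na.rm = TRUE))
    warning("some subjects have constant X; they inform intercepts and ",
            "variance components only", call. = FALSE)
  d
}

# ML fits only need the factorization, not lme4's post-fit derivative
# check; skipping it roughly halves the per-fit cost in Monte-Carlo loops
# without changing estimates or Wald SEs.
.lmer_ctrl <- function() lme4::lmerControl(calc.derivs = FALSE)

# Extract (b_hat, se_b, loglik, converged) from an lmer fit; slope term `term`.
.lmer_slope <- function(fm, term) {
  fe <- lme4::fixef(fm)
  vc <- as.matrix(stats::vcov(fm))
  msgs <- fm@optinfo$conv$lme4$messages
  list(b = unname(fe[[term]]),
       se = sqrt(vc[term, term]),
       loglik = as.numeric(stats::logLik(fm)),
       converged = fm@optinfo$conv$opt == 0 && is.null(msgs))
}

#' Static cross-sectional (mixed) regression of Y on X
#'
#' The conventional static model that ignores cross-lags: for panels of
#' several subjects, a linear mixed model
#' `Y ~ 1 + b*X + (1 | subject)` fitted by maximum likelihood; for a single
#' subject, ordinary least squares of `Y` on `X`. This estimator treats `X`
#' as exogenous and is therefore biased on short cross-lagged series, in the
#' direction opposite to the sign of the cross-lag, and additionally inflated
#' by positive among-subject covariance.
#'
#' @param panel Panel data.frame.
#' @param x,y Column names of the covariate and response (defaults `"X"`,
#'   `"Y"`; pass `"X_obs"`/`"Y_obs"` to fit on error-contaminated values).
#' @return A `crosslag_fit`.
#' @export
fit_stat_overall <- function(panel, x = "X", y = "Y") {
  d <- .prep_regression_panel(panel, x, y)
  S <- length(unique(d$subject))
  if (S == 1L) {
    fm <- stats::lm(Y ~ X, data = d)
    cf <- summary(fm)$coefficients
    est <- c(a = unname(stats::coef(fm)[1]), b = unname(stats::coef(fm)[2]),
             sigma_eps = summary(fm)$sigma)
    res <- list(b = est[["b"]], se = cf["X", "Std. Error"],
                loglik = as.numeric(stats::logLik(fm)), converged = TRUE)
  } else {
    fm <- lme4::lmer(Y ~ X + (1 | subject), data = d, REML = FALSE,
                     control = .lmer_ctrl())
    res <- .lmer_slope(fm, "X")
    vc <- as.data.frame(lme4::VarCorr(fm))
    est <- c(a = unname(lme4::fixef(fm)[1]), b = res$b,
             sd_subject = vc$sdcor[1], sigma_eps = vc$sdcor[2])
  }
  new_crosslag_fit("STAT_OVERALL", estimates = est, se_b = res$se,
                   loglik = res$loglik, converged = res$converged,
                   n_subjects = S, n_obs = nrow(d),
                   sd_x = stats::sd(d$X), sd_y = stats::sd(d$Y))
}

#' Static within-subject regression (within-subject centring)
#'
#' As [fit_stat_overall()], but the covariate is replaced by its
#' within-subject-centred version, filtering out the masking effect of
#' among-subject covariance and isolating the average within-subject
#' association. For a single subject, the slope is identical to
#' [fit_stat_overall()] (centring only shifts the intercept). On short
#' cross-lagged series, the within-subject focus reinstates the bias
#' opposite to the cross-lag sign.
#'
#' @inheritParams fit_stat_overall
#' @return A `crosslag_fit`.
#' @export
fit_stat_within <- function(panel, x = "X", y = "Y") {
  d <- .prep_regression_panel(panel, x, y)
  d <- within_subject_centre(d, "X")
  S <- length(unique(d$subject))
  if (S == 1L) {
    fm <- stats::lm(Y ~ X_within, data = d)
    cf <- summary(fm)$coefficients
    est <- c(a = unname(stats::coef(fm)[1]), b = unname(stats::coef(fm)[2]),
             sigma_eps = summary(fm)$sigma)
    res <- list(b = est[["b"]], se = cf["X_within", "Std. Error"],
                loglik = as.numeric(stats::logLik(fm)), converged = TRUE)
  } else {
    fm <- lme4::lmer(Y ~ X_within + (1 | subject), data = d, REML = FALSE,
                     control = .lmer_ctrl())
    res <- .lmer_slope(fm, "X_within")
    vc <- as.data.frame(lme4::VarCorr(fm))
    est <- c(a = unname(lme4::fixef(fm)[1]), b = res$b,
             sd_subject = vc$sdcor[1], sigma_eps = vc$sdcor[2])
  }
  new_crosslag_fit("STAT_WITHIN", estimates = est, se_b = res$se,
                   loglik = res$loglik, converged = res$converged,
                   n_subjects = S, n_obs = nrow(d),
                   sd_x = stats::sd(d$X), sd_y = stats::sd(d$Y))
}

#' Lagged-dependent-variable mixed model
#'
#' Accounts for the response autocorrelation that a cross-lag induces by
#' adding the within-subject-centred lagged response as a covariate:
#' `Y_t ~ 1 + b*X_t + gamma*centred(Y_{t-1}) + (1 | subject)`. Rows with an
#' undefined lag (the first step of each subject) are dropped. The lag term
#' is centred within subject so it absorbs within-subject temporal
#' dependency rather than among-subject level differences.
#'
#' @inheritParams fit_stat_overall
#' @return A `crosslag_fit` whose estimates include the auto-lag coefficient
#'   `gamma`.
#' @export
fit_dyn_ldvm <- function(panel, x = "X", y = "Y") {
  d <- .prep_regression_panel(panel, x, y)
  d$Y_lag <- stats::ave(d$Y, d$subject,
                        FUN = function(v) c(NA_real_, v[-length(v)]))
  nlag <- tapply(!is.na(d$Y_lag), d$subject, sum)
  if (any(nlag < 1L))
    stop("subject(s) ", paste(names(nlag)[nlag < 1L], collapse = ", "),
         " have no usable observations after lagging (need >= 2 time steps)",
         call. = FALSE)
  d <- d[!is.na(d$Y_lag), , drop = FALSE]
  d <- within_subject_centre(d, "Y_lag")
  S <- length(unique(d$subject))
  if (S == 1L) {
    fm <- stats::lm(Y ~ X + Y_lag_within, data = d)
    cf <- summary(fm)$coefficients
    est <- c(a = unname(stats::coef(fm)[1]), b = unname(stats::coef(fm)[2]),
             gamma = unname(stats::coef(fm)[3]),
             sigma_eps = summary(fm)$sigma)
    res <- list(b = est[["b"]], se = cf["X", "Std. Error"],
                loglik = as.numeric(stats::logLik(fm)), converged = TRUE)
  } else {
    fm <- lme4::lmer(Y ~ X + Y_lag_within + (1 | subject), data = d,
                     REML = FALSE, control = .lmer_ctrl())
    res <- .lmer_slope(fm, "X")
    vc <- as.data.frame(lme4::VarCorr(fm))
    est <- c(a = unname(lme4::fixef(fm)[1]), b = res$b,
             gamma = unname(lme4::fixef(fm)[["Y_lag_within"]]),
             sd_subject = vc$sdcor[1], sigma_eps = vc$sdcor[2])
  }
  new_crosslag_fit("DYN_LDVM", estimates = est, se_b = res$se,
                   loglik = res$loglik, converged = res$converged,
                   n_subjects = S, n_obs = nrow(d),
                   sd_x = stats::sd(d$X), sd_y = stats::sd(d$Y))
}
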