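# Shared test utilities.

# A tiny hand-built balanced panel (no generating spec attached).
make_panel <- function(subjects, values_x, values_y) {
  Tn <- length(values_x[[1]])
  data.frame(
    subject = rep(subjects, each = Tn),
    time = rep(seq_len(Tn), times = length(subjects)),
    X = unlist(values_x),
    Y = unlist(values_y)
  )
}

# Suppress lme4 boundary-fit chatter in Monte-Carlo loops.
quietly <- function(expr) suppressWarnings(suppressMessages(expr))

# Independent conditional log-likelihood of the cross-lagged system given
# random-intercept draws, built directly from the model equations and
# conditioning on each subject's first X observation. `mu`, `nu` are
# (n_draws x S) matrices; returns a vector of length n_draws. Deliberately
# shares no code with the package's stacked-covariance evaluation: it is
# the integrand for brute-force Monte-Carlo integration oracles.
cond_loglik_given_re <- function(panel, params, structure, mu, nu) {
  p <- params
  subs <- unique(panel$subject)
  ll <- numeric(nrow(mu))
  for (i in seq_along(subs)) {
    d <- panel[panel$subject == subs[i], ]
    d <- d[order(d$time), ]
    Tn <- nrow(d)
    # Y-equation: residual r_t - mu, all t
    ry <- d$Y - p$a - p$b * d$X
    ll <- ll - Tn * log(p$sigma_eps * sqrt(2 * pi)) -
      (sum(ry^2) - 2 * mu[, i] * sum(ry) + Tn * mu[, i]^2) /
        (2 * p$sigma_eps^2)
    # X-equation, t >= 2
    rx <- d$X[-1] - p$c - p$d * d$Y[-Tn]
    if (structure != "tradeoff") rx <- rx - p$f * d$Z[-Tn] * d$X[-Tn]
    nx <- if (structure == "tradeoff") nu[, i] else 0
    ll <- ll - (Tn - 1) * log(p$sigma_kappa * sqrt(2 * pi)) -
      (sum(rx^2) - 2 * nx * sum(rx) + (Tn - 1) * nx^2) /
        (2 * p$sigma_kappa^2)
    # Z-equation
    if (structure %in% c("grouplive", "density")) {
      rz <- d$Z - p$g
      nz <- if (structure == "grouplive") nu[, i] else 0
      ll <- ll - Tn * log(p$sigma_lambda * sqrt(2 * pi)) -
        (sum(rz^2) - 2 * nz * sum(rz) + Tn * nz^2) / (2 * p$sigma_lambda^2)
    }
  }
  ll
}

# log of the Monte-Carlo average of exp(ll), with its delta-method SE.
log_mean_exp <- function(ll) {
  m <- max(ll)
  w <- exp(ll - m)
  est <- m + log(mean(w))
  se <- stats::sd(w) / (mean(w) * sqrt(length(w)))
  c(est = est, se = se)
}
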