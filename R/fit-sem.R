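# Dynamical structural equation model (DYN_SEM): joint maximum-likelihood
# estimation of the multi-equation cross-lagged system with correlated
# among-subject random intercepts.
#
# Conditional on each subject's first observation and on the observed lagged
# covariates, the system
#   Y_t = a + b X_t            + mu_s + eps_t
#   X_t = c + d Y_{t-1} [+ f Z_{t-1} X_{t-1}] [+ nu_s] + kap_t
#   [Z_t = g [+ nu_s] + lam_t]
# factorizes along time, so given (mu_s, nu_s) the stacked responses are
# independent Gaussians with equation-specific residual variances. The
# random intercepts integrate out analytically: each subject's stacked
# residual vector is multivariate normal with covariance
#   V = R + U Omega U',
# where R is the diagonal of residual variances and U the 0/1 loading matrix
# of (mu, nu) onto the equations. The marginal likelihood below evaluates
# exactly that, shared across subjects of equal series length, and is
# maximized by quasi-Newton on an unconstrained parameterization (log SDs,
# atanh correlation) so the estimated Omega is positive definite by
# construction.
#
# Initial condition: with random intercepts present, the first observation
# X_1 is itself correlated with (mu_s, nu_s) — under the stationary Gaussian
# process, X_1 | (mu, nu) is normal with mean linear in the intercepts.
# Simply conditioning on X_1 would therefore be inconsistent at fixed T (the
# classic dynamic-panel initial-conditions problem). The model instead
# includes an X_1 row with free mean, free loadings on (mu, nu) and a free
# residual SD, which represents that joint distribution exactly — the same
# device as letting first observations correlate freely with the latent
# intercepts in a wide-format SEM. Without random intercepts the X_1 row
# carries free, unshared parameters only, which is equivalent to
# conditioning on X_1, so it is dropped.

# Row-block ids: 1 = Y-equation, 2 = X-equation, 3 = Z-equation, 4 = X_1 row.

# Assemble per-T-group response/covariate matrices in canonical row order
# (Y rows t=1..T, X rows t=2..T, Z rows t=1..T), columns = subjects.
.sem_build <- function(panel, structure, x = "X", y = "Y", z = "Z",
                       include_crosslag = TRUE, model_initial = TRUE) {
  structure <- match.arg(structure, c("tradeoff", "grouplive", "density"))
  need <- c("subject", "time", x, y, if (structure != "tradeoff") z)
  for (v in need) {
    if (!v %in% names(panel))
      stop("panel lacks required column `", v, "` for the ", structure,
           " structure", call. = FALSE)
  }
  d <- as.data.frame(panel)[order(panel$subject, panel$time), ]
  d$X <- d[[x]]; d$Y <- d[[y]]
  if (structure != "tradeoff") d$Z <- d[[z]]
  Ts <- tapply(d$time, d$subject, length)
  if (any(Ts < 2L))
    stop("every subject needs >= 2 time steps", call. = FALSE)
  S <- length(Ts)
  has_z <- structure != "tradeoff"
  # random-effect attachment; dropped entirely for a single series
  re <- if (S == 1L || structure == "density") "none" else structure
  init_row <- model_initial && re != "none"
  coef_names <- c("a", "b", "c", if (include_crosslag) "d",
                  if (has_z) c("f", "g"))
  groups <- lapply(split(d, Ts[as.character(d$subject)]), function(dd) {
    Tn <- length(unique(dd$time))
    Sg <- nrow(dd) / Tn
    Ym <- matrix(dd$Y, nrow = Tn)
    Xm <- matrix(dd$X, nrow = Tn)
    Zm <- if (has_z) matrix(dd$Z, nrow = Tn) else NULL
    W <- if (has_z) Zm[-Tn, , drop = FALSE] * Xm[-Tn, , drop = FALSE]
         else NULL
    n <- 2L * Tn - 1L + (if (has_z) Tn else 0L) +
      (if (init_row) 1L else 0L)
    block <- c(rep(1L, Tn), rep(2L, Tn - 1L), if (has_z) rep(3L, Tn),
               if (init_row) 4L)
    U <- NULL
    if (re != "none") {
      U <- matrix(0, n, 2)
      U[block == 1L, 1] <- 1
      U[block == if (re == "tradeoff") 2L else 3L, 2] <- 1
      # the X_1 row's loadings are free parameters, filled per evaluation
    }
    list(Tn = Tn, Sg = Sg, n = n, block = block, U = U,
         Ym = Ym, Xm = Xm, Zm = Zm, W = W,
         subjects = unique(dd$subject))
  })
  list(structure = structure, groups = groups, coef_names = coef_names,
       has_z = has_z, re = re, S = S, N = nrow(d),
       include_crosslag = include_crosslag,
       sd_x = stats::sd(d$X), sd_y = stats::sd(d$Y))
}

# Exact marginal negative log-likelihood. `beta` named per coef_names,
# `sigmas` = c(sigma_eps, sigma_kappa[, sigma_lambda]), `Omega` 2x2 or NULL,
# `init` = list(m1, lmu, lnu, s1) for the X_1 row (structures with random
# intercepts only).
.sem_nll <- function(build, beta, sigmas, Omega, init = NULL) {
  b <- as.list(beta)
  if (!build$include_crosslag) b$d <- 0
  nll <- 0
  for (gr in build$groups) {
    Tn <- gr$Tn
    rY <- gr$Ym - b$a - b$b * gr$Xm
    rX <- gr$Xm[-1L, , drop = FALSE] - b$c -
      b$d * gr$Ym[-Tn, , drop = FALSE]
    if (build$has_z) rX <- rX - b$f * gr$W
    Rm <- rbind(rY, rX)
    if (build$has_z) Rm <- rbind(Rm, gr$Zm - b$g)
    s2 <- c(sigmas[1]^2, sigmas[2]^2, sigmas[3]^2, NA_real_)[gr$block]
    if (build$re != "none") {
      U <- gr$U
      if (!is.null(init) && any(gr$block == 4L)) {
        Rm <- rbind(Rm, gr$Xm[1L, , drop = FALSE] - init$m1)
        s2[gr$block == 4L] <- init$s1^2
        U[gr$block == 4L, ] <- c(init$lmu, init$lnu)
      }
      V <- diag(s2, gr$n) + U %*% Omega %*% t(U)
      ch <- tryCatch(chol(V), error = function(e) NULL)
      if (is.null(ch)) return(1e10)
      zq <- backsolve(ch, Rm, transpose = TRUE)
      nll <- nll + 0.5 * (gr$Sg * gr$n * log(2 * pi) +
                            gr$Sg * 2 * sum(log(diag(ch))) +
                            sum(zq^2))
    } else {
      nll <- nll + 0.5 * (gr$Sg * gr$n * log(2 * pi) +
                            gr$Sg * sum(log(s2)) +
                            sum(sweep(Rm^2, 1, s2, "/")))
    }
  }
  if (!is.finite(nll)) 1e10 else nll
}

# Moment-based starting values: per-equation OLS plus among-subject spread
# of mean residuals for the random-intercept SDs.
.sem_start <- function(build) {
  gr1 <- build$groups
  yv <- unlist(lapply(gr1, function(g) as.vector(g$Ym)))
  xv_on_y <- unlist(lapply(gr1, function(g) as.vector(g$Xm)))
  cf_y <- stats::coef(stats::lm.fit(cbind(1, xv_on_y), yv))
  xresp <- unlist(lapply(gr1, function(g) as.vector(g$Xm[-1L, , drop = FALSE])))
  ylag <- unlist(lapply(gr1, function(g) as.vector(g$Ym[-g$Tn, , drop = FALSE])))
  Mx <- cbind(rep(1, length(xresp)), if (build$include_crosslag) ylag,
              if (build$has_z) unlist(lapply(gr1, function(g) as.vector(g$W))))
  cf_x <- stats::coef(stats::lm.fit(Mx, xresp))
  beta <- c(a = unname(cf_y[1]), b = unname(cf_y[2]), c = unname(cf_x[1]))
  k <- 2L
  if (build$include_crosslag) { beta["d"] <- unname(cf_x[k]); k <- k + 1L }
  if (build$has_z) {
    beta["f"] <- unname(cf_x[k])
    zv <- unlist(lapply(gr1, function(g) as.vector(g$Zm)))
    beta["g"] <- mean(zv)
  }
  res_y <- yv - cbind(1, xv_on_y) %*% cf_y
  res_x <- xresp - Mx %*% cf_x
  sig <- c(max(stats::sd(res_y), 1e-3), max(stats::sd(res_x), 1e-3),
           if (build$has_z) max(stats::sd(zv - mean(zv)), 1e-3) else 1e-3)
  re_start <- c(log_sd_mu = log(0.5 * sig[1] + 1e-3),
                log_sd_nu = log(0.5 * sig[if (build$re == "tradeoff") 2 else 3] +
                                  1e-3),
                atanh_rho = 0)
  x1 <- unlist(lapply(gr1, function(g) g$Xm[1L, ]))
  init_start <- c(m1 = mean(x1), lmu = 0, lnu = 0,
                  log_s1 = log(max(stats::sd(x1), 1e-2)))
  list(beta = beta[build$coef_names], sigmas = sig, re = re_start,
       init = init_start)
}

#' Dynamical structural equation model with correlated random intercepts
#'
#' Jointly maximizes the exact marginal likelihood of the multi-equation
#' cross-lagged system (the `Y`, `X` and, where applicable, `Z` equations),
#' integrating the correlated among-subject random intercepts
#' `(mu_s, nu_s) ~ MVN(0, Omega)` out analytically. Each subject's first
#' observation `X_1` is modelled with a free mean, free loadings on the
#' random intercepts and a free residual SD — exact for the stationary
#' Gaussian process — rather than conditioned on, which would be
#' inconsistent at fixed series length (the dynamic-panel initial-conditions
#' problem). The correlated intercepts are the only parameters shared
#' between the `Y` equation and the cross-lag equation, and are what lets the
#' cross-lag inform the estimate of the contemporaneous effect `b`; for a
#' single series all random-intercept terms are dropped, the equations
#' decouple, and the `b` estimate coincides with [fit_stat_overall()].
#'
#' Structures:
#' * `"tradeoff"` — `X_t = c + d*Y_{t-1} + nu_s + kap`; `nu` attaches to `X`.
#' * `"grouplive"` — `X_t = c + d*Y_{t-1} + f*Z_{t-1}*X_{t-1} + kap`;
#'   `Z_t = g + nu_s + lam`; `nu` attaches to `Z`.
#' * `"density"` — as `grouplive` but without random intercepts (single
#'   population; multiple subjects are treated as independent replicate
#'   populations).
#'
#' Optimization is quasi-Newton (BFGS) on an unconstrained reparameterization
#' (log residual SDs, log random-intercept SDs, atanh correlation), so the
#' estimated `Omega` is positive definite by construction. Starting values
#' are per-equation least squares and sample-moment SDs. Non-convergence is
#' flagged in the result, not raised. Wald standard errors come from the
#' numerical Hessian at the optimum.
#'
#' @param panel Panel data.frame with `subject`, `time`, covariate and
#'   response columns (plus `Z` for the grouplive/density structures).
#' @param structure `"tradeoff"`, `"grouplive"` or `"density"`; inferred from
#'   the panel's generating [process_spec()] when available.
#' @param x,y,z Column names to fit on (pass `"X_obs"`/`"Y_obs"` for
#'   error-contaminated values).
#' @param include_crosslag Set `FALSE` to drop the `d*Y_{t-1}` path (for
#'   misspecification studies; doing so reinstates static-model bias).
#' @param correlated_intercepts Set `FALSE` to force `cor(mu, nu) = 0`
#'   (likewise reinstates bias).
#' @param se Compute the Wald standard error of `b` from the numerical
#'   Hessian (disable in large Monte-Carlo loops that only need the point
#'   estimate).
#' @param control Passed to [stats::optim()] (BFGS); defaults
#'   `maxit = 500`, `reltol = 1e-10`.
#' @return A `crosslag_fit` with estimates of `a`-`g`, residual SDs and the
#'   `Omega` elements (`sd_mu`, `sd_nu`, `cor_mu_nu`, `cov_mu_nu`).
#' @examples
#' p <- simulate_panel(process_spec("tradeoff_multi", n_subjects = 80, seed = 7))
#' fit_dyn_sem(p, "tradeoff")
#' @export
fit_dyn_sem <- function(panel, structure = NULL, x = "X", y = "Y", z = "Z",
                        include_crosslag = TRUE, correlated_intercepts = TRUE,
                        se = TRUE,
                        control = list(maxit = 500, reltol = 1e-10)) {
  structure <- .infer_structure(panel, structure)
  build <- .sem_build(panel, structure, x, y, z, include_crosslag)
  st <- .sem_start(build)
  p <- length(st$beta)
  nsig <- if (build$has_z) 3L else 2L
  has_re <- build$re != "none"
  nre <- if (!has_re) 0L else if (correlated_intercepts) 3L else 2L
  par0 <- c(st$beta, log(st$sigmas[seq_len(nsig)]),
            if (has_re) st$re[seq_len(nre)],
            if (has_re) st$init)
  unpack <- function(par) {
    beta <- par[seq_len(p)]
    names(beta) <- build$coef_names
    sig <- exp(par[p + seq_len(nsig)])
    sigmas <- c(sig, if (nsig == 2L) 1)[1:3]
    Omega <- NULL
    init <- NULL
    if (has_re) {
      sd_mu <- exp(par[p + nsig + 1L])
      sd_nu <- exp(par[p + nsig + 2L])
      rho <- if (correlated_intercepts) tanh(par[p + nsig + 3L]) else 0
      Omega <- matrix(c(sd_mu^2, rho * sd_mu * sd_nu,
                        rho * sd_mu * sd_nu, sd_nu^2), 2, 2)
      k <- p + nsig + nre
      init <- list(m1 = par[k + 1L], lmu = par[k + 2L], lnu = par[k + 3L],
                   s1 = exp(par[k + 4L]))
    }
    list(beta = beta, sigmas = sigmas, Omega = Omega, init = init)
  }
  fn <- function(par) {
    u <- unpack(par)
    .sem_nll(build, u$beta, u$sigmas, u$Omega, u$init)
  }
  # forward-difference gradient: p + 1 evaluations instead of optim's 2p
  gr <- function(par) {
    f0 <- fn(par)
    vapply(seq_along(par), function(i) {
      h <- 1e-7 * max(1, abs(par[i]))
      p2 <- par
      p2[i] <- p2[i] + h
      (fn(p2) - f0) / h
    }, numeric(1))
  }
  opt <- stats::optim(par0, fn, gr, method = "BFGS", control = control)
  u <- unpack(opt$par)
  bidx <- which(build$coef_names == "b")
  se_b <- NA_real_
  hess_ok <- !se
  if (se) {
    hess <- tryCatch(stats::optimHess(opt$par, fn), error = function(e) NULL)
    if (!is.null(hess)) {
      vc <- tryCatch(solve(hess), error = function(e) NULL)
      if (!is.null(vc) && is.finite(vc[bidx, bidx]) && vc[bidx, bidx] > 0) {
        se_b <- sqrt(vc[bidx, bidx])
        hess_ok <- TRUE
      }
    }
  }
  est <- u$beta
  est["sigma_eps"] <- u$sigmas[1]
  est["sigma_kappa"] <- u$sigmas[2]
  if (build$has_z) est["sigma_lambda"] <- u$sigmas[3]
  if (has_re) {
    est["sd_mu"] <- sqrt(u$Omega[1, 1])
    est["sd_nu"] <- sqrt(u$Omega[2, 2])
    est["cor_mu_nu"] <- u$Omega[1, 2] / (est[["sd_mu"]] * est[["sd_nu"]])
    est["cov_mu_nu"] <- u$Omega[1, 2]
    est["x1_mean"] <- u$init$m1
    est["x1_load_mu"] <- u$init$lmu
    est["x1_load_nu"] <- u$init$lnu
    est["x1_sd"] <- u$init$s1
  }
  new_crosslag_fit("DYN_SEM", structure = structure, estimates = est,
                   se_b = se_b, loglik = -opt$value,
                   converged = opt$convergence == 0 && hess_ok,
                   n_subjects = build$S, n_obs = build$N,
                   sd_x = build$sd_x, sd_y = build$sd_y,
                   extra = list(omega = u$Omega, optim = opt))
}

.infer_structure <- function(panel, structure) {
  if (!is.null(structure))
    return(match.arg(structure, c("tradeoff", "grouplive", "density")))
  spec <- attr(panel, "spec")
  if (inherits(spec, "process_spec")) {
    return(switch(spec$kind,
                  tradeoff_single = , tradeoff_multi = "tradeoff",
                  density_single = "density",
                  grouplive_multi = "grouplive"))
  }
  stop("`structure` must be given for panels without a generating spec",
       call. = FALSE)
}

#' Evaluate the DYN_SEM marginal log-likelihood at fixed parameters
#'
#' Computes the exact marginal log-likelihood of the dynamical SEM at given
#' parameter values without any optimization — chiefly useful for validating
#' the analytic integration over the random intercepts against brute-force
#' alternatives.
#'
#' @inheritParams fit_dyn_sem
#' @param params Named list with `a`, `b`, `c`, `d` (and `f`, `g` for
#'   grouplive/density), `sigma_eps`, `sigma_kappa` (and `sigma_lambda`), and
#'   a 2x2 `omega` (ignored where the structure carries no random effects).
#'   If `m1`, `lmu`, `lnu`, `s1` are supplied the `X_1` row is modelled with
#'   them; otherwise the likelihood conditions on each subject's first
#'   observation.
#' @return The marginal log-likelihood (a scalar).
#' @export
dyn_sem_loglik <- function(panel, structure = NULL, params, x = "X", y = "Y",
                           z = "Z") {
  structure <- .infer_structure(panel, structure)
  model_initial <- !is.null(params$m1)
  build <- .sem_build(panel, structure, x, y, z, include_crosslag = TRUE,
                      model_initial = model_initial)
  beta <- unlist(params[build$coef_names])
  sigmas <- c(params$sigma_eps, params$sigma_kappa,
              if (!is.null(params$sigma_lambda)) params$sigma_lambda else 1)
  Omega <- if (build$re != "none") params$omega else NULL
  init <- if (model_initial && build$re != "none")
    list(m1 = params$m1, lmu = params$lmu, lnu = params$lnu, s1 = params$s1)
  -.sem_nll(build, beta, sigmas, Omega, init)
}
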