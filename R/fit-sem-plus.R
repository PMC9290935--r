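# Errors-in-variables dynamical SEM (DYN_SEM+): the cross-lagged system with
# latent true values X', Y' observed through known-variance Gaussian
# measurement error,
#   X_obs = X' + theta,  Y_obs = Y' + eta.
#
# Substituting the Y-equation into the X-equation makes the latent X' an
# AR(1) process,
#   X'_t = (c + d a) + phi_t X'_{t-1} + d mu [+ nu] + d eps_{t-1} + kap_t,
# with phi_t = b d for the trade-off structure and phi_t = b d + f Z_{t-1}
# for the group-living / density structures. Because Z carries no
# measurement error, phi_t is fully observed and the entire latent system is
# linear-Gaussian: each subject's observed vector (Y_obs, X_obs [, Z]) is
# multivariate normal with mean and covariance built by propagating the
# independent noise basis (initial deviation, eps_t, kap_t) through the
# recursion, plus L Omega L' for the random intercepts and the known
# measurement-error variances on the diagonal. The marginal likelihood is
# evaluated exactly and maximized by BFGS — no Monte-Carlo integration is
# involved.
#
# Initial condition: for the trade-off structure X'_1 gets its stationary
# distribution (mean and variance implied by the parameters, including the
# random intercepts). For the group-living / density structures the
# coefficient is time-varying, so X'_1 gets a free N(m1, s1^2) distribution,
# with a free loading on mu for group living.

# Per-subject observed-vector mean and covariance under the latent model.
# Returns list(m, V) for subject index s of `dat`.
.semplus_subject_mv <- function(dat, th, s) {
  Tn <- dat$Tn
  nb <- 1L + Tn + (Tn - 1L)
  Cx <- matrix(0, Tn, nb)
  mx <- numeric(Tn)
  Lx <- matrix(0, Tn, 2)
  bd <- th$b * th$d
  if (dat$structure == "tradeoff") {
    if (abs(bd) >= 0.999) return(NULL)
    mx[1] <- (th$c + th$d * th$a) / (1 - bd)
    Lx[1, ] <- c(th$d, 1) / (1 - bd)
    v0 <- (th$d^2 * th$sigma_eps^2 + th$sigma_kappa^2) / (1 - bd^2)
    Cx[1, 1] <- sqrt(v0)
    phi <- rep(bd, Tn)
  } else {
    mx[1] <- th$m1
    Cx[1, 1] <- th$s1
    if (dat$structure == "grouplive") Lx[1, ] <- c(th$q_mu, th$q_nu)
    phi <- bd + th$f * c(0, dat$Z[-Tn, s])
  }
  nu_in_x <- dat$structure == "tradeoff"
  for (t in 2:Tn) {
    mx[t] <- th$c + th$d * th$a + phi[t] * mx[t - 1]
    Cx[t, ] <- phi[t] * Cx[t - 1, ]
    Cx[t, 1L + (t - 1L)] <- Cx[t, 1L + (t - 1L)] + th$d * th$sigma_eps
    Cx[t, 1L + Tn + (t - 1L)] <- th$sigma_kappa
    Lx[t, ] <- phi[t] * Lx[t - 1, ] + c(th$d, if (nu_in_x) 1 else 0)
  }
  Cy <- th$b * Cx
  Cy[cbind(1:Tn, 1L + 1:Tn)] <- Cy[cbind(1:Tn, 1L + 1:Tn)] + th$sigma_eps
  my <- th$a + th$b * mx
  Ly <- th$b * Lx
  Ly[, 1] <- Ly[, 1] + 1
  Cfull <- rbind(Cy, Cx)
  V <- tcrossprod(Cfull)
  diag(V) <- diag(V) + c(rep(th$tau_y, Tn), rep(th$tau_x, Tn))
  m <- c(my, mx)
  L <- rbind(Ly, Lx)
  if (dat$has_z) {
    nz <- Tn
    Vz <- diag(rep(th$sigma_lambda^2, nz), nz)
    V <- rbind(cbind(V, matrix(0, 2 * Tn, nz)),
               cbind(matrix(0, nz, 2 * Tn), Vz))
    m <- c(m, rep(th$g, nz))
    Lz <- matrix(0, nz, 2)
    if (dat$structure == "grouplive") Lz[, 2] <- 1
    L <- rbind(L, Lz)
  }
  if (!is.null(th$Omega)) V <- V + L %*% th$Omega %*% t(L)
  list(m = m, V = V)
}

.semplus_nll <- function(dat, th) {
  if (dat$structure == "tradeoff") {
    # V and m identical across subjects: factor once, solve all residuals
    mv <- .semplus_subject_mv(dat, th, 1L)
    if (is.null(mv)) return(1e10)
    ch <- tryCatch(chol(mv$V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    n <- length(mv$m)
    Rm <- dat$obs - mv$m
    zq <- backsolve(ch, Rm, transpose = TRUE)
    nll <- 0.5 * (dat$S * n * log(2 * pi) + dat$S * 2 * sum(log(diag(ch))) +
                    sum(zq^2))
    return(if (is.finite(nll)) nll else 1e10)
  }
  .semplus_nll_z(dat, th)
}

# Group-living / density structures: the AR coefficient phi_t = b d +
# f Z_{t-1} varies per subject, so the propagation weights are built for all
# subjects at once (vectorized over subjects) and the per-subject Gaussian
# factorizations done in a tight loop. For the density structure (no random
# intercepts) the Z-equation is independent of the (Y, X) block and is
# evaluated in closed form.
.semplus_nll_z <- function(dat, th) {
  Tn <- dat$Tn
  S <- dat$S
  nb <- 2L * Tn # xi0, eps_1..T, kap_2..T
  grouplive <- dat$structure == "grouplive"
  if (grouplive && is.null(th$Omega)) th$Omega <- matrix(0, 2, 2)
  phi <- th$b * th$d + th$f * dat$Z # phi[t, s] uses Z[t-1, ]; shift below
  cda <- th$c + th$d * th$a
  mx <- matrix(0, Tn, S)
  mx[1, ] <- th$m1
  # propagation weights, stored column-major per subject: row (j-1)*Tn + t
  Call <- matrix(0, Tn * nb, S)
  Mprev <- matrix(0, S, nb)
  Mprev[, 1] <- th$s1
  Call[1L, ] <- th$s1
  if (grouplive) {
    Lmu <- matrix(0, Tn, S)
    Lmu[1, ] <- th$q_mu
    Lnu <- matrix(0, Tn, S) # nu reaches X' only via its initial condition
    Lnu[1, ] <- th$q_nu
  }
  dse <- th$d * th$sigma_eps
  rows_of <- function(t) (0:(nb - 1L)) * Tn + t
  for (t in 2:Tn) {
    ph <- phi[t - 1L, ]
    M <- ph * Mprev
    M[, t] <- M[, t] + dse          # eps_{t-1} is basis column 1 + (t-1)
    M[, Tn + t] <- th$sigma_kappa   # kap_t is basis column 1 + Tn + (t-1)
    Call[rows_of(t), ] <- t(M)
    mx[t, ] <- cda + ph * mx[t - 1L, ]
    if (grouplive) {
      Lmu[t, ] <- ph * Lmu[t - 1L, ] + th$d
      Lnu[t, ] <- ph * Lnu[t - 1L, ]
    }
    Mprev <- M
  }
  my <- th$a + th$b * mx
  idx_eps <- cbind(1:Tn, 1L + 1:Tn)
  tau_diag <- c(rep(th$tau_y, Tn), rep(th$tau_x, Tn))
  nobs <- if (grouplive) 3L * Tn else 2L * Tn
  ii <- seq_len(2L * Tn)
  nll <- 0.5 * S * nobs * log(2 * pi)
  if (grouplive) {
    Vbig <- matrix(0, 3L * Tn, 3L * Tn)
    zi <- (2L * Tn + 1L):(3L * Tn)
    Lsub <- matrix(0, 3L * Tn, 2L)
    Lsub[zi, 2L] <- 1
  }
  Cfull <- matrix(0, 2L * Tn, nb)
  for (s in seq_len(S)) {
    Cx <- matrix(Call[, s], Tn, nb)
    Cy <- th$b * Cx
    Cy[idx_eps] <- Cy[idx_eps] + th$sigma_eps
    Cfull[1:Tn, ] <- Cy
    Cfull[(Tn + 1L):(2L * Tn), ] <- Cx
    V <- tcrossprod(Cfull)
    diag(V) <- diag(V) + tau_diag
    if (grouplive) {
      Vbig[ii, ii] <- V
      Vbig[zi, zi] <- diag(rep(th$sigma_lambda^2, Tn), Tn)
      Lsub[1:Tn, 1L] <- th$b * Lmu[, s] + 1
      Lsub[(Tn + 1L):(2L * Tn), 1L] <- Lmu[, s]
      Lsub[1:Tn, 2L] <- th$b * Lnu[, s]
      Lsub[(Tn + 1L):(2L * Tn), 2L] <- Lnu[, s]
      Vs <- Vbig + Lsub %*% th$Omega %*% t(Lsub)
      r <- dat$obs[, s] - c(my[, s], mx[, s], rep(th$g, Tn))
    } else {
      Vs <- V
      r <- dat$obs[ii, s] - c(my[, s], mx[, s])
    }
    ch <- tryCatch(chol(Vs), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    zq <- backsolve(ch, r, transpose = TRUE)
    nll <- nll + sum(log(diag(ch))) + 0.5 * sum(zq^2)
  }
  if (!grouplive) {
    # independent Z-equation, closed form
    nll <- nll - sum(stats::dnorm(dat$Z, th$g, max(th$sigma_lambda, 1e-8),
                                  log = TRUE))
  }
  if (is.finite(nll)) nll else 1e10
}

#' Errors-in-variables dynamical SEM with known measurement-error variances
#'
#' Extends [fit_dyn_sem()] by treating the true `X` and `Y` as latent
#' variables observed through independent Gaussian measurement error whose
#' variances are known from external sources (e.g. repeated measurements) and
#' are supplied, not estimated. The exact marginal likelihood of the full
#' linear-Gaussian system — latent cross-lagged process, correlated random
#' intercepts, measurement layer — is maximized directly; see the file-level
#' notes for the construction. Because `Z` is measured without error, the
#' group-living and density lag products are linear in the latent values and
#' the likelihood remains exact for all three structures.
#'
#' With both error variances zero the latent layer is degenerate and the
#' routine delegates to [fit_dyn_sem()], so the estimates coincide exactly.
#'
#' @inheritParams fit_dyn_sem
#' @param x,y Observed (error-contaminated) column names; defaults
#'   `"X_obs"`, `"Y_obs"` as produced by [add_measurement_error()].
#' @param error_variances Numeric vector `c(x = , y = )` of known
#'   measurement-error variances. Defaults to the panel's
#'   `"error_variances"` attribute when present.
#' @param se Compute the Wald standard error of `b` from the numerical
#'   Hessian (set `FALSE` to skip the extra Hessian evaluations in large
#'   Monte-Carlo loops where only the point estimate is needed).
#' @return A `crosslag_fit` (model `"DYN_SEM_PLUS"`).
#' @examples
#' p <- simulate_panel(process_spec("tradeoff_multi", n_subjects = 60, seed = 3))
#' pe <- add_measurement_error(p, measurement_error_spec(0.25, 0, seed = 4))
#' fit_dyn_sem_plus(pe, "tradeoff", se = FALSE)
#' @export
fit_dyn_sem_plus <- function(panel, structure = NULL, x = "X_obs",
                             y = "Y_obs", z = "Z", error_variances = NULL,
                             se = TRUE,
                             control = list(maxit = 500, reltol = 1e-9)) {
  structure <- .infer_structure(panel, structure)
  if (is.null(error_variances))
    error_variances <- attr(panel, "error_variances")
  if (is.null(error_variances) || length(error_variances) != 2L)
    stop("`error_variances` must supply the known error variances c(x=, y=)",
         call. = FALSE)
  tau_x <- unname(error_variances[[1]])
  tau_y <- unname(error_variances[[2]])
  if (tau_x < 0 || tau_y < 0)
    stop("error variances must be non-negative", call. = FALSE)
  for (v in c("subject", "time", x, y)) {
    if (!v %in% names(panel))
      stop("panel lacks required column `", v, "`", call. = FALSE)
  }
  if (tau_x < 1e-12 && tau_y < 1e-12) {
    fit <- fit_dyn_sem(panel, structure, x = x, y = y, z = z)
    fit$model <- "DYN_SEM_PLUS"
    return(fit)
  }
  if (tau_x >= stats::var(panel[[x]]) || tau_y >= stats::var(panel[[y]]))
    stop("an error variance is as large as the observed variance; ",
         "the latent model is not identifiable", call. = FALSE)

  d <- as.data.frame(panel)[order(panel$subject, panel$time), ]
  Ts <- tapply(d$time, d$subject, length)
  if (length(unique(Ts)) != 1L)
    stop("fit_dyn_sem_plus requires a balanced panel", call. = FALSE)
  Tn <- unique(Ts)[[1]]
  S <- length(Ts)
  has_z <- structure != "tradeoff"
  if (has_z && !z %in% names(d))
    stop("panel lacks required column `", z, "` for the ", structure,
         " structure", call. = FALSE)
  dat <- list(structure = structure, Tn = Tn, S = S, has_z = has_z,
              Z = if (has_z) matrix(d[[z]], nrow = Tn) else NULL,
              obs = rbind(matrix(d[[y]], nrow = Tn),
                          matrix(d[[x]], nrow = Tn),
                          if (has_z) matrix(d[[z]], nrow = Tn)))
  has_re <- S > 1L && structure != "density"

  # start from the uncorrected DYN_SEM fit on the observed columns
  fit0 <- fit_dyn_sem(panel, structure, x = x, y = y, z = z)
  e0 <- fit0$estimates
  g0 <- function(nm, def = 0) if (nm %in% names(e0)) unname(e0[[nm]]) else def
  sig_start <- function(obs_sd, tau) {
    sqrt(max(obs_sd^2 - tau, 0.25 * obs_sd^2))
  }
  x1 <- d[[x]][d$time == 1L]
  par0 <- c(a = g0("a"), b = g0("b"), c = g0("c"), d = g0("d"))
  if (has_z) par0 <- c(par0, f = g0("f"), g = g0("g"))
  par0 <- c(par0,
            log_sig_eps = log(sig_start(g0("sigma_eps", 1), tau_y)),
            log_sig_kap = log(sig_start(g0("sigma_kappa", 1), tau_x)))
  if (has_z) par0 <- c(par0, log_sig_lam = log(max(g0("sigma_lambda", 0.1),
                                                   1e-3)))
  if (structure != "tradeoff")
    par0 <- c(par0, m1 = mean(x1),
              log_s1 = log(max(stats::sd(x1), 1e-2)),
              if (structure == "grouplive") c(q_mu = 0, q_nu = 0))
  if (has_re)
    par0 <- c(par0, log_sd_mu = log(max(g0("sd_mu", 0.3), 1e-2)),
              log_sd_nu = log(max(g0("sd_nu", 0.3), 1e-2)),
              atanh_rho = atanh(min(max(g0("cor_mu_nu"), -0.95), 0.95)))

  unpack <- function(par) {
    th <- list(a = par[["a"]], b = par[["b"]], c = par[["c"]], d = par[["d"]],
               f = if (has_z) par[["f"]] else 0,
               g = if (has_z) par[["g"]] else 0,
               sigma_eps = exp(par[["log_sig_eps"]]),
               sigma_kappa = exp(par[["log_sig_kap"]]),
               sigma_lambda = if (has_z) exp(par[["log_sig_lam"]]) else 1,
               m1 = if (structure != "tradeoff") par[["m1"]] else 0,
               s1 = if (structure != "tradeoff") exp(par[["log_s1"]]) else 1,
               q_mu = if (structure == "grouplive") par[["q_mu"]] else 0,
               q_nu = if (structure == "grouplive") par[["q_nu"]] else 0,
               tau_x = tau_x, tau_y = tau_y, Omega = NULL)
    if (has_re) {
      sd_mu <- exp(par[["log_sd_mu"]])
      sd_nu <- exp(par[["log_sd_nu"]])
      rho <- tanh(par[["atanh_rho"]])
      th$Omega <- matrix(c(sd_mu^2, rho * sd_mu * sd_nu,
                           rho * sd_mu * sd_nu, sd_nu^2), 2, 2)
    }
    th
  }
  fn <- function(par) .semplus_nll(dat, unpack(par))
  # forward-difference gradient: p + 1 evaluations per gradient instead of
  # the 2p that optim's internal central differences would use
  gr <- function(par) {
    f0 <- fn(par)
    vapply(seq_along(par), function(i) {
      h <- 1e-6 * max(1, abs(par[i]))
      p2 <- par
      p2[i] <- p2[i] + h
      (fn(p2) - f0) / h
    }, numeric(1))
  }
  opt <- stats::optim(par0, fn, gr, method = "BFGS", control = control)
  th <- unpack(opt$par)

  se_b <- NA_real_
  hess_ok <- !se
  if (se) {
    hess <- tryCatch(stats::optimHess(opt$par, fn), error = function(e) NULL)
    if (!is.null(hess)) {
      bidx <- which(names(par0) == "b")
      vc <- tryCatch(solve(hess), error = function(e) NULL)
      if (!is.null(vc) && is.finite(vc[bidx, bidx]) && vc[bidx, bidx] > 0) {
        se_b <- sqrt(vc[bidx, bidx])
        hess_ok <- TRUE
      }
    }
  }
  est <- c(a = th$a, b = th$b, c = th$c, d = th$d)
  if (has_z) est <- c(est, f = th$f, g = th$g)
  est <- c(est, sigma_eps = th$sigma_eps, sigma_kappa = th$sigma_kappa)
  if (has_z) est["sigma_lambda"] <- th$sigma_lambda
  if (has_re) {
    est["sd_mu"] <- sqrt(th$Omega[1, 1])
    est["sd_nu"] <- sqrt(th$Omega[2, 2])
    est["cor_mu_nu"] <- th$Omega[1, 2] / (est[["sd_mu"]] * est[["sd_nu"]])
    est["cov_mu_nu"] <- th$Omega[1, 2]
  }
  new_crosslag_fit("DYN_SEM_PLUS", structure = structure, estimates = est,
                   se_b = se_b, loglik = -opt$value,
                   converged = opt$convergence == 0 && hess_ok,
                   n_subjects = S, n_obs = nrow(d),
                   sd_x = stats::sd(d[[x]]), sd_y = stats::sd(d[[y]]),
                   extra = list(omega = th$Omega,
                                error_variances = c(x = tau_x, y = tau_y),
                                optim = opt))
}

#' Evaluate the DYN_SEM+ marginal log-likelihood at fixed parameters
#'
#' Exact marginal log-likelihood of the errors-in-variables dynamical SEM at
#' given parameter values, exposed for validation against brute-force
#' Monte-Carlo integration over the latent process.
#'
#' @inheritParams fit_dyn_sem_plus
#' @param params Named list: structural coefficients (`a`-`g` as the
#'   structure requires), `sigma_eps`, `sigma_kappa` (and `sigma_lambda`),
#'   `omega` (2x2, where random intercepts apply), and for the
#'   grouplive/density structures the initial-condition parameters `m1`,
#'   `s1` (and `q_mu` for grouplive).
#' @return The marginal log-likelihood (a scalar).
#' @export
dyn_sem_plus_loglik <- function(panel, structure = NULL, params,
                                x = "X_obs", y = "Y_obs", z = "Z",
                                error_variances = NULL) {
  structure <- .infer_structure(panel, structure)
  if (is.null(error_variances))
    error_variances <- attr(panel, "error_variances")
  d <- as.data.frame(panel)[order(panel$subject, panel$time), ]
  Tn <- length(unique(d$time))
  S <- length(unique(d$subject))
  has_z <- structure != "tradeoff"
  dat <- list(structure = structure, Tn = Tn, S = S, has_z = has_z,
              Z = if (has_z) matrix(d[[z]], nrow = Tn) else NULL,
              obs = rbind(matrix(d[[y]], nrow = Tn),
                          matrix(d[[x]], nrow = Tn),
                          if (has_z) matrix(d[[z]], nrow = Tn)))
  th <- list(a = params$a, b = params$b, c = params$c, d = params$d,
             f = if (!is.null(params$f)) params$f else 0,
             g = if (!is.null(params$g)) params$g else 0,
             sigma_eps = params$sigma_eps, sigma_kappa = params$sigma_kappa,
             sigma_lambda = if (!is.null(params$sigma_lambda))
               params$sigma_lambda else 1,
             m1 = if (!is.null(params$m1)) params$m1 else 0,
             s1 = if (!is.null(params$s1)) params$s1 else 1,
             q_mu = if (!is.null(params$q_mu)) params$q_mu else 0,
             q_nu = if (!is.null(params$q_nu)) params$q_nu else 0,
             tau_x = unname(error_variances[[1]]),
             tau_y = unname(error_variances[[2]]),
             Omega = if (S > 1L && structure != "density") params$omega)
  -.semplus_nll(dat, th)
}
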