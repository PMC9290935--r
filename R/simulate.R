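# Panel simulation from the four cross-lagged processes, plus the
# measurement-error overlay and long-format CSV serialization.

#' Simulate a multi-subject cross-lagged panel
#'
#' Generates a panel from the recursion defined by a [process_spec()]. Each
#' subject is initialized at the process's deterministic stationary point
#' (including its own random intercepts), run for `burn_in` extra steps that
#' are then discarded, and recorded for `n_time` steps. Per-subject random
#' intercepts `(mu_s, nu_s)` are drawn once from `MVN(0, omega)` and retained
#' as an attribute for testing.
#'
#' All random draws come from a single generator stream seeded with
#' `spec$seed`; the caller's RNG state is left untouched. Identical specs
#' therefore produce bit-identical panels.
#'
#' Trajectories whose `|X|` exceeds `1e6` abort with an explosion error
#' rather than propagating overflow silently.
#'
#' @param spec A validated [process_spec()].
#' @return A `crosslag_panel`: a data.frame with columns `subject`, `time`,
#'   `X`, `Y` and (density / group-living kinds) `Z`, carrying attributes
#'   `spec` (the generating specification) and `intercepts` (data.frame of
#'   realized `mu`, `nu` per subject).
#' @examples
#' p <- simulate_panel(process_spec("tradeoff_single", n_time = 20, seed = 42))
#' head(p)
#' @export
simulate_panel <- function(spec) {
  validate_process_spec(spec)
  S <- spec$n_subjects
  Tn <- spec$n_time
  total <- spec$burn_in + Tn
  has_z <- .spec_has_z(spec)
  has_re <- .spec_has_intercepts(spec)

  .with_seed(spec$seed, {
    if (has_re) {
      re <- .rmvnorm2(S, spec$omega)
    } else {
      re <- matrix(0, S, 2)
    }
    mu <- re[, 1]
    nu <- re[, 2]

    # deterministic stationary point per subject (noise-free fixed point)
    if (has_z) {
      zbar <- spec$g + if (spec$kind == "grouplive_multi") nu else 0
      nu_x <- 0
    } else {
      zbar <- rep(0, S)
      nu_x <- if (spec$kind == "tradeoff_multi") nu else rep(0, S)
    }
    denom <- 1 - spec$b * spec$d - spec$f * zbar
    denom[abs(denom) < 1e-8] <- sign(denom[abs(denom) < 1e-8] + 1e-12) * 1e-8
    x_prev <- (spec$c + spec$d * (spec$a + mu) + nu_x) / denom
    y_prev <- spec$a + spec$b * x_prev + mu
    z_prev <- zbar

    X <- matrix(NA_real_, S, Tn)
    Y <- matrix(NA_real_, S, Tn)
    Z <- if (has_z) matrix(NA_real_, S, Tn) else NULL

    for (t in seq_len(total)) {
      kap <- stats::rnorm(S, 0, spec$sigma_kappa)
      eps <- stats::rnorm(S, 0, spec$sigma_eps)
      x_t <- spec$c + spec$d * y_prev + kap
      if (has_z) x_t <- x_t + spec$f * z_prev * x_prev
      if (spec$kind == "tradeoff_multi") x_t <- x_t + nu
      y_t <- spec$a + spec$b * x_t + mu + eps
      if (has_z) {
        lam <- stats::rnorm(S, 0, spec$sigma_lambda)
        z_t <- spec$g + lam + if (spec$kind == "grouplive_multi") nu else 0
      }
      if (any(!is.finite(x_t)) || max(abs(x_t)) > 1e6)
        stop("explosion: |X| exceeded 1e6 during simulation; ",
             "the process parameters are (numerically) explosive",
             call. = FALSE)
      if (t > spec$burn_in) {
        k <- t - spec$burn_in
        X[, k] <- x_t
        Y[, k] <- y_t
        if (has_z) Z[, k] <- z_t
      }
      x_prev <- x_t
      y_prev <- y_t
      if (has_z) z_prev <- z_t
    }

    panel <- data.frame(
      subject = rep(seq_len(S), each = Tn),
      time = rep(seq_len(Tn), times = S),
      X = as.vector(t(X)),
      Y = as.vector(t(Y))
    )
    if (has_z) panel$Z <- as.vector(t(Z))
    attr(panel, "spec") <- spec
    attr(panel, "intercepts") <- data.frame(subject = seq_len(S),
                                            mu = mu, nu = nu)
    class(panel) <- c("crosslag_panel", "data.frame")
    panel
  })
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# n draws from a bivariate normal with mean zero and covariance `sigma`
# (2x2 PSD); degenerate components allowed.
.rmvnorm2 <- function(n, sigma) {
  ev <- eigen(sigma, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  A <- ev$vectors %*% diag(sqrt(lam), 2)
  matrix(stats::rnorm(2 * n), n, 2) %*% t(A)
}

#' @export
print.crosslag_panel <- function(x, ...) {
  spec <- attr(x, "spec")
  ns <- length(unique(x$subject))
  cat(sprintf("Cross-lagged panel: %d subject(s), %d rows", ns, nrow(x)))
  if (!is.null(spec) && inherits(spec, "process_spec"))
    cat(sprintf(" [%s]", spec$kind))
  if (!is.null(x$X_obs) || !is.null(x$Y_obs))
    cat(" (with measurement error)")
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}

#' Plot subject trajectories of a simulated panel
#'
#' Draws `Y` against `X` per subject (a few subjects by default), connecting
#' successive time steps, to visualize the directional within-subject pattern
#' that a cross-lag induces.
#'
#' @param x A `crosslag_panel`.
#' @param subjects Subjects to draw (default: up to 5).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.crosslag_panel <- function(x, subjects = NULL, ...) {
  ids <- unique(x$subject)
  if (is.null(subjects)) subjects <- utils::head(ids, 5)
  d <- x[x$subject %in% subjects, , drop = FALSE]
  graphics::plot(d$X, d$Y, type = "n", xlab = "X", ylab = "Y", ...)
  for (i in seq_along(subjects)) {
    di <- d[d$subject == subjects[i], ]
    di <- di[order(di$time), ]
    graphics::lines(di$X, di$Y, col = i, type = "o", pch = 16, cex = 0.6)
  }
  invisible(x)
}

#' Overlay Gaussian measurement error on a simulated panel
#'
#' Appends observed columns `X_obs` and `Y_obs` equal to the true values plus
#' independent Gaussian errors. For a fraction `frac`, the error variance is
#' `frac / (1 - frac)` times the empirical variance of the true values, so
#' that the error makes up exactly `frac` of the resulting *total* variance;
#' the repeat-measurement correlation (reliability) is then `1 - frac`. True
#' columns are retained, and the realized error variances are stored in the
#' `"error_variances"` attribute for use by [fit_dyn_sem_plus()].
#'
#' @param panel A panel with true `X` and `Y` columns.
#' @param me A [measurement_error_spec()] (or `NULL` for the default 25%).
#' @return The panel with `X_obs`, `Y_obs` columns appended.
#' @examples
#' p <- simulate_panel(process_spec("tradeoff_multi", n_subjects = 20, seed = 1))
#' pe <- add_measurement_error(p, measurement_error_spec(0.25, 0, seed = 2))
#' attr(pe, "error_variances")
#' @export
add_measurement_error <- function(panel, me = measurement_error_spec()) {
  if (!all(c("X", "Y") %in% names(panel)))
    stop("panel must contain true `X` and `Y` columns", call. = FALSE)
  stopifnot(inherits(me, "measurement_error_spec"))
  n <- nrow(panel)
  err_var <- function(frac, v) if (frac == 0) 0 else frac / (1 - frac) * v
  vx <- err_var(me$frac_x, stats::var(panel$X))
  vy <- err_var(me$frac_y, stats::var(panel$Y))
  .with_seed(me$seed, {
    panel$X_obs <- panel$X + stats::rnorm(n, 0, sqrt(vx))
    panel$Y_obs <- panel$Y + stats::rnorm(n, 0, sqrt(vy))
  })
  attr(panel, "error_variances") <- c(x = vx, y = vy)
  attr(panel, "me_spec") <- me
  panel
}

#' Read and write panels as long-format CSV
#'
#' The on-disk dialect is a plain UTF-8 CSV with header
#' `subject,time,X,Y[,Z][,X_obs,Y_obs]`, `.` as decimal separator and empty
#' fields for missing values.
#'
#' @param panel A panel data.frame.
#' @param path File path.
#' @return `write_panel_csv` returns `path` invisibly; `read_panel_csv`
#'   returns a `crosslag_panel` (metadata marked `"empirical"` since the
#'   generating process is not stored in the CSV).
#' @export
write_panel_csv <- function(panel, path) {
  keep <- intersect(c("subject", "time", "X", "Y", "Z", "X_obs", "Y_obs"),
                    names(panel))
  utils::write.csv(as.data.frame(panel)[, keep, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "time", "X", "Y")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("panel CSV is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  .validate_panel(d)
  attr(d, "spec") <- "empirical"
  class(d) <- c("crosslag_panel", "data.frame")
  d
}

# Panel structural invariants: unique (subject, time), contiguous time
# within subject, finite stored values.
.validate_panel <- function(panel) {
  key <- paste(panel$subject, panel$time)
  if (anyDuplicated(key))
    stop("panel invariant violated: duplicated (subject, time) pairs",
         call. = FALSE)
  bad <- vapply(split(panel$time, panel$subject), function(tt) {
    tt <- sort(tt)
    !(tt[1] == 1L && all(diff(tt) == 1L))
  }, logical(1))
  if (any(bad))
    stop("panel invariant violated: time not contiguous 1..T for subject(s) ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  vals <- unlist(panel[intersect(c("X", "Y", "Z", "X_obs", "Y_obs"),
                                 names(panel))], use.names = FALSE)
  if (any(!is.finite(vals)))
    stop("panel invariant violated: non-finite values present", call. = FALSE)
  invisible(panel)
}
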