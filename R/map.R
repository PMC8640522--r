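# Maximum a posteriori (MAP) Bayesian estimation of individual random
# effects and AUC from sparse concentration records.

#' Sparse observation set for one subject
#'
#' @param time Observation times (h).
#' @param conc Observed concentrations (mg/L).
#' @param cov A [covariate_profile()].
#' @param reg A [regimen()].
#' @param blq Below-quantification flags (excluded from estimation).
#' @param steady_state Assume steady state (default) or post-first-dose.
#' @param id Optional subject identifier.
#' @return An object of class `mpa_observations`.
#' @export
observation_set <- function(time, conc, cov, reg, blq = 0,
                            steady_state = TRUE, id = NULL) {
  stopifnot(inherits(cov, "mpa_covariates"), inherits(reg, "mpa_regimen"))
  if (length(time) != length(conc)) {
    stop("`time` and `conc` lengths differ", call. = FALSE)
  }
  blq <- rep_len(as.integer(blq), length(time))
  if (any(conc < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  if (steady_state && length(time) && any(time < 0 | time > reg$tau)) {
    stop("steady-state observation times must lie within [0, tau]",
         call. = FALSE)
  }
  structure(list(time = as.numeric(time), conc = as.numeric(conc),
                 blq = blq, cov = cov, reg = reg,
                 steady_state = steady_state, id = id),
            class = "mpa_observations")
}

# indices of random effects actually estimated (positive variance)
active_eta <- function(pop) which(omega_sd(pop) > 0)

# Lean steady-state/single-dose predictor on a bare parameter vector
# (ka, cl, v2, q, v3, tlag, f); mirrors concentration() without S3
# dispatch or validation — the optimizer hot path.
conc_fast <- function(p, dose, tau, t, ss) {
  ka <- p[1]
  k10 <- p[2] / p[3]; k12 <- p[4] / p[3]; k21 <- p[4] / p[5]
  s <- k10 + k12 + k21
  disc <- sqrt(max(s * s - 4 * k10 * k21, 0))
  l1 <- (s + disc) / 2; l2 <- (s - disc) / 2
  if (abs(ka - l1) < 1e-8 * l1 || abs(ka - l2) < 1e-8 * max(l2, 1e-12)) {
    ka <- ka * (1 + 1e-6)
  }
  A <- (k21 - l1) / ((ka - l1) * (l2 - l1))
  B <- (k21 - l2) / ((ka - l2) * (l1 - l2))
  C <- (k21 - ka) / ((l1 - ka) * (l2 - ka))
  sc <- p[7] * dose * ka / p[3]
  if (ss) {
    tp <- (t - p[6]) %% tau
    sc * (A * exp(-l1 * tp) / (1 - exp(-l1 * tau)) +
            B * exp(-l2 * tp) / (1 - exp(-l2 * tau)) +
            C * exp(-ka * tp) / (1 - exp(-ka * tau)))
  } else {
    tp <- t - p[6]
    out <- A * exp(-l1 * tp) + B * exp(-l2 * tp) + C * exp(-ka * tp)
    out[tp <= 0] <- 0
    sc * out
  }
}

# Build the per-subject objective once: covariate adjustment, data
# extraction and constants are hoisted out of the optimizer loop. The
# closure takes the active-eta vector and agrees with map_objective().
make_map_objective <- function(obs, pop, form = "fixed_weight") {
  act <- active_eta(pop)
  omega2_act <- omega_sd(pop)[act]^2
  keep <- obs$blq == 0
  tt <- obs$time[keep]
  y <- obs$conc[keep]
  cl_fac <- 1 + (obs$cov$egfr - pop$egfr_ref) * pop$theta_egfr_cl
  if (cl_fac <= 0) {
    stop("covariate model yields non-positive clearance at eGFR = ",
         obs$cov$egfr, call. = FALSE)
  }
  typ <- c(pop$ka_tv,
           pop$cl_tv * cl_fac,
           pop$v2_tv * (obs$cov$alb / pop$alb_ref)^pop$theta_alb_v2,
           pop$q_tv, pop$v3_tv, pop$tlag_tv,
           pop$f_tv * pop$theta_ppi_f^obs$cov$ppi)
  sp2 <- pop$sigma_prop^2
  sa2 <- pop$sigma_add^2
  dose <- obs$reg$dose
  tau <- obs$reg$tau
  ss <- obs$steady_state
  big <- .Machine$double.xmax
  if (identical(form, "els")) {
    function(e) {
      if (any(abs(e) > 20)) return(big)
      prior <- sum(e * e / omega2_act)
      if (!length(tt)) return(prior)
      full <- numeric(7)
      full[act] <- e
      f <- conc_fast(typ * exp(full), dose, tau, tt, ss)
      g2 <- sp2 * f * f + sa2
      if (any(g2 <= 0) || any(!is.finite(f))) return(big)
      sum((y - f)^2 / g2 + log(g2)) + prior
    }
  } else {
    g2y <- sp2 * y * y + sa2     # weights anchored at the observations
    function(e) {
      if (any(abs(e) > 20)) return(big)
      prior <- sum(e * e / omega2_act)
      if (!length(tt)) return(prior)
      full <- numeric(7)
      full[act] <- e
      f <- conc_fast(typ * exp(full), dose, tau, tt, ss)
      if (any(!is.finite(f))) return(big)
      sum((y - f)^2 / g2y) + prior
    }
  }
}

#' MAP objective function
#'
#' Posterior objective for one subject's random effects. Two forms are
#' available. `"fixed_weight"` (the default used for AUC forecasting)
#' weights each squared residual by the combined error variance evaluated
#' at the observed concentration, `(y - f)^2 / g(y)^2`, plus the prior
#' penalty `eta' Omega^-1 eta`. `"els"` is the extended least-squares form
#' `(y - f)^2 / g(f)^2 + log(g(f)^2)` — the exact -2 log joint density —
#' whose `log g^2` term, with a large proportional error component,
#' systematically rewards under-prediction of the profile (by roughly
#' sigma_prop^2 in relative terms); it remains the form used inside the
#' population marginal likelihood where it is not optional. Random effects
#' with zero population variance are fixed at zero and excluded.
#'
#' @param eta Random-effect vector, either full length 7 (canonical order)
#'   or of length `length(active_eta(pop))` for the estimated subset.
#' @param obs An [observation_set()].
#' @param pop An [mpa_params()] object.
#' @param form `"fixed_weight"` or `"els"`.
#' @return Objective value (scalar, -2 log posterior up to constants).
#' @export
map_objective <- function(eta, obs, pop, form = c("fixed_weight", "els")) {
  form <- match.arg(form)
  act <- active_eta(pop)
  full <- rep(0, length(.MPA_ETA_NAMES))
  names(full) <- .MPA_ETA_NAMES
  if (length(eta) == length(full)) {
    full[] <- eta
  } else if (length(eta) == length(act)) {
    full[act] <- eta
  } else {
    stop("`eta` has wrong length", call. = FALSE)
  }
  omega2 <- omega_sd(pop)^2
  if (any(full[omega2 == 0] != 0)) {
    stop("non-zero eta supplied for a zero-variance random effect",
         call. = FALSE)
  }
  # line searches can wander into absurd territory (e^20-fold parameter
  # shifts); cut them off before they overflow the model
  if (any(abs(full) > 20)) return(.Machine$double.xmax)
  prior <- sum(full[act]^2 / omega2[act])
  keep <- obs$blq == 0
  if (!any(keep)) return(prior)
  ind <- apply_covariates(pop, obs$cov, eta = full)
  f <- concentration(ind, obs$reg, obs$time[keep],
                     steady_state = obs$steady_state)
  y <- obs$conc[keep]
  if (identical(form, "els")) {
    g2 <- (pop$sigma_prop * f)^2 + pop$sigma_add^2
    if (any(g2 <= 0)) return(.Machine$double.xmax)
    sum((y - f)^2 / g2 + log(g2)) + prior
  } else {
    g2y <- (pop$sigma_prop * y)^2 + pop$sigma_add^2
    sum((y - f)^2 / g2y) + prior
  }
}

#' Control settings for [map_fit()]
#'
#' @param n_starts Number of optimizer starts: eta = 0 plus
#'   `n_starts - 1` deterministic perturbed starts.
#' @param start_scale Perturbation size in units of omega.
#' @param maxit Maximum BFGS iterations per start.
#' @param grad_tol Gradient-norm threshold for the convergence flag.
#' @param reltol Relative objective tolerance passed to [stats::optim()].
#' @param objective Objective form, `"fixed_weight"` (default) or `"els"`;
#'   see [map_objective()].
#' @return A list of class `map_control`.
#' @export
map_control <- function(n_starts = 5, start_scale = 0.5, maxit = 500,
                        grad_tol = 1e-3, reltol = 1e-12,
                        objective = c("fixed_weight", "els")) {
  structure(list(n_starts = n_starts, start_scale = start_scale,
                 maxit = maxit, grad_tol = grad_tol, reltol = reltol,
                 objective = match.arg(objective)),
            class = "map_control")
}

# deterministic multi-start points: origin plus alternating +/- patterns
map_starts <- function(pop, control) {
  act <- active_eta(pop)
  d <- length(act)
  sd <- omega_sd(pop)[act]
  starts <- list(rep(0, d))
  if (control$n_starts > 1) {
    pat <- list(rep(1, d), rep(-1, d),
                rep_len(c(1, -1), d), rep_len(c(-1, 1), d))
    extra <- min(control$n_starts - 1, length(pat))
    for (k in seq_len(extra)) {
      starts[[k + 1]] <- control$start_scale * sd * pat[[k]]
    }
  }
  starts
}

numeric_grad <- function(fn, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    (fn(xp) - fn(xm)) / (2 * hi)
  }, numeric(1))
}

#' MAP Bayesian fit for one subject
#'
#' Minimizes [map_objective()] by BFGS from multiple deterministic starts
#' (the prior mode plus perturbed points); the best converged minimum wins,
#' ties broken by lexicographically smallest eta. With no usable
#' observations the prior mode (eta = 0) is returned directly.
#'
#' @param obs An [observation_set()].
#' @param pop An [mpa_params()] object.
#' @param control A [map_control()].
#' @return An object of class `map_fit` with `eta_hat` (full-length,
#'   canonical order), `individual`, `objective`, `converged` and
#'   `auc_ipred` (steady-state trapezoidal AUC on a 0.5-h grid).
#' @export
map_fit <- function(obs, pop, control = map_control()) {
  stopifnot(inherits(obs, "mpa_observations"), inherits(pop, "mpa_params"))
  act <- active_eta(pop)
  n_obs <- sum(obs$blq == 0)
  fn <- make_map_objective(obs, pop, form = control$objective)
  if (n_obs == 0 || length(act) == 0) {
    eta_hat <- rep(0, length(.MPA_ETA_NAMES))
    names(eta_hat) <- .MPA_ETA_NAMES
    ind <- apply_covariates(pop, obs$cov, eta = eta_hat)
    fit <- structure(list(eta_hat = eta_hat, individual = ind,
                          objective = fn(rep(0, length(act))),
                          converged = TRUE, n_obs = n_obs, obs = obs,
                          pop = pop),
                     class = "map_fit")
    fit$auc_ipred <- auc_from_map(fit)
    return(fit)
  }
  best <- NULL
  for (start in map_starts(pop, control)) {
    res <- tryCatch(
      stats::optim(start, fn, method = "BFGS",
                   control = list(maxit = control$maxit,
                                  reltol = control$reltol)),
      error = function(e) NULL)
    if (is.null(res)) next
    better <- is.null(best) ||
      res$value < best$value - 1e-10 ||
      (abs(res$value - best$value) <= 1e-10 &&
         isTRUE(all(res$par < best$par | res$par == best$par)) &&
         !identical(res$par, best$par))
    if (better) best <- res
  }
  if (is.null(best)) {
    stop("MAP optimization failed from every start", call. = FALSE)
  }
  grad <- numeric_grad(fn, best$par)
  converged <- best$convergence == 0 &&
    sqrt(sum(grad^2)) < control$grad_tol * max(1, abs(best$value))
  eta_hat <- rep(0, length(.MPA_ETA_NAMES))
  names(eta_hat) <- .MPA_ETA_NAMES
  eta_hat[act] <- best$par
  ind <- apply_covariates(pop, obs$cov, eta = eta_hat)
  fit <- structure(list(eta_hat = eta_hat, individual = ind,
                        objective = best$value, converged = converged,
                        n_obs = n_obs, obs = obs, pop = pop),
                   class = "map_fit")
  fit$auc_ipred <- auc_from_map(fit)
  fit
}

#' @export
print.map_fit <- function(x, ...) {
  cat(sprintf("MAP fit (%d observations, %s)\n", x$n_obs,
              if (x$converged) "converged" else "NOT converged"))
  cat("  eta:", paste(sprintf("%s %+0.3f", names(x$eta_hat), x$eta_hat),
                      collapse = ", "), "\n")
  cat(sprintf("  AUC_0-12h (ipred): %.2f mg.h/L\n", x$auc_ipred))
  invisible(x)
}

#' AUC from a MAP fit
#'
#' Steady-state profile of the fitted individual on a fine grid over one
#' dosing interval, integrated by the linear trapezoidal rule.
#'
#' @param fit A [map_fit()] result.
#' @param dt Grid step (h), default 0.5.
#' @return AUC in mg.h/L.
#' @export
auc_from_map <- function(fit, dt = 0.5) {
  stopifnot(inherits(fit, "map_fit"))
  reg <- fit$obs$reg
  times <- seq(0, reg$tau, by = dt)
  if (times[length(times)] < reg$tau) times <- c(times, reg$tau)
  auc_trapezoid(predict_profile(fit$individual, reg, times,
                                steady_state = TRUE))
}
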