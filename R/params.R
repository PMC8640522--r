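# Population parameters, covariate profiles, dosing regimens and the
# covariate submodels that turn typical values into individual parameters.

# canonical parameter order used for random effects throughout the package
.MPA_ETA_NAMES <- c("ka", "cl", "v2", "q", "v3", "tlag", "f")

#' Population pharmacokinetic parameters for mycophenolic acid
#'
#' Builds the population-parameter object used by every other function in
#' the package. The defaults are the final population estimates for adult
#' heart-transplant recipients on mycophenolate mofetil: a two-compartment
#' disposition model with first-order absorption and an absorption lag,
#' apparent oral parameters (CL/F, V2/F, Q/F, V3/F), fixed bioavailability
#' F = 0.95, and three covariate effects — proton-pump-inhibitor (PPI)
#' co-medication multiplying F, estimated glomerular filtration rate (eGFR)
#' entering clearance linearly around a reference of 57 mL/min/1.73 m2, and
#' albumin entering the central volume as a power function around 40 g/L.
#'
#' Between-subject variability is lognormal per parameter and reported as a
#' percent coefficient of variation; residual error combines a proportional
#' and an additive component.
#'
#' @param ka_tv Typical absorption rate constant (1/h).
#' @param cl_tv Typical apparent clearance CL/F (L/h) at the eGFR reference.
#' @param v2_tv Typical apparent central volume V2/F (L) at the albumin
#'   reference.
#' @param q_tv Typical apparent inter-compartmental clearance Q/F (L/h).
#' @param v3_tv Typical apparent peripheral volume V3/F (L).
#' @param tlag_tv Typical absorption lag time (h).
#' @param f_tv Reference bioavailability (fraction, fixed at 0.95).
#' @param theta_ppi_f Multiplicative factor on F under PPI co-medication.
#' @param theta_egfr_cl Linear eGFR slope on CL/F, per mL/min/1.73 m2.
#' @param theta_alb_v2 Power exponent of albumin on V2/F.
#' @param egfr_ref Reference eGFR (mL/min/1.73 m2) at which CL/F equals
#'   `cl_tv`.
#' @param alb_ref Reference albumin (g/L) at which V2/F equals `v2_tv`.
#' @param iiv_cv Named numeric vector of between-subject variability as %CV
#'   for `ka`, `cl`, `v2`, `q`, `v3`, `tlag`, `f`.
#' @param sigma_prop Proportional residual error (fraction).
#' @param sigma_add Additive residual error (mg/L).
#' @param iiv_transform How the %CV maps to the standard deviation of the
#'   lognormal random effect: `"cv"` uses omega = CV/100 (the reporting
#'   convention 100*sqrt(omega^2)); `"lognormal_exact"` uses
#'   omega^2 = log(1 + (CV/100)^2).
#' @return An object of class `mpa_params`.
#' @examples
#' pop <- mpa_params()
#' pop$cl_tv
#' @export
mpa_params <- function(ka_tv = 0.781,
                       cl_tv = 7.36,
                       v2_tv = 5.69,
                       q_tv = 17.0,
                       v3_tv = 560,
                       tlag_tv = 0.408,
                       f_tv = 0.95,
                       theta_ppi_f = 0.724,
                       theta_egfr_cl = 0.00791,
                       theta_alb_v2 = -7.31,
                       egfr_ref = 57,
                       alb_ref = 40,
                       iiv_cv = c(ka = 41.5, cl = 41.2, v2 = 186.5,
                                  q = 33.3, v3 = 189.5, tlag = 13.1,
                                  f = 22.1),
                       sigma_prop = 0.261,
                       sigma_add = 0.144,
                       iiv_transform = c("cv", "lognormal_exact")) {
  iiv_transform <- match.arg(iiv_transform)
  iiv <- rep(0, length(.MPA_ETA_NAMES))
  names(iiv) <- .MPA_ETA_NAMES
  if (length(iiv_cv)) {
    if (is.null(names(iiv_cv))) {
      stop("`iiv_cv` must be a named vector", call. = FALSE)
    }
    unknown <- setdiff(names(iiv_cv), .MPA_ETA_NAMES)
    if (length(unknown)) {
      stop("unknown parameters in `iiv_cv`: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    iiv[names(iiv_cv)] <- as.numeric(iiv_cv)
  }
  pop <- structure(
    list(ka_tv = ka_tv, cl_tv = cl_tv, v2_tv = v2_tv, q_tv = q_tv,
         v3_tv = v3_tv, tlag_tv = tlag_tv, f_tv = f_tv,
         theta_ppi_f = theta_ppi_f, theta_egfr_cl = theta_egfr_cl,
         theta_alb_v2 = theta_alb_v2, egfr_ref = egfr_ref,
         alb_ref = alb_ref, iiv_cv = iiv, sigma_prop = sigma_prop,
         sigma_add = sigma_add, iiv_transform = iiv_transform),
    class = "mpa_params")
  validate_mpa_params(pop)
  pop
}

validate_mpa_params <- function(pop) {
  tv <- c(ka_tv = pop$ka_tv, cl_tv = pop$cl_tv, v2_tv = pop$v2_tv,
          q_tv = pop$q_tv, v3_tv = pop$v3_tv, tlag_tv = pop$tlag_tv,
          f_tv = pop$f_tv, theta_ppi_f = pop$theta_ppi_f)
  if (any(!is.finite(tv)) || any(tv[names(tv) != "tlag_tv"] <= 0) ||
      pop$tlag_tv < 0) {
    stop("typical values and the PPI factor must be positive and finite",
         call. = FALSE)
  }
  if (pop$f_tv > 1) stop("`f_tv` must lie in (0, 1]", call. = FALSE)
  if (pop$sigma_prop < 0 || pop$sigma_add < 0) {
    stop("residual-error components must be non-negative", call. = FALSE)
  }
  if (any(pop$iiv_cv < 0)) stop("`iiv_cv` must be non-negative", call. = FALSE)
  invisible(pop)
}

#' Standard deviations of the lognormal random effects
#'
#' @param pop An [mpa_params()] object.
#' @return Named vector of omega (sd of eta) per parameter.
#' @export
omega_sd <- function(pop) {
  cv <- pop$iiv_cv / 100
  if (identical(pop$iiv_transform, "lognormal_exact")) {
    sqrt(log1p(cv^2))
  } else {
    cv
  }
}

#' Diagonal between-subject covariance matrix
#'
#' @inheritParams omega_sd
#' @return 7 x 7 diagonal matrix of omega^2 in canonical parameter order.
#' @export
omega_matrix <- function(pop) {
  sd <- omega_sd(pop)
  diag(sd^2, nrow = length(sd))
}

#' @export
print.mpa_params <- function(x, ...) {
  cat("MPA population parameters\n")
  cat(sprintf("  Ka %.3g 1/h, CL/F %.3g L/h, V2/F %.3g L, Q/F %.3g L/h, V3/F %.3g L\n",
              x$ka_tv, x$cl_tv, x$v2_tv, x$q_tv, x$v3_tv))
  cat(sprintf("  Tlag %.3g h, F %.3g (PPI factor %.3g)\n",
              x$tlag_tv, x$f_tv, x$theta_ppi_f))
  cat(sprintf("  eGFR slope on CL %.3g (ref %g), ALB exponent on V2 %.3g (ref %g)\n",
              x$theta_egfr_cl, x$egfr_ref, x$theta_alb_v2, x$alb_ref))
  cat(sprintf("  IIV %%CV: %s\n",
              paste(sprintf("%s %.4g", names(x$iiv_cv), x$iiv_cv),
                    collapse = ", ")))
  cat(sprintf("  residual error: %.3g proportional, %.3g mg/L additive\n",
              x$sigma_prop, x$sigma_add))
  invisible(x)
}

#' Read or write a population-parameter configuration file
#'
#' Parameter files are YAML with one field per entry of [mpa_params()]; a
#' ready-made default configuration ships with the package under
#' `system.file("params", "mpa-population.yaml", package = "mpapk")`.
#'
#' @param path File path.
#' @return `read_params()` returns an `mpa_params` object; `write_params()`
#'   returns `path` invisibly.
#' @export
read_params <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(mpa_params))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown parameter fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$iiv_cv)) raw$iiv_cv <- unlist(raw$iiv_cv)
  do.call(mpa_params, raw)
}

#' @rdname read_params
#' @param pop An [mpa_params()] object to serialize.
#' @export
write_params <- function(pop, path) {
  stopifnot(inherits(pop, "mpa_params"))
  out <- unclass(pop)
  out$iiv_cv <- as.list(out$iiv_cv)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Per-subject covariate profile
#'
#' @param egfr Estimated glomerular filtration rate (mL/min/1.73 m2).
#' @param alb Serum albumin (g/L).
#' @param ppi PPI co-medication flag (0/1).
#' @param scr,age,sex,weight Optional demographics; `scr` (mg/dL), `age`
#'   (years) and `sex` (`"male"`/`"female"`) allow eGFR derivation via
#'   [mdrd_egfr()].
#' @return An object of class `mpa_covariates`.
#' @export
covariate_profile <- function(egfr, alb, ppi = 0, scr = NULL, age = NULL,
                              sex = NULL, weight = NULL) {
  if (!is.finite(egfr) || egfr <= 0) stop("`egfr` must be > 0", call. = FALSE)
  if (!is.finite(alb) || alb <= 0) stop("`alb` must be > 0", call. = FALSE)
  if (!ppi %in% c(0, 1)) stop("`ppi` must be 0 or 1", call. = FALSE)
  structure(list(egfr = egfr, alb = alb, ppi = ppi, scr = scr, age = age,
                 sex = sex, weight = weight),
            class = "mpa_covariates")
}

#' Dosing regimen
#'
#' @param dose Mycophenolate mofetil dose (mg).
#' @param tau Dosing interval (h), 12 for twice-daily dosing.
#' @param n_doses Number of doses administered; `Inf` means steady state.
#' @return An object of class `mpa_regimen`.
#' @export
regimen <- function(dose, tau = 12, n_doses = Inf) {
  if (!is.finite(dose) || dose <= 0) stop("`dose` must be > 0", call. = FALSE)
  if (!is.finite(tau) || tau <= 0) stop("`tau` must be > 0", call. = FALSE)
  if (!(is.infinite(n_doses) || (n_doses >= 1 && n_doses == round(n_doses)))) {
    stop("`n_doses` must be a positive integer or Inf", call. = FALSE)
  }
  structure(list(dose = dose, tau = tau, n_doses = n_doses),
            class = "mpa_regimen")
}

#' Covariate-adjusted individual parameters
#'
#' Applies the covariate submodels to the typical values and attaches the
#' random effects `eta` (all zero here, i.e. the population-predicted
#' individual):
#' \itemize{
#'   \item CL/F = cl_tv * (1 + (eGFR - egfr_ref) * theta_egfr_cl)
#'   \item V2/F = v2_tv * (ALB / alb_ref)^theta_alb_v2
#'   \item F = f_tv * theta_ppi_f^PPI
#' }
#'
#' @param pop An [mpa_params()] object.
#' @param cov A [covariate_profile()].
#' @param eta Optional named random-effect vector (canonical order); defaults
#'   to all zero.
#' @return An object of class `mpa_individual` with realized `ka`, `cl`,
#'   `v2`, `q`, `v3`, `tlag`, `f` and the `eta` used.
#' @export
apply_covariates <- function(pop, cov, eta = NULL) {
  stopifnot(inherits(pop, "mpa_params"), inherits(cov, "mpa_covariates"))
  if (is.null(eta)) {
    eta <- rep(0, length(.MPA_ETA_NAMES))
    names(eta) <- .MPA_ETA_NAMES
  } else {
    full <- rep(0, length(.MPA_ETA_NAMES))
    names(full) <- .MPA_ETA_NAMES
    full[names(eta)] <- eta
    eta <- full
  }
  cl_fac <- 1 + (cov$egfr - pop$egfr_ref) * pop$theta_egfr_cl
  if (cl_fac <= 0) {
    stop("covariate model yields non-positive clearance at eGFR = ",
         cov$egfr, call. = FALSE)
  }
  typ <- c(ka = pop$ka_tv,
           cl = pop$cl_tv * cl_fac,
           v2 = pop$v2_tv * (cov$alb / pop$alb_ref)^pop$theta_alb_v2,
           q = pop$q_tv,
           v3 = pop$v3_tv,
           tlag = pop$tlag_tv,
           f = pop$f_tv * pop$theta_ppi_f^cov$ppi)
  ind <- as.list(typ * exp(eta))
  ind$eta <- eta
  ind$covariates <- cov
  structure(ind, class = "mpa_individual")
}

#' Draw an individual from the population
#'
#' Realizes one subject: covariate-adjusted typical values times
#' `exp(eta)` with eta drawn independently N(0, omega^2) per parameter
#' (diagonal between-subject covariance).
#'
#' @inheritParams apply_covariates
#' @param seed Integer seed; required for reproducibility.
#' @return An `mpa_individual`.
#' @export
sample_individual <- function(pop, cov, seed) {
  eta <- with_seed(seed, draw_eta(pop))
  apply_covariates(pop, cov, eta = eta)
}

# one eta draw using the current RNG stream
draw_eta <- function(pop) {
  sd <- omega_sd(pop)
  eta <- stats::rnorm(length(sd), mean = 0, sd = sd)
  names(eta) <- .MPA_ETA_NAMES
  eta
}

# Evaluate code under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
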