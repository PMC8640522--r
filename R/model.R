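# Closed-form two-compartment disposition with first-order lagged
# absorption, and the combined residual-error model.

# Macro constants of the triexponential solution. Returns hybrid rate
# constants and coefficients such that
#   C(t) = F*D*ka/V2 * (A e^{-l1 tp} + B e^{-l2 tp} + C e^{-ka tp})
# with tp = t - tlag. When ka collides with a hybrid rate the absorption
# constant is nudged by a relative 1e-6 to stay off the removable
# singularity (a measure-zero configuration).
macro_constants <- function(ka, cl, v2, q, v3) {
  k10 <- cl / v2
  k12 <- q / v2
  k21 <- q / v3
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- sqrt(max(s^2 - 4 * p, 0))
  l1 <- (s + disc) / 2
  l2 <- (s - disc) / 2
  if (abs(ka - l1) < 1e-8 * l1 || abs(ka - l2) < 1e-8 * max(l2, 1e-12)) {
    ka <- ka * (1 + 1e-6)
  }
  list(ka = ka,
       l1 = l1, l2 = l2,
       A = (k21 - l1) / ((ka - l1) * (l2 - l1)),
       B = (k21 - l2) / ((ka - l2) * (l1 - l2)),
       C = (k21 - ka) / ((l1 - ka) * (l2 - ka)))
}

#' Model-predicted MPA concentration
#'
#' Closed-form concentration of the two-compartment model with first-order
#' absorption and an absorption lag. For a single dose, time is measured
#' from dosing and concentrations are zero up to the lag. At steady state
#' under repeated dosing every exponential term is divided by
#' `1 - exp(-rate * tau)`; the profile is periodic with period `tau` and
#' times before the lag wrap to the previous dose. A finite `n_doses`
#' superposes that many single doses given `tau` apart.
#'
#' @param ind An `mpa_individual` (see [apply_covariates()]).
#' @param reg An [regimen()].
#' @param t Time(s) in hours. For steady state, interpreted within a dosing
#'   interval (values are wrapped modulo `tau`).
#' @param steady_state Logical; defaults to `TRUE` when `reg$n_doses` is
#'   infinite.
#' @return Concentration(s) in mg/L.
#' @export
concentration <- function(ind, reg, t,
                          steady_state = is.infinite(reg$n_doses)) {
  stopifnot(inherits(ind, "mpa_individual"), inherits(reg, "mpa_regimen"))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  mc <- macro_constants(ind$ka, ind$cl, ind$v2, ind$q, ind$v3)
  scale <- ind$f * reg$dose * mc$ka / ind$v2
  if (steady_state) {
    tp <- (t - ind$tlag) %% reg$tau
    val <- mc$A * exp(-mc$l1 * tp) / (1 - exp(-mc$l1 * reg$tau)) +
      mc$B * exp(-mc$l2 * tp) / (1 - exp(-mc$l2 * reg$tau)) +
      mc$C * exp(-mc$ka * tp) / (1 - exp(-mc$ka * reg$tau))
    return(scale * val)
  }
  n <- if (is.infinite(reg$n_doses)) 1L else as.integer(reg$n_doses)
  out <- numeric(length(t))
  for (j in seq_len(n) - 1L) {
    tp <- t - j * reg$tau - ind$tlag
    pos <- tp > 0
    if (!any(pos)) next
    tpp <- tp[pos]
    out[pos] <- out[pos] + scale *
      (mc$A * exp(-mc$l1 * tpp) + mc$B * exp(-mc$l2 * tpp) +
         mc$C * exp(-mc$ka * tpp))
  }
  out
}

#' Concentration-time profile
#'
#' Vectorized wrapper around [concentration()] returning a profile
#' data frame. Times must be sorted non-decreasing; for steady state they
#' must lie within one dosing interval `[0, tau]`.
#'
#' @inheritParams concentration
#' @param times Sorted vector of times (h).
#' @param id Optional subject identifier carried in the result.
#' @return A data frame of class `pk_profile` with columns `time` and
#'   `conc` (and `id` when given).
#' @export
predict_profile <- function(ind, reg, times,
                            steady_state = is.infinite(reg$n_doses),
                            id = NULL) {
  if (length(times) && is.unsorted(times)) {
    stop("`times` must be sorted non-decreasing", call. = FALSE)
  }
  if (steady_state && length(times) && any(times > reg$tau)) {
    stop("steady-state times must lie within [0, tau]", call. = FALSE)
  }
  conc <- if (length(times)) {
    concentration(ind, reg, times, steady_state = steady_state)
  } else {
    numeric(0)
  }
  out <- data.frame(time = as.numeric(times), conc = as.numeric(conc))
  if (!is.null(id)) out <- cbind(id = id, out)
  class(out) <- c("pk_profile", "data.frame")
  out
}

#' Residual-error standard deviation
#'
#' Combined error model: `sd = sqrt((sigma_prop * c_pred)^2 + sigma_add^2)`.
#'
#' @param c_pred Predicted concentration(s), mg/L.
#' @param pop An [mpa_params()] object.
#' @return Standard deviation(s), mg/L.
#' @export
residual_sd <- function(c_pred, pop) {
  stopifnot(inherits(pop, "mpa_params"))
  if (any(c_pred < 0)) stop("`c_pred` must be non-negative", call. = FALSE)
  sqrt((pop$sigma_prop * c_pred)^2 + pop$sigma_add^2)
}

#' Add residual noise to a predicted profile
#'
#' Adds independent normal noise with the combined-error standard deviation
#' to each concentration; results are floored at zero (concentrations are
#' non-negative). Quantification-limit censoring is a separate step, see
#' [censor_lloq()].
#'
#' @param profile A `pk_profile` from [predict_profile()].
#' @param pop An [mpa_params()] object.
#' @param seed Integer seed.
#' @return The profile with perturbed `conc`.
#' @export
add_residual_noise <- function(profile, pop, seed) {
  stopifnot(inherits(profile, "pk_profile"))
  noisy <- with_seed(seed, {
    profile$conc + stats::rnorm(nrow(profile),
                                sd = residual_sd(profile$conc, pop))
  })
  profile$conc <- pmax(noisy, 0)
  profile
}
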