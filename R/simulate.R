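# Exposure computation: trapezoidal and analytic AUC, the 24-scenario
# covariate grid, and cohort-scale profile simulation.

#' Linear trapezoidal AUC
#'
#' @param time Either a numeric time vector or a `pk_profile` data frame
#'   (in which case `conc` is taken from it).
#' @param conc Concentrations matching `time` when given as a vector.
#' @return AUC in mg.h/L.
#' @export
auc_trapezoid <- function(time, conc = NULL) {
  if (is.data.frame(time)) {
    conc <- time$conc
    time <- time$time
  }
  if (length(time) < 2) {
    stop("at least two points are required for a trapezoidal AUC",
         call. = FALSE)
  }
  if (length(time) != length(conc)) {
    stop("`time` and `conc` lengths differ", call. = FALSE)
  }
  sum(0.5 * (utils::head(conc, -1) + utils::tail(conc, -1)) * diff(time))
}

#' Analytic steady-state AUC over one dosing interval
#'
#' At steady state the AUC over one interval equals `F * dose / CL`,
#' independent of the disposition constants.
#'
#' @param ind An `mpa_individual`.
#' @param reg A [regimen()].
#' @return AUC in mg.h/L.
#' @export
auc_analytic_ss <- function(ind, reg) {
  if (ind$cl <= 0) stop("clearance must be positive", call. = FALSE)
  ind$f * reg$dose / ind$cl
}

#' Covariate scenario grid
#'
#' Default grid of 24 steady-state scenarios: eGFR 30/60/90/130, albumin
#' 30/40/60, with and without PPI, at 500 mg twice daily.
#'
#' @param egfr_levels,alb_levels,ppi_levels Covariate levels.
#' @param dose,tau Dose (mg) and interval (h).
#' @return A `scenario_grid` list.
#' @export
scenario_grid <- function(egfr_levels = c(30, 60, 90, 130),
                          alb_levels = c(30, 40, 60),
                          ppi_levels = c(0, 1),
                          dose = 500, tau = 12) {
  structure(list(egfr_levels = egfr_levels, alb_levels = alb_levels,
                 ppi_levels = ppi_levels, dose = dose, tau = tau),
            class = "scenario_grid")
}

# round half away from zero to `digits` decimals (presentation convention)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Steady-state AUC under covariate scenarios
#'
#' For every cell of the grid, computes the population-predicted (all
#' random effects zero) steady-state profile on a 0.5-h grid over one
#' 12-h dosing interval (inclusive endpoints, 25 points) and its linear
#' trapezoidal AUC.
#'
#' @param pop An [mpa_params()] object.
#' @param grid A [scenario_grid()].
#' @param dt Grid step (h) for the trapezoid.
#' @return A data frame with columns `ppi`, `alb`, `egfr`, `auc`
#'   (trapezoidal, unrounded) and `auc_report` (one decimal, half away
#'   from zero).
#' @export
scenario_table <- function(pop = mpa_params(), grid = scenario_grid(),
                           dt = 0.5) {
  cells <- expand.grid(egfr = grid$egfr_levels, alb = grid$alb_levels,
                       ppi = grid$ppi_levels, KEEP.OUT.ATTRS = FALSE)
  reg <- regimen(grid$dose, grid$tau)
  times <- seq(0, grid$tau, by = dt)
  auc <- vapply(seq_len(nrow(cells)), function(i) {
    cov <- covariate_profile(egfr = cells$egfr[i], alb = cells$alb[i],
                             ppi = cells$ppi[i])
    ind <- apply_covariates(pop, cov)
    auc_trapezoid(predict_profile(ind, reg, times, steady_state = TRUE))
  }, numeric(1))
  out <- data.frame(ppi = cells$ppi, alb = cells$alb, egfr = cells$egfr,
                    auc = auc, auc_report = round_half_up(auc, 1))
  out[order(out$ppi, out$alb, out$egfr), , drop = FALSE]
}

#' Simulate a cohort of concentration profiles
#'
#' Draws one individual per cohort row (lognormal between-subject
#' variability), predicts steady-state concentrations at the schedule, and
#' optionally adds residual noise. The returned dataset carries the true
#' individual parameters and analytic AUCs for recovery testing.
#'
#' @param pop An [mpa_params()] object.
#' @param cohort A data frame with columns `id`, `egfr`, `alb`, `ppi`,
#'   `dose` and optionally `tau` (default 12), e.g. from
#'   [generate_cohort()].
#' @param schedule Sampling times (h) within the dosing interval.
#' @param seed Integer seed.
#' @param with_noise Add residual error to the observations?
#' @return A list of class `pk_cohort_sim` with elements `dataset` (a
#'   long-format [PK dataset][read_pk_dataset()]), `true_params` (one row
#'   per subject: realized parameters, eta, analytic steady-state AUC) and
#'   `schedule`.
#' @export
simulate_cohort_profiles <- function(pop, cohort, schedule, seed,
                                     with_noise = FALSE) {
  if (!nrow(cohort)) stop("`cohort` is empty", call. = FALSE)
  if (is.null(cohort$tau)) cohort$tau <- 12
  rows <- vector("list", nrow(cohort))
  tp <- vector("list", nrow(cohort))
  with_seed(seed, {
    for (i in seq_len(nrow(cohort))) {
      cov <- covariate_profile(egfr = cohort$egfr[i], alb = cohort$alb[i],
                               ppi = cohort$ppi[i])
      eta <- draw_eta(pop)
      ind <- apply_covariates(pop, cov, eta = eta)
      reg <- regimen(cohort$dose[i], cohort$tau[i])
      prof <- predict_profile(ind, reg, schedule, steady_state = TRUE)
      if (with_noise) {
        prof$conc <- pmax(prof$conc +
                            stats::rnorm(nrow(prof),
                                         sd = residual_sd(prof$conc, pop)),
                          0)
      }
      id <- cohort$id[i]
      dose_row <- data.frame(id = id, time = 0, amt = cohort$dose[i],
                             dv = NA_real_, evid = 1L, mdv = 1L, blq = 0L,
                             ppi = cohort$ppi[i], egfr = cohort$egfr[i],
                             alb = cohort$alb[i])
      obs_rows <- data.frame(id = id, time = prof$time, amt = NA_real_,
                             dv = prof$conc, evid = 0L, mdv = 0L, blq = 0L,
                             ppi = cohort$ppi[i], egfr = cohort$egfr[i],
                             alb = cohort$alb[i])
      rows[[i]] <- rbind(dose_row, obs_rows)
      tp[[i]] <- data.frame(id = id, ka = ind$ka, cl = ind$cl, v2 = ind$v2,
                            q = ind$q, v3 = ind$v3, tlag = ind$tlag,
                            f = ind$f, t(eta) |>
                              `colnames<-`(paste0("eta_", names(eta))),
                            auc_ss = auc_analytic_ss(ind, reg))
    }
  })
  dataset <- do.call(rbind, rows)
  rownames(dataset) <- NULL
  structure(list(dataset = dataset,
                 true_params = do.call(rbind, tp),
                 schedule = schedule),
            class = "pk_cohort_sim")
}
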