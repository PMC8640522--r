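# Shared fixtures, built in code.

typical_pop <- function(...) mpa_params(...)

typical_individual <- function(pop = mpa_params(), egfr = 57, alb = 40,
                               ppi = 0) {
  apply_covariates(pop, covariate_profile(egfr, alb, ppi))
}

# a population with variability on clearance only: keeps inner MAP
# problems one-dimensional for fast population-level tests
cl_only_pop <- function(cv = 40) {
  mpa_params(iiv_cv = c(cl = cv))
}

# small simulated dataset: n subjects, sparse or intensive schedule
small_dataset <- function(n = 8, pop = cl_only_pop(), schedule = "sparse",
                          seed = 11, with_noise = TRUE, dose = 500) {
  cfg <- cohort_config(n = n)
  cohort <- generate_cohort(cfg, seed = seed)
  cohort$dose <- dose
  simulate_cohort_profiles(pop, cohort, sampling_schedule(schedule),
                           seed = seed + 1, with_noise = with_noise)
}

# numerical ODE oracle for the depot + central + peripheral system
ode_oracle <- function(ind, dose, times) {
  rhs <- function(t, y, p) {
    list(c(-p[["ka"]] * y[1],
           p[["ka"]] * y[1] - (p[["k10"]] + p[["k12"]]) * y[2] +
             p[["k21"]] * y[3],
           p[["k12"]] * y[2] - p[["k21"]] * y[3]))
  }
  p <- c(ka = ind$ka, k10 = ind$cl / ind$v2, k12 = ind$q / ind$v2,
         k21 = ind$q / ind$v3)
  tp <- pmax(times - ind$tlag, 0)
  grid <- c(0, sort(unique(tp[tp > 0])))
  out <- deSolve::ode(c(ind$f * dose, 0, 0), grid, rhs, p,
                      rtol = 1e-10, atol = 1e-12)
  vals <- out[match(tp, out[, 1]), 3] / ind$v2
  ifelse(times <= ind$tlag, 0, vals)
}

# independent brute-force implementation of the 1983 rank procedure
pb_oracle <- function(x, y) {
  s <- c()
  n <- length(x)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) next
      if (dx == 0) next
      s <- c(s, dy / dx)
    }
  }
  s <- sort(s[s != -1])
  k <- sum(s < -1)
  nn <- length(s)
  b <- if (nn %% 2 == 1) s[(nn + 1) / 2 + k] else
    mean(s[nn / 2 + k + 0:1])
  c(slope = b, intercept = stats::median(y - b * x))
}

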