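test_that("MAP objective combines data term and prior as stated", {
  pop <- mpa_params()
  cov <- covariate_profile(57, 40, 0)
  reg <- regimen(500)
  none <- observation_set(numeric(0), numeric(0), cov, reg)

  expect_equal(map_objective(rep(0, 7), none, pop), 0)
  eta <- rep(0.1, 7)
  expect_equal(map_objective(eta, none, pop),
               sum(eta^2 / omega_sd(pop)^2))
  expect_gt(map_objective(eta, none, pop), 0)

  # a single noise-free observation at the prior-mode prediction: the
  # extended-least-squares form leaves only the log-variance term, the
  # observation-weighted form is exactly zero
  ind <- apply_covariates(pop, cov)
  f0 <- concentration(ind, reg, 2)
  one <- observation_set(2, f0, cov, reg)
  expect_equal(map_objective(rep(0, 7), one, pop, form = "els"),
               log(residual_sd(f0, pop)^2))
  expect_equal(map_objective(rep(0, 7), one, pop), 0)

  # duplicating an observation doubles its data term exactly (both forms)
  two <- observation_set(c(2, 2), c(f0, f0), cov, reg)
  eta <- stats::setNames(seq(-0.3, 0.3, by = 0.1), names(omega_sd(pop)))
  prior <- sum(eta^2 / omega_sd(pop)^2)
  for (form in c("fixed_weight", "els")) {
    expect_equal(map_objective(eta, two, pop, form = form) - prior,
                 2 * (map_objective(eta, one, pop, form = form) - prior))
  }

  singular <- mpa_params(iiv_cv = c(cl = 40))
  expect_error(map_objective(rep(0.1, 7), none, singular), "zero-variance")
})

test_that("MAP fit returns the prior mode without data and shrinks toward it", {
  pop <- mpa_params()
  cov <- covariate_profile(70, 38, 1)
  reg <- regimen(500)

  fit0 <- map_fit(observation_set(numeric(0), numeric(0), cov, reg), pop)
  expect_equal(unname(fit0$eta_hat), rep(0, 7))
  expect_equal(fit0$individual$cl, apply_covariates(pop, cov)$cl)
  expect_true(fit0$converged)

  # BLQ records are excluded: estimation sees only the usable sample
  ind <- apply_covariates(pop, cov)
  f <- concentration(ind, reg, c(0.2, 4))
  with_blq <- observation_set(c(0.2, 4), c(0.05, f[2]), cov, reg,
                              blq = c(1, 0))
  no_blq <- observation_set(4, f[2], cov, reg)
  expect_equal(map_fit(with_blq, pop)$eta_hat,
               map_fit(no_blq, pop)$eta_hat, tolerance = 1e-6)
})

test_that("dense noise-free data recover the individual", {
  pop <- mpa_params()
  cov <- covariate_profile(57, 40, 0)
  reg <- regimen(500)
  eta_true <- stats::setNames(c(0.2, -0.3, 0.5, 0.1, -0.2, 0.05, 0.1),
                              c("ka", "cl", "v2", "q", "v3", "tlag", "f"))
  ind <- apply_covariates(pop, cov, eta = eta_true)
  tt <- seq(0, 12, by = 0.5)
  prof <- predict_profile(ind, reg, tt, steady_state = TRUE)
  fit <- map_fit(observation_set(tt, prof$conc, cov, reg), pop)
  # the identifiable clearance in oral data is CL/F
  expect_lt(abs(fit$individual$cl / fit$individual$f - ind$cl / ind$f) /
              (ind$cl / ind$f), 0.02)
  # the posterior tolerates scale misfit of a few percent because the
  # assumed proportional error (26.1%) keeps the data term soft
  expect_lt(abs(fit$auc_ipred - auc_trapezoid(prof)) / auc_trapezoid(prof),
            0.08)
  expect_true(fit$converged)
})

test_that("AUC from a MAP fit follows the fitted profile", {
  pop <- mpa_params()
  reg <- regimen(500)
  cov <- covariate_profile(90, 40, 0)
  fit <- map_fit(observation_set(numeric(0), numeric(0), cov, reg), pop)

  # identical pathway to the scenario engine at the same covariates
  tab <- scenario_table()
  expect_equal(fit$auc_ipred,
               tab$auc[tab$ppi == 0 & tab$alb == 40 & tab$egfr == 90])

  # fine grid converges to F*dose/CL
  expect_lt(abs(auc_from_map(fit, dt = 0.001) -
                  auc_analytic_ss(fit$individual, reg)) /
              auc_analytic_ss(fit$individual, reg), 5e-4)

  # linear in dose
  cov2 <- covariate_profile(90, 40, 0)
  fit2 <- map_fit(observation_set(numeric(0), numeric(0), cov2,
                                  regimen(1000)), pop)
  expect_equal(fit2$auc_ipred, 2 * fit$auc_ipred, tolerance = 1e-10)
})
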