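test_that("trapezoidal AUC follows its definition", {
  tt <- seq(0, 12, by = 0.5)
  expect_equal(auc_trapezoid(tt, rep(1, length(tt))), 12)
  expect_equal(auc_trapezoid(c(0, 1), c(0, 2)), 1)
  expect_error(auc_trapezoid(1, 2), "two points")
  expect_error(auc_trapezoid(c(0, 1), c(1, 2, 3)), "lengths")

  # fine grid converges to the analytic steady-state identity F*D/CL
  ind <- typical_individual()
  reg <- regimen(500)
  prof <- predict_profile(ind, reg, seq(0, 12, by = 0.5))
  expect_lt(abs(auc_trapezoid(prof) - auc_analytic_ss(ind, reg)) /
              auc_analytic_ss(ind, reg), 0.01)
})

test_that("analytic steady-state AUC is F*dose/CL", {
  pop <- mpa_params()
  reg <- regimen(500)
  expect_equal(auc_analytic_ss(typical_individual(pop), reg), 475 / 7.36)
  expect_equal(auc_analytic_ss(typical_individual(pop, egfr = 90), reg),
               475 / (7.36 * (1 + 33 * 0.00791)))

  half_f <- typical_individual(pop)
  half_f$f <- half_f$f / 2
  expect_equal(auc_analytic_ss(half_f, reg),
               auc_analytic_ss(typical_individual(pop), reg) / 2)
})

test_that("scenario table covers the grid with the expected structure", {
  tab <- scenario_table()
  expect_equal(nrow(tab), 24)
  expect_equal(nrow(unique(tab[c("ppi", "alb", "egfr")])), 24)

  # exposure falls monotonically with renal function in every stratum
  for (p in 0:1) {
    for (a in c(30, 40, 60)) {
      auc <- tab$auc[tab$ppi == p & tab$alb == a][order(
        tab$egfr[tab$ppi == p & tab$alb == a])]
      expect_true(all(diff(auc) < 0))
    }
  }

  # PPI rows scale the matching no-PPI rows by the bioavailability factor
  no_ppi <- tab[tab$ppi == 0, ]
  with_ppi <- tab[tab$ppi == 1, ]
  ord <- order(no_ppi$alb, no_ppi$egfr)
  ratio <- with_ppi$auc[order(with_ppi$alb, with_ppi$egfr)] /
    no_ppi$auc[ord]
  expect_equal(ratio, rep(0.724, 12), tolerance = 0.01)

  # half-hour trapezoid stays near the analytic identity in every cell;
  # the deviation peaks at albumin 60 where the central volume collapses
  # and the absorption peak is sharpest
  pop <- mpa_params()
  for (i in seq_len(nrow(tab))) {
    ind <- apply_covariates(pop, covariate_profile(tab$egfr[i], tab$alb[i],
                                                   tab$ppi[i]))
    tol <- if (tab$alb[i] == 60) 0.06 else 0.015
    expect_lt(abs(tab$auc[i] - auc_analytic_ss(ind, regimen(500))) /
                auc_analytic_ss(ind, regimen(500)), tol)
  }
})

test_that("cohort simulation is reproducible and respects degenerate variance", {
  pop0 <- mpa_params(iiv_cv = c(ka = 0))       # all variability off
  cohort <- data.frame(id = 1:4, egfr = 57, alb = 40, ppi = 0, dose = 500)
  sim <- simulate_cohort_profiles(pop0, cohort, c(0, 1, 4), seed = 3)
  obs <- sim$dataset[sim$dataset$evid == 0, ]
  ind <- typical_individual()
  expected <- concentration(ind, regimen(500), c(0, 1, 4))
  for (i in 1:4) {
    expect_equal(obs$dv[obs$id == i], expected)
  }

  pop <- mpa_params()
  a <- simulate_cohort_profiles(pop, cohort, c(0, 1, 4), seed = 9,
                                with_noise = TRUE)
  b <- simulate_cohort_profiles(pop, cohort, c(0, 1, 4), seed = 9,
                                with_noise = TRUE)
  expect_identical(a$dataset, b$dataset)
  expect_error(simulate_cohort_profiles(pop, cohort[0, ], c(0, 1), seed = 1),
               "empty")

  # mean analytic AUC across a cohort matches a direct Monte-Carlo of
  # F/CL ratios under the same lognormal clearance model
  big <- data.frame(id = 1:400, egfr = 57, alb = 40, ppi = 0, dose = 500)
  pop_cl <- cl_only_pop(cv = 41.2)
  sim_big <- simulate_cohort_profiles(pop_cl, big, c(0, 6), seed = 21)
  mc <- local({
    set.seed(21)
    mean(475 / (7.36 * exp(stats::rnorm(2e5, 0, 0.412))))
  })
  expect_lt(abs(mean(sim_big$true_params$auc_ss) - mc) / mc, 0.05)
})
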