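test_that("linearized information matrix is symmetric PSD and grows with samples", {
  pop <- mpa_params()
  cov <- covariate_profile(57, 40, 0)
  reg <- regimen(500)

  F3 <- linearized_fim(c(0, 1, 4), cov, reg, pop)
  expect_equal(F3, t(F3))
  ev <- eigen(F3, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-6 * max(ev)))

  # adding a sample can only add information (regularized criterion)
  expect_gte(mpapk:::ed_logdet(linearized_fim(c(0, 1, 4, 6), cov, reg, pop),
                               pop),
             mpapk:::ed_logdet(F3, pop))
})

test_that("collapsed model matches the analytic single-parameter information", {
  # only the clearance fixed effect carries information when variability is
  # switched off and the error is purely additive
  pop <- mpa_params(iiv_cv = c(), sigma_prop = 0, sigma_add = 0.2)
  cov <- covariate_profile(57, 40, 0)
  reg <- regimen(500)
  tt <- c(1, 4, 8)
  F1 <- linearized_fim(tt, cov, reg, pop)

  h <- 1e-4 * pop$cl_tv
  pp <- mpa_params(cl_tv = pop$cl_tv + h, iiv_cv = c(), sigma_prop = 0,
                   sigma_add = 0.2)
  pm <- mpa_params(cl_tv = pop$cl_tv - h, iiv_cv = c(), sigma_prop = 0,
                   sigma_add = 0.2)
  dfdcl <- (concentration(apply_covariates(pp, cov), reg, tt) -
              concentration(apply_covariates(pm, cov), reg, tt)) / (2 * h)
  expect_equal(F1["cl_tv", "cl_tv"], sum(dfdcl^2) / 0.2^2,
               tolerance = 1e-4)
})

test_that("ED criterion has set semantics and respects forced designs", {
  pop <- mpa_params()
  expect_equal(ed_criterion(c(0, 1, 4), pop, n_mc = 3, seed = 5),
               ed_criterion(c(4, 0, 1), pop, n_mc = 3, seed = 5))

  # n_mc = 1 reduces to a single-profile evaluation
  cfg <- cohort_config()
  one <- ed_criterion(c(0, 1, 4), pop, config = cfg, n_mc = 1, seed = 7)
  cohort <- generate_cohort({cfg$n <- 1; cfg}, seed = 7)
  cov <- covariate_profile(cohort$egfr, cohort$alb, cohort$ppi)
  fim <- linearized_fim(c(0, 1, 4), cov, regimen(500), pop)
  expect_equal(one, mpapk:::ed_logdet(fim, pop), tolerance = 1e-8)

  only_predose <- optimize_design(grid = 0, max_samples = 1, n_mc = 2,
                                  seed = 1, pop = pop)
  expect_equal(only_predose$support, 0)

  forced <- optimize_design(grid = c(0, 1, 4), max_samples = 3, n_mc = 2,
                            seed = 1, pop = pop)
  expect_equal(forced$support, c(0, 1, 4))
  expect_true(all(diff(forced$evaluated$criterion) <= 1e-12))
})

test_that("stepwise regression recovers an exact linear AUC construction", {
  sim <- small_dataset(n = 45, pop = mpa_params(), schedule = "intensive",
                       seed = 31, with_noise = FALSE)
  obs <- sim$dataset[sim$dataset$evid == 0, ]
  ids <- unique(obs$id)
  conc <- t(vapply(ids, function(i) {
    d <- obs[obs$id == i, ]
    d$dv[match(c(1, 4), d$time)]
  }, numeric(2)))
  colnames(conc) <- c(1, 4)
  auc <- 2 * conc[, "1"] + 5 * conc[, "4"]
  m <- stepwise_mlr(conc, auc)
  expect_equal(m$timepoints, c(1, 4))
  expect_equal(m$coefficients, c(2, 5), tolerance = 1e-8)
  expect_null(m$intercept)
  expect_equal(m$r2, 1, tolerance = 1e-10)

  # a duplicated predictor is perfectly collinear and must not be added
  dup <- cbind(conc, conc[, "1"])
  colnames(dup) <- c(1, 4, 2)
  m2 <- stepwise_mlr(dup, auc)
  expect_equal(sort(m2$timepoints), c(1, 4))
  expect_true(all(m2$vif < 10))
})

test_that("fitted and published equations apply as linear combinations", {
  eq <- published_equation()
  expect_equal(eq$timepoints, c(0, 0.5, 1, 4.5))
  expect_null(eq$intercept)
  expect_equal(sum(eq$coefficients), 3.539 + 0.288 + 1.349 + 6.773)

  zeros <- stats::setNames(rep(0, 4), c(0, 0.5, 1, 4.5))
  expect_equal(apply_mlr(eq, zeros), 0)
  units <- stats::setNames(rep(1, 4), c(0, 0.5, 1, 4.5))
  expect_equal(apply_mlr(eq, units), 11.949)

  partial <- stats::setNames(rep(1, 3), c(0.5, 1, 4.5))
  expect_error(apply_mlr(eq, partial), "MAP")
})

test_that("design-time MAP evaluation reports agreement of AUC estimates", {
  st <- evaluate_design_auc(c(0, 1, 4), n_virtual = 12, seed = 41)
  expect_s3_class(st, "agreement_stats")
  expect_equal(st$n + st$excluded, 12)
  expect_gt(st$pct_rmse, 0)
  expect_gt(st$pb_slope, 0.5)

  # a dense design pins the individual down almost exactly (a residual
  # percent-level slack remains from the prior's pull)
  dense <- evaluate_design_auc(seq(0, 12, 0.5), n_virtual = 8, seed = 42)
  expect_lt(dense$pct_rmse, 2)
})
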