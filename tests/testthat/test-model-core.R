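test_that("covariate submodels reproduce the published factors", {
  pop <- mpa_params()

  ref <- typical_individual(pop)
  expect_equal(ref$cl, 7.36)
  expect_equal(ref$v2, 5.69)
  expect_equal(ref$f, 0.95)
  expect_equal(unname(ref$eta), rep(0, 7))

  ppi <- typical_individual(pop, ppi = 1)
  expect_equal(ppi$f, 0.95 * 0.724)

  renal <- typical_individual(pop, egfr = 90)
  expect_equal(renal$cl, 7.36 * (1 + 33 * 0.00791))

  hypo <- typical_individual(pop, alb = 30)
  expect_equal(hypo$v2, 5.69 * (30 / 40)^-7.31)

  expect_error(covariate_profile(-5, 40), "egfr")
  expect_error(covariate_profile(50, 0), "alb")
  # a steep enough negative slope can push clearance through zero
  steep <- mpa_params(theta_egfr_cl = 0.05)
  expect_error(apply_covariates(steep, covariate_profile(20, 40, 0)),
               "clearance")
})

test_that("individual sampling is lognormal around the adjusted typical value", {
  cov <- covariate_profile(57, 40, 0)

  frozen <- mpa_params(iiv_cv = c(cl = 0))
  expect_equal(sample_individual(frozen, cov, seed = 1)$cl,
               apply_covariates(frozen, cov)$cl)

  pop <- mpa_params()
  a <- sample_individual(pop, cov, seed = 99)
  b <- sample_individual(pop, cov, seed = 99)
  expect_identical(a$cl, b$cl)
  expect_identical(a$eta, b$eta)

  # lognormal median equals the typical value
  cls <- vapply(1:10000, function(i) {
    sample_individual(pop, cov, seed = i)$cl
  }, numeric(1))
  expect_lt(abs(stats::median(cls) - 7.36) / 7.36, 0.02)

  expect_error(mpa_params(iiv_cv = c(cl = -5)), "non-negative")
})

test_that("closed-form concentrations match the ODE oracle and the lag", {
  pop <- mpa_params()
  ind <- typical_individual(pop)
  reg <- regimen(500)

  expect_identical(concentration(ind, reg, 0.3, steady_state = FALSE), 0)

  tt <- c(0.5, 1, 2, 4, 8, 12, 24)
  cf <- concentration(ind, reg, tt, steady_state = FALSE)
  expect_equal(cf, ode_oracle(ind, 500, tt), tolerance = 1e-6)

  # steady state is periodic over the dosing interval
  expect_equal(concentration(ind, reg, 0), concentration(ind, reg, 12))
})

test_that("steady state equals long-run superposition of single doses", {
  # terminal half-life is ~76 h, so many doses are needed to accumulate
  ind <- typical_individual()
  tt <- seq(0.5, 12, by = 0.5)
  css <- concentration(ind, regimen(500), tt, steady_state = TRUE)
  acc <- concentration(ind, regimen(500, n_doses = 200), tt + 199 * 12,
                       steady_state = FALSE)
  expect_equal(css, acc, tolerance = 1e-3)
})

test_that("profile prediction is vectorized and validates input", {
  ind <- typical_individual()
  reg <- regimen(500)

  single <- predict_profile(ind, reg, 2)
  expect_equal(single$conc, concentration(ind, reg, 2))

  empty <- predict_profile(ind, reg, numeric(0))
  expect_equal(nrow(empty), 0)

  grid <- predict_profile(ind, reg, seq(0, 12, by = 0.5))
  expect_equal(nrow(grid), 25)

  expect_error(predict_profile(ind, reg, c(2, 1)), "sorted")
  expect_error(predict_profile(ind, reg, c(0, 13)), "tau")
})

test_that("combined residual error has the published components", {
  pop <- mpa_params()
  expect_equal(residual_sd(0, pop), 0.144)
  expect_equal(residual_sd(1, mpa_params(sigma_add = 0)), 0.261)
  expect_equal(residual_sd(10, pop), sqrt(2.61^2 + 0.144^2))
  expect_error(residual_sd(-1, pop), "non-negative")
})

test_that("residual noise is reproducible with the documented spread", {
  pop <- mpa_params()
  ind <- typical_individual(pop)
  prof <- predict_profile(ind, regimen(500), seq(0, 12, 0.5))

  clean <- mpa_params(sigma_prop = 0, sigma_add = 0)
  expect_equal(add_residual_noise(prof, clean, seed = 1)$conc, prof$conc)

  a <- add_residual_noise(prof, pop, seed = 5)
  b <- add_residual_noise(prof, pop, seed = 5)
  expect_identical(a$conc, b$conc)
  expect_true(all(a$conc >= 0))

  flat <- prof[1, ][rep(1, 10000), ]
  flat$conc <- 5
  class(flat) <- c("pk_profile", "data.frame")
  noisy <- add_residual_noise(flat, pop, seed = 6)
  expect_lt(abs(stats::sd(noisy$conc) - sqrt((0.261 * 5)^2 + 0.144^2)),
            0.05)
})

test_that("parameter configuration round-trips through YAML", {
  pop <- mpa_params()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_params(pop, path)
  back <- read_params(path)
  expect_equal(back$cl_tv, pop$cl_tv)
  expect_equal(back$iiv_cv, pop$iiv_cv)

  shipped <- read_params(system.file("params", "mpa-population.yaml",
                                     package = "mpapk"))
  expect_equal(shipped$egfr_ref, 57)
  expect_equal(shipped$alb_ref, 40)
  expect_equal(shipped$theta_ppi_f, 0.724)
})
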