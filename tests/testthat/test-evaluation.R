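test_that("percentage error metrics follow their definitions", {
  expect_equal(percent_me(c(1, 2), c(1, 2)), 0)
  expect_equal(percent_me(110, 100), 10)
  expect_equal(percent_me(c(90, 110), c(100, 100)), 0)

  expect_equal(percent_rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(percent_rmse(c(90, 110), c(100, 100)), 10)
  expect_equal(percent_rmse(110, 100), 10)

  # scale invariance and positivity
  pred <- c(50, 61, 44); ref <- c(52, 60, 47)
  expect_equal(percent_rmse(3 * pred, 3 * ref), percent_rmse(pred, ref))
  expect_equal(percent_me(3 * pred, 3 * ref), percent_me(pred, ref))
  expect_gt(percent_rmse(pred, ref), 0)
  expect_error(percent_me(1, c(1, 2)), "lengths")
  expect_error(percent_rmse(c(1, 2), c(0, 2)), "positive")
})

test_that("Passing-Bablok matches exact lines and the brute-force oracle", {
  x <- c(1, 2, 3, 5, 8)
  fit <- passing_bablok(x, x)
  expect_equal(fit$slope, 1)
  expect_equal(fit$intercept, 0)

  fit2 <- passing_bablok(x, 2 * x + 1)
  expect_equal(fit2$slope, 2)
  expect_equal(fit2$intercept, 1)

  fit3 <- passing_bablok(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.9))
  oracle3 <- pb_oracle(c(1, 2, 3, 4), c(1.1, 1.9, 3.2, 3.9))
  expect_equal(fit3$slope, unname(oracle3["slope"]))
  expect_equal(fit3$intercept, unname(oracle3["intercept"]))

  set.seed(77)
  for (n in 3:8) {
    for (rep in 1:20) {
      x <- stats::rnorm(n)
      y <- 1.5 * x + stats::rnorm(n, sd = 0.3)
      got <- passing_bablok(x, y)
      want <- pb_oracle(x, y)
      expect_equal(got$slope, unname(want["slope"]))
      expect_equal(got$intercept, unname(want["intercept"]))
    }
  }

  expect_error(passing_bablok(1:2, 1:2), "3 points")
  expect_error(passing_bablok(rep(1, 4), 1:4), "all x equal")
})

test_that("Bland-Altman limits use the sample standard deviation", {
  same <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$bias, 0)
  expect_equal(same$loa, c(0, 0))
  expect_equal(same$outlier_count, 0)

  ba <- bland_altman(c(100, 100), c(110, 90))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, 14.142, tolerance = 1e-4)
  expect_equal(ba$loa, c(-27.718, 27.718), tolerance = 1e-3)

  set.seed(5)
  x <- stats::rnorm(50); y <- x + stats::rnorm(50)
  ba2 <- bland_altman(x, y)
  expect_equal(ba2$outlier_count, sum(ba2$outliers))
  expect_lte(ba2$loa[1], ba2$loa[2])
  expect_error(bland_altman(1, 1), "2 points")
})

test_that("NPDE is reproducible and flags extreme observations at the cap", {
  pop <- cl_only_pop()
  sim <- small_dataset(n = 10, pop = pop, schedule = "sparse", seed = 51)
  a <- npde(sim$dataset, pop, n_sim = 200, seed = 3)
  b <- npde(sim$dataset, pop, n_sim = 200, seed = 3)
  expect_identical(a$npde, b$npde)
  expect_true(all(is.finite(a$npde$npde)))

  # an observation far above anything the model can simulate lands on the
  # capped maximum quantile
  boosted <- sim$dataset
  hit <- which(boosted$evid == 0)[1]
  boosted$dv[hit] <- 500
  res <- npde(boosted, pop, n_sim = 200, seed = 3)
  expect_equal(max(res$npde$npde[res$npde$id == boosted$id[hit]]),
               stats::qnorm(1 - 1 / (2 * 200)))
  expect_error(npde(sim$dataset, pop, n_sim = 50), "at least 100")
})

test_that("pcVPC bands are ordered and correction is exact for uniform predictions", {
  pop <- mpa_params()
  cohort <- data.frame(id = 1:15, egfr = 57, alb = 40, ppi = 0, dose = 500)
  sim <- simulate_cohort_profiles(pop, cohort,
                                  sampling_schedule("intensive"),
                                  seed = 61, with_noise = TRUE)
  res <- pcvpc(sim$dataset, pop, n_sim = 150, seed = 62)
  expect_true(all(res$band$sim_p5 <= res$band$sim_p50))
  expect_true(all(res$band$sim_p50 <= res$band$sim_p95))
  # identical covariates and doses mean uniform within-bin predictions, so
  # corrected observed medians equal raw observed medians
  obs <- sim$dataset[sim$dataset$evid == 0, ]
  raw_med <- tapply(obs$dv, obs$time, stats::median)
  expect_equal(as.numeric(res$band$obs_p50[order(res$band$t_mid)]),
               as.numeric(raw_med[order(as.numeric(names(raw_med)))]),
               tolerance = 1e-10)
  # self-simulated data mostly fall inside the 5-95% band
  expect_gt(res$inside_fraction, 0.75)
})
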