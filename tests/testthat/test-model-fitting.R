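test_that("noiseless tables are inverted to machine precision", {
  for (p in list(lysozyme_params(), thermolysin_params())) {
    fit <- fit_soak_model(exact_table(p))
    expect_equal(fit$params$o_max, p$o_max, tolerance = 1e-6)
    expect_equal(fit$params$tau, p$tau, tolerance = 1e-6)
    expect_lt(fit$loss, 1e-10)
    expect_equal(fit$r_squared, 1, tolerance = 1e-8)
  }
})

test_that("optimizer agrees with the exhaustive grid oracle on small tables", {
  cases <- list(
    list(truth = soak_params(0.85, 0.60), n = 25, noise = 0.08, seed = 4),
    list(truth = soak_params(0.95, 1.40), n = 30, noise = 0.05, seed = 9),
    list(truth = soak_params(0.70, 0.25), n = 20, noise = 0.10, seed = 21))
  for (cs in cases) {
    cfg <- generator_config(n_obs = cs$n, truth = cs$truth,
                            size_bins = c(0, 100, 200, 300),
                            time_range = c(0, 600), noise_sd = cs$noise)
    obs <- generate_observations(cfg, seed = cs$seed)
    g <- grid_fit_soak_model(obs)
    f <- fit_soak_model(obs)
    expect_lte(abs(g$o_max - f$params$o_max), 0.001 + 1e-9)
    expect_lte(abs(g$tau - f$params$tau), 0.001 + 1e-9)
  }
})

test_that("fit recovers generating parameters at study scale", {
  cfg <- soak_preset("lysozyme_nag")
  fits <- vapply(1:50, function(s) {
    f <- fit_soak_model(generate_observations(cfg, seed = s))
    c(f$params$o_max, f$params$tau)
  }, numeric(2))
  expect_lt(abs(median(fits[1, ]) - cfg$truth$o_max), 0.03)
  expect_lt(abs(median(fits[2, ]) / cfg$truth$tau - 1), 0.10)
})

test_that("degenerate tables are rejected as unidentifiable", {
  expect_error(fit_soak_model(data.frame(crystal_length = c(10, 20),
                                         soak_time = c(5, 10),
                                         occupancy = c(0.2, 0.3))),
               "at least 3")
  expect_error(fit_soak_model(data.frame(crystal_length = c(10, 20, 30),
                                         soak_time = c(0, 0, 0),
                                         occupancy = c(0.01, 0.01, 0.01))),
               "unidentifiable")
  expect_error(fit_soak_model(data.frame(crystal_length = c(10, 20, 30),
                                         soak_time = c(10, 20, 30),
                                         occupancy = c(0.5, 0.5, 0.5))),
               "unidentifiable")
})

test_that("identity-line R^2 follows its defining formula", {
  h <- hand_case()
  direct <- 1 - sum((h$o_refine - h$o_calc)^2) /
    sum((h$o_refine - mean(h$o_refine))^2)
  expect_equal(r_squared_unity_slope(h$o_refine, h$o_calc), direct)
  expect_equal(r_squared_unity_slope(h$o_refine, h$o_refine), 1)
  expect_equal(r_squared_unity_slope(h$o_refine,
                                     rep(mean(h$o_refine), 4)), 0)
  # worse than the mean: negative by convention
  expect_lt(r_squared_unity_slope(c(0.2, 0.8), c(0.8, 0.2)), 0)
  expect_error(r_squared_unity_slope(c(0.5, 0.5), c(0.4, 0.6)), "variance")
  # never exceeds 1; equals 1 only with zero residuals
  set.seed(2)
  for (i in 1:20) {
    a <- runif(6); b <- a + rnorm(6, 0, 0.05)
    r2 <- r_squared_unity_slope(a, b)
    expect_lte(r2, 1)
    if (any(a != b)) expect_lt(r2, 1)
  }
})

test_that("mean absolute residual and population SD match hand values", {
  h <- hand_case()
  expect_equal(mean_abs_residual(h$o_refine, h$o_calc), 0.05)
  expect_equal(mean_abs_residual(c(0.5), c(0.4)), 0.1)
  expect_equal(mean_abs_residual(h$o_refine, h$o_refine), 0)
  expect_error(mean_abs_residual(1:3, 1:4), "equal length")

  expect_equal(population_sd(c(1, 1, 1, 1)), 0)
  expect_equal(population_sd(c(0, 2)), 1)   # sample convention would give sqrt(2)
  expect_equal(population_sd(c(2, 4, 4, 4, 5, 5, 7, 9)), 2)
  expect_error(population_sd(numeric(0)), "non-empty")
})

test_that("residual-size diagnostic identifies planted and absent structure", {
  obs <- exact_table(lysozyme_params(), n = 60, seed = 3)
  fit <- fit_soak_model(obs)
  # all-zero residuals: zero polynomial, R^2 defined as 0
  flat <- fit
  flat$residuals <- rep(0, nrow(obs))
  d0 <- residual_size_diagnostic(flat, obs, degree = 3)
  expect_equal(d0$r_squared, 0)
  expect_equal(max(abs(d0$coefficients)), 0, tolerance = 1e-12)
  # planted linear trend: degree-1 fit recovers the slope exactly
  fake <- fit
  a <- 5e-4
  fake$residuals <- a * obs$crystal_length
  d1 <- residual_size_diagnostic(fake, obs, degree = 1)
  expect_equal(d1$coefficients[2], a, tolerance = 1e-10)
  expect_equal(d1$r_squared, 1, tolerance = 1e-10)
  # honest noise at study scale: diagnostic R^2 stays small
  big <- generate_observations(soak_preset("lysozyme_nag"), seed = 8)
  dbig <- residual_size_diagnostic(fit_soak_model(big), big, degree = 3)
  expect_lt(abs(dbig$r_squared), 0.05)
  expect_error(residual_size_diagnostic(fit, obs, degree = 60), "degree")
})

test_that("size binning is a half-open partition with overflow", {
  obs <- soak_observations(c(30, 60, 119, 150), c(10, 20, 30, 40),
                           c(0.2, 0.3, 0.4, 0.5))
  bins <- bin_by_size(obs, c(0, 60, 120))
  expect_equal(bins[[1]]$n, 1)            # [0, 60) holds 30
  expect_equal(bins[[2]]$n, 2)            # [60, 120) holds 60 and 119
  expect_true(bins[[3]]$overflow)
  expect_equal(bins[[3]]$n, 1)            # 150 overflows
  expect_equal(sum(vapply(bins, `[[`, numeric(1), "n")), nrow(obs))

  empty <- obs[0, , drop = FALSE]
  expect_true(all(vapply(bin_by_size(empty, c(0, 60, 120)), `[[`,
                         numeric(1), "n") == 0))

  big <- generate_observations(soak_preset("lysozyme_nag"), seed = 5)
  bb <- bin_by_size(big, c(0, 60, 120, 180, 240, 360, 480))
  expect_equal(sum(vapply(bb, `[[`, numeric(1), "n")), 354)
  expect_error(bin_by_size(obs, c(0, 60, 60)), "increasing")
})
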