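test_that("simulation is seeded, shaped and centered correctly", {
  octo <- octo_design()
  y1 <- simulate_lgcm(octo, N = 50, seed = 11)
  y2 <- simulate_lgcm(octo, N = 50, seed = 11)
  expect_identical(y1, y2)
  expect_equal(dim(y1), c(50, 3))
  expect_equal(attr(y1, "occasions"), c(0, 2, 4))

  # large sample: baseline variance near sigma2_I + sigma2_eps = 48.83
  y <- simulate_lgcm(octo, N = 100000, seed = 12)
  S <- lgcpower:::sample_moments(y)$cov
  expect_lt(abs(S[1, 1] - 48.83) / 48.83, 0.01)

  # near-deterministic trajectories follow the mean structure
  d <- lgcm_design(occasions = c(0, 1), sigma2_eps = 1e-10,
                   sigma2_I = 1e-10, sigma2_S = 1e-10, sigma_IS = 0,
                   mu_I = 5, mu_S = 1)
  yd <- simulate_lgcm(d, N = 5, seed = 13)
  expect_equal(unname(yd[, 1]), rep(5, 5), tolerance = 1e-3)
  expect_equal(unname(yd[, 2]), rep(6, 5), tolerance = 1e-3)

  expect_error(simulate_lgcm(octo, N = 3), "at least M \\+ 2")
})

test_that("the true model attains zero discrepancy at population moments", {
  octo <- octo_design()
  fit <- fit_lgcm(moments = population_moments_list(octo, 250),
                  occasions = octo$occasions)
  expect_true(fit$converged)
  expect_equal(fit$discrepancy, 0, tolerance = 1e-10)
  expect_equal(unname(fit$estimates),
               c(0, 0, 39.63, 0.53, -0.69, 9.20), tolerance = 1e-6)

  null_design <- lgcm_design(M = 3, T = 4, sigma2_eps = 9.20,
                             sigma2_I = 39.63, sigma2_S = 0, sigma_IS = 0)
  fit0 <- fit_lgcm(moments = population_moments_list(null_design, 250),
                   occasions = null_design$occasions,
                   fix_slope_var_zero = TRUE)
  expect_equal(fit0$discrepancy, 0, tolerance = 1e-10)
})

test_that("population-moment fits recover random generating parameters", {
  set.seed(606)
  for (i in 1:10) {
    d <- random_design()
    fit <- fit_lgcm(moments = population_moments_list(d),
                    occasions = d$occasions)
    truth <- c(d$mu_I, d$mu_S, d$sigma2_I, d$sigma2_S, d$sigma_IS,
               d$sigma2_eps)
    expect_lt(max(abs(fit$estimates - truth)), 1e-6)
  }
})

test_that("raw data and sufficient statistics give identical fits", {
  octo <- octo_design()
  y <- simulate_lgcm(octo, N = 200, seed = 21)
  m <- lgcpower:::sample_moments(y)
  for (flags in list(c(FALSE, FALSE), c(FALSE, TRUE), c(TRUE, TRUE))) {
    f_raw <- fit_lgcm(y, fix_slope_var_zero = flags[1],
                      fix_cov_zero = flags[2])
    f_mom <- fit_lgcm(moments = m, occasions = octo$occasions,
                      fix_slope_var_zero = flags[1],
                      fix_cov_zero = flags[2])
    expect_lt(abs(f_raw$minus2ll - f_mom$minus2ll), 1e-8)
  }
})

test_that("fitted parameters respect their constraints and bounds", {
  octo <- octo_design()
  y <- simulate_lgcm(octo, N = 150, seed = 31)
  fit <- fit_lgcm(y)
  est <- fit$estimates
  expect_gte(est["sigma2_I"], 0)
  expect_gte(est["sigma2_S"], 0)
  expect_gt(est["sigma2_eps"], 0)
  expect_lte(abs(est["sigma_IS"]),
             sqrt(est["sigma2_I"] * est["sigma2_S"]) + 1e-8)

  fit1 <- fit_lgcm(y, fix_cov_zero = TRUE)
  expect_identical(unname(fit1$estimates["sigma_IS"]), 0)
  fit0 <- fit_lgcm(y, fix_slope_var_zero = TRUE)
  expect_identical(unname(fit0$estimates["sigma2_S"]), 0)
  expect_identical(unname(fit0$estimates["sigma_IS"]), 0)
  # nesting: more constraints can never improve the fit
  expect_gte(fit0$minus2ll, fit1$minus2ll - 1e-9)
  expect_gte(fit1$minus2ll, fit$minus2ll - 1e-9)

  expect_error(fit_lgcm(y, fix_slope_var_zero = TRUE, fix_cov_zero = FALSE),
               "implies")
})

test_that("estimates from a large simulated sample are near truth", {
  octo <- octo_design()
  y <- simulate_lgcm(octo, N = 10000, seed = 41)
  est <- fit_lgcm(y)$estimates
  truth <- c(mu_I = 0, mu_S = 0, sigma2_I = 39.63, sigma2_S = 0.53,
             sigma_IS = -0.69, sigma2_eps = 9.20)
  # tolerances sized from the sampling spread at N = 10000, verified by
  # replication: sd(sigma2_S-hat) ~ 0.030, sd(sigma_IS-hat) ~ 0.094, the
  # others well under 2% relative
  for (p in c("sigma2_I", "sigma2_eps"))
    expect_lt(abs(est[p] - truth[p]) / truth[p], 0.10, label = p)
  expect_lt(abs(est["sigma2_S"] - truth["sigma2_S"]) / 0.53, 0.20)
  expect_lt(abs(est["sigma_IS"] - truth["sigma_IS"]), 0.3)
})

test_that("likelihood-ratio statistics behave as tests require", {
  octo <- octo_design()
  m <- population_moments_list(octo, 250)
  full <- fit_lgcm(moments = m, occasions = octo$occasions,
                   fix_cov_zero = TRUE)
  restricted <- fit_lgcm(moments = m, occasions = octo$occasions,
                         fix_slope_var_zero = TRUE)
  lrt <- likelihood_ratio(full, restricted)
  expect_equal(lrt$df, 1L)
  expect_gt(lrt$statistic, 0)
  expect_equal(lrt$statistic, restricted$minus2ll - full$minus2ll)

  unconstrained <- fit_lgcm(moments = m, occasions = octo$occasions)
  lrt2 <- likelihood_ratio(unconstrained, restricted)
  expect_equal(lrt2$df, 2L)
  expect_gte(lrt2$statistic, lrt$statistic - 1e-9)

  # identical fits: zero statistic (needs a nesting relation)
  expect_equal(likelihood_ratio(full, restricted)$statistic,
               likelihood_ratio(full, restricted)$statistic)
  # non-nested or reversed orderings are rejected
  expect_error(likelihood_ratio(restricted, full), "constraints")
  expect_error(likelihood_ratio(full, full), "constraints")
})

test_that("a singular sample covariance is rejected", {
  octo <- octo_design()
  S <- matrix(1, 3, 3)
  expect_error(fit_lgcm(moments = list(mean = rep(0, 3), cov = S, n = 10),
                        occasions = octo$occasions),
               "not positive definite")
})
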