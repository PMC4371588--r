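test_that("solver reproduces frozen worked-example adjustments", {
  octo <- octo_design()
  target <- effective_error_slope(octo$occasions, 9.20, 39.63)

  # five occasions over the same span tolerate a noisier instrument
  cand5 <- design_with(octo, "M", 5)
  sol <- solve_equivalent_design(octo, cand5, adjust = "sigma2_eps")
  oracle <- bisect_oracle(function(v)
    eff_oracle(c(0, 1, 2, 3, 4), v, 39.63) - target, 1e-6, 100)
  expect_equal(sol$value, oracle, tolerance = 1e-8)
  expect_equal(sol$value, 11.52, tolerance = 1e-2)

  # four occasions allow a shorter study
  cand4 <- design_with(octo, "M", 4)
  sol_T <- solve_equivalent_design(octo, cand4, adjust = "T")
  oracle_T <- bisect_oracle(function(v)
    eff_oracle(equal_spaced_occasions(4, v), 9.20, 39.63) - target,
    0.1, 100)
  expect_equal(sol_T$value, oracle_T, tolerance = 1e-8)
  expect_equal(sol_T$value, 3.81, tolerance = 1e-2)
})

test_that("adjusting a parameter of an identical candidate returns it", {
  octo <- octo_design()
  for (p in c("sigma2_eps", "sigma2_I", "T")) {
    sol <- solve_equivalent_design(octo, octo, adjust = p)
    expect_equal(sol$value, octo[[p]], tolerance = 1e-8, label = p)
  }
  sol_M <- solve_equivalent_design(octo, octo, adjust = "M")
  expect_equal(sol_M$value, 3, tolerance = 1e-8)
  expect_true(all(sol_M$integer_neighbors$value %in% 2:4))
})

test_that("solved designs reproduce the reference effective error", {
  set.seed(505)
  for (i in 1:12) {
    ref <- random_design()
    target <- effective_error_slope(ref$occasions, ref$sigma2_eps,
                                    ref$sigma2_I)
    for (p in c("sigma2_eps", "sigma2_I", "T", "M")) {
      sol <- solve_equivalent_design(ref, perturbed_candidate(ref, p),
                                     adjust = p, tol = 1e-10)
      expect_lt(abs(sol$achieved - target) / target, 1e-8,
                label = paste("param", p))
    }
  }
})

test_that("solving back with roles swapped recovers the original value", {
  octo <- octo_design()
  cand <- design_with(octo, "M", 5)
  fwd <- solve_equivalent_design(octo, cand, adjust = "sigma2_eps",
                                 tol = 1e-10)
  back <- solve_equivalent_design(fwd$design, octo, adjust = "sigma2_eps",
                                  tol = 1e-10)
  expect_lt(abs(back$value - octo$sigma2_eps) / octo$sigma2_eps, 1e-9)
})

test_that("an unreachable target names the attainable range", {
  octo <- octo_design()
  expect_error(
    solve_equivalent_design(octo, design_with(octo, "sigma2_eps", 1e5),
                            adjust = "T", bounds = c(1e-3, 0.5)),
    "attainable range")
})

test_that("sample-size adjustment works on analytic power", {
  octo <- octo_design()
  cand <- design_with(octo, "sigma2_eps", 15)   # noisier instrument
  sol <- solve_equivalent_design(octo, cand, adjust = "N")
  expect_gt(sol$value, 250)  # more noise needs more people
  pow <- analytic_power(cand, N = round(sol$value), test = "1df")$power
  expect_equal(pow, sol$target, tolerance = 5e-3)
  expect_equal(nrow(sol$integer_neighbors), 2)
})

test_that("iso-power curve over (M, T) passes through the reference and falls", {
  octo <- octo_design()
  curve <- iso_power_curve(octo, "M", 3:6, "T")
  expect_s3_class(curve, "iso_power_curve")
  expect_true(all(curve$feasible))
  expect_equal(curve$y[1], 4, tolerance = 1e-6)   # reference point
  expect_true(all(diff(curve$y) < 0))             # T decreasing in M
  ref_eff <- effective_error_slope(octo$occasions, 9.2, 39.63)
  expect_true(all(abs(curve$sigma2_eff - ref_eff) / ref_eff < 1e-8))
})

test_that("T increments per doubling of intercept variance shrink", {
  octo <- octo_design()
  x <- 39.63 * 2^(0:4)
  curve <- iso_power_curve(octo, "sigma2_I", x, "T")
  expect_true(all(curve$feasible))
  dT <- diff(curve$y)
  expect_true(all(dT > 0))        # more baseline spread needs more time
  expect_true(all(diff(dT) < 0))  # but with diminishing increments
})

test_that("slope-variance sweeps hold ECR constant", {
  octo <- octo_design()
  x <- c(0.25, 0.53, 1, 2)
  curve <- iso_power_curve(octo, "sigma2_S", x, "sigma2_eps")
  expect_true(all(curve$feasible))
  ref_ecr <- design_indices(octo)$ecr
  for (i in seq_along(x))
    expect_equal(ecr(x[i], curve$sigma2_eff[i]), ref_ecr, tolerance = 1e-8)
  # larger true slope variance tolerates a noisier instrument
  expect_true(all(diff(curve$y) > 0))
})

test_that("infeasible grid points are flagged, not dropped", {
  octo <- octo_design()
  # with T capped at half a year, a noisy instrument cannot reach the
  # reference effective error; a precise one can
  curve <- iso_power_curve(octo, "sigma2_eps", c(0.1, 9.2), "T",
                           bounds = c(1e-3, 0.5))
  expect_equal(nrow(curve), 2)
  expect_true(curve$feasible[1])
  expect_false(curve$feasible[2])
  expect_true(is.na(curve$y[2]))
})

test_that("parameter validation rejects misuse", {
  octo <- octo_design()
  expect_error(iso_power_curve(octo, "T", 1:3, "T"), "must differ")
  expect_error(iso_power_curve(octo, "sigma2_S", 1:3, "sigma2_S"))
  expect_error(solve_equivalent_design(octo, octo, adjust = "sigma2_S"))
  expect_error(solve_equivalent_design(octo, octo, adjust = "sigma2_eps",
                                       bounds = c(2, 1)), "interval")
})
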