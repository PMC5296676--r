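test_that("exact Bigelow data recover z and D_Tref with zero-width intervals", {
  tab <- exact_bigelow_table(z = 30, d_tref = 50, t_ref = 120)
  f <- fit_secondary(tab, t_ref = 120)
  expect_equal(f$z, 30)
  expect_equal(f$d_tref, 50)
  expect_equal(f$z_ci95_half, 0, tolerance = 1e-9)
  expect_equal(f$d_tref_ci95_half, 0, tolerance = 1e-9)
})

test_that("estimates are delta transforms of the oracle OLS coefficients", {
  set.seed(421)
  temps <- c(80, 95, 110, 125)
  d <- 10^(log10(60) + (120 - temps) / 28 + rnorm(4, sd = 0.03))
  f <- fit_secondary(dt_table(temps, d), t_ref = 120)
  o <- oracle_ols(120 - temps, log10(d))
  expect_equal(f$z, 1 / o$slope, tolerance = 1e-10)
  expect_equal(f$d_tref, 10^o$intercept, tolerance = 1e-10)
  expect_equal(f$z_ci95_half, (1 / o$slope)^2 * o$t_crit * o$se_slope,
               tolerance = 1e-10)
  expect_equal(f$d_tref_ci95_half,
               log(10) * 10^o$intercept * o$t_crit * o$se_intercept,
               tolerance = 1e-10)
})

test_that("fit is invariant to row order and t_ref never changes z", {
  set.seed(422)
  tab <- carnitine_dt("original")
  perm <- sample(nrow(tab))
  shuffled <- dt_table(tab$temperature[perm], tab$d_value[perm],
                       tab$ci95_half[perm])
  f1 <- fit_secondary(tab, t_ref = 120)
  f2 <- fit_secondary(shuffled, t_ref = 120)
  expect_equal(f1$z, f2$z)
  expect_equal(f1$d_tref, f2$d_tref)

  f3 <- fit_secondary(tab, t_ref = 100)
  expect_equal(f3$z, f1$z)            # z is t_ref-free
  expect_false(isTRUE(all.equal(f3$d_tref, f1$d_tref)))
  # and the two parametrizations agree through the model equation
  expect_equal(log10(f3$d_tref), log10(f1$d_tref) + (120 - 100) / f1$z,
               tolerance = 1e-10)
})

test_that("increasing D with temperature is rejected", {
  tab <- dt_table(c(80, 90, 100), c(10, 20, 40))
  expect_error(fit_secondary(tab), "temperature dependence")
  expect_error(dt_table(c(80, 90), c(10, 20)), "at least 3")
  expect_error(dt_table(c(80, 80, 90), c(1, 2, 3)), "distinct")
  expect_error(dt_table(c(80, 90, 100), c(1, -2, 3)), "positive")
})

test_that("predict back-transforms the linear model with band intervals", {
  tab <- carnitine_dt("original")
  f <- fit_secondary(tab, t_ref = 120)
  p <- predict(f, temperature = c(90, 120), interval = "prediction")
  expect_equal(p$d_value[2], f$d_tref * 10^0, tolerance = 1e-12)
  expect_true(all(p$lower < p$d_value & p$d_value < p$upper))
  pc <- predict(f, temperature = c(90, 120), interval = "confidence")
  expect_true(all(pc$lower >= p$lower & pc$upper <= p$upper))
  # asymmetric on the D scale, symmetric on log10 D
  expect_equal(log10(p$upper) - log10(p$d_value),
               log10(p$d_value) - log10(p$lower), tolerance = 1e-12)
})

test_that("delta transforms follow the first-order propagation rules", {
  expect_equal(propagate_delta("d_from_inv_d", 100, 1e-4), 1)
  expect_equal(propagate_delta("z_from_inv_z", 30, 0.001), 0.9)
  expect_equal(propagate_delta("d_from_log_d", 10, 1 / log(10)), 10)
  expect_equal(propagate_delta("d_from_log_d", 5, 0), 0)
  # positively homogeneous in the input half-width
  set.seed(423)
  for (kind in c("d_from_inv_d", "z_from_inv_z", "d_from_log_d")) {
    v <- runif(1, 1, 100)
    d <- runif(1, 0, 1)
    expect_equal(propagate_delta(kind, v, 2 * d),
                 2 * propagate_delta(kind, v, d), tolerance = 1e-12)
  }
  expect_error(propagate_delta("d_from_inv_d", -1, 0.1), "positive")
  expect_error(propagate_delta("d_from_inv_d", 1, -0.1), "non-negative")
})
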