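test_that("summarize_pooled reports mean, n-1 SD and the CI convention", {
  cfg <- mc_config()
  s <- summarize_pooled(c(0, 0, 2, 2), cfg)
  expect_equal(s$mean, 1)
  expect_equal(s$sd, sqrt(4 / 3))
  expect_equal(s$ci95_half, 2 * sqrt(4 / 3))
  const <- summarize_pooled(rep(5, 10), cfg)
  expect_equal(const$sd, 0)
  expect_equal(const$ci95_half, 0)
  expect_error(summarize_pooled(1, cfg), "at least 2")

  set.seed(441)
  v <- rnorm(10000)
  s <- summarize_pooled(v, cfg)
  expect_lt(abs(s$mean), 3 / sqrt(10000))
  expect_lt(abs(s$sd - 1), 0.03)
  # percentile convention on the same draws
  pc <- summarize_pooled(v, mc_config(summary_method = "percentile"))
  expect_lt(abs(pc$ci95_half - 1.96), 0.08)
})

test_that("zero input uncertainty collapses stage 1 to the deterministic fit", {
  tab0 <- dt_table(c(80, 90, 100, 110, 120),
                   10^(log10(50) + (120 - c(80, 90, 100, 110, 120)) / 30) *
                     10^c(0.01, -0.02, 0.015, -0.01, 0.005), 0)
  det <- fit_secondary(tab0, t_ref = 120)
  mc <- run_two_stage_mc(tab0, mc_config(n_outer = 30, n_inner = 200, seed = 9))
  expect_true(all(mc$d_tref$per_outer$estimate == det$d_tref))
  expect_true(all(mc$z$per_outer$estimate == det$z))
  expect_true(all(mc$d_tref$per_outer$ci95_half == det$d_tref_ci95_half))
  # pooled means converge to the deterministic estimates
  expect_lt(abs(mc$d_tref$mean - det$d_tref),
            3 * mc$d_tref$sd / sqrt(mc$d_tref$n))
  expect_lt(abs(mc$z$mean - det$z), 3 * mc$z$sd / sqrt(mc$z$n))
})

test_that("identical seed and config give bit-identical results", {
  tab <- carnitine_dt("original")
  cfg <- mc_config(n_outer = 40, n_inner = 40, seed = 17)
  a <- run_two_stage_mc(tab, cfg)
  b <- run_two_stage_mc(tab, cfg)
  expect_identical(a$d_tref$pooled, b$d_tref$pooled)
  expect_identical(a$z$pooled, b$z$pooled)
  c2 <- run_two_stage_mc(tab, mc_config(n_outer = 40, n_inner = 40, seed = 18))
  expect_false(identical(a$d_tref$pooled, c2$d_tref$pooled))
})

test_that("pooled CIs grow monotonically with the input CI scale", {
  tab <- carnitine_dt("original")
  for (seed in c(3, 11)) {
    hw <- sapply(c(1, 2, 5), function(scale) {
      t2 <- dt_table(tab$temperature, tab$d_value, scale * tab$ci95_half)
      mc <- run_two_stage_mc(t2, mc_config(n_outer = 100, n_inner = 100,
                                           seed = seed))
      c(mc$d_tref$ci95_half, mc$z$ci95_half)
    })
    expect_true(all(diff(hw[1, ]) > 0))
    expect_true(all(diff(hw[2, ]) > 0))
  }
})

test_that("pooled means stay on the deterministic estimates", {
  for (errors in c("original", "expanded")) {
    tab <- carnitine_dt(errors)
    det <- fit_secondary(tab, t_ref = 120)
    mc <- run_two_stage_mc(tab, mc_config(seed = 5))
    se_d <- mc$d_tref$sd / sqrt(mc$config$n_outer)
    se_z <- mc$z$sd / sqrt(mc$config$n_outer)
    expect_lt(abs(mc$d_tref$mean - det$d_tref), 3 * se_d)
    expect_lt(abs(mc$z$mean - det$z), 3 * se_z)
  }
})

test_that("narrow-error pooled samples are approximately normal", {
  mc <- run_two_stage_mc(carnitine_dt("original"), mc_config(seed = 2))
  for (p in list(mc$d_tref, mc$z)) {
    m <- oracle_moments(p$pooled)
    expect_lt(abs(m$skewness), 0.3)
    expect_lt(abs(m$excess_kurtosis), 0.5)
  }
  # the expanded case is a wider scale mixture: still near-symmetric for
  # D_Tref, but with heavier-than-normal tails
  mce <- run_two_stage_mc(carnitine_dt("expanded"), mc_config(seed = 2))
  expect_lt(abs(oracle_moments(mce$d_tref$pooled)$skewness), 0.3)
})

test_that("continuous stage-2 sampling agrees with the discretized default", {
  tab <- carnitine_dt("expanded")
  a <- run_two_stage_mc(tab, mc_config(n_outer = 200, n_inner = 200, seed = 6))
  b <- run_two_stage_mc(tab, mc_config(n_outer = 200, n_inner = 200, seed = 6,
                                       stage2_sampling = "normal"))
  expect_lt(abs(a$d_tref$ci95_half - b$d_tref$ci95_half),
            0.1 * a$d_tref$ci95_half)
  expect_lt(abs(a$z$ci95_half - b$z$ci95_half), 0.1 * a$z$ci95_half)
})

test_that("degenerate outer draws are redrawn with a count, or abort", {
  # mild non-monotonicity risk: some draws invert the temperature trend
  tab <- dt_table(c(80, 90, 100), c(200, 100, 50), c(120, 60, 30))
  mc <- run_two_stage_mc(tab, mc_config(n_outer = 200, n_inner = 10, seed = 3))
  expect_gt(mc$n_rejected, 0)
  expect_length(mc$d_tref$pooled, 200 * 10)
  # hopeless case: trend buried in noise, rejection rate above the cap
  flat <- dt_table(c(80, 90, 100), c(110, 100, 90), c(80, 80, 80))
  expect_error(
    run_two_stage_mc(flat, mc_config(n_outer = 100, n_inner = 10, seed = 3)),
    "rejection rate")
  expect_error(
    run_two_stage_mc(flat, mc_config(n_outer = 100, n_inner = 10, seed = 3,
                                     reject_policy = "error")),
    "non-positive")
})

test_that("validate_sampler recovers the tabulated means and CIs", {
  tab <- carnitine_dt("expanded")
  cfg <- mc_config(seed = 8)
  v <- validate_sampler(tab, n = 500, cfg)
  sig <- tab$ci95_half / cfg$ci_to_sigma_factor
  expect_true(all(abs(v$recovered_mean - tab$d_value) <=
                    3 * sig / sqrt(500)))
  # at 80 degC the recovered pair sits near the inputs (896.3 / 267.7)
  expect_lt(abs(v$recovered_mean[1] - 896.3), 20)
  expect_lt(abs(v$recovered_ci95_half[1] - 267.7), 30)

  # zero-sigma rows are recovered exactly
  z <- validate_sampler(dt_table(c(80, 90, 100), c(100, 50, 25), 0), 50, cfg)
  expect_equal(z$recovered_mean, c(100, 50, 25))
  expect_equal(z$recovered_ci95_half, c(0, 0, 0))

  # large n: recovered CI within 2% of the discrete distribution's
  # analytic SD times the summary factor
  d <- discretize_normal(896.3, 267.7 / 2, 4)
  analytic_sd <- sqrt(sum(d$probabilities * (d$midpoints - 896.3)^2))
  vl <- validate_sampler(tab, n = 50000, cfg)
  expect_lt(abs(vl$recovered_ci95_half[1] - 2 * analytic_sd),
            0.02 * 2 * analytic_sd)
})

test_that("sensitivity analysis is reproducible and tabulates every size", {
  tab <- carnitine_dt("expanded")
  cfg <- mc_config(seed = 12)
  a <- sensitivity_analysis(tab, c(25, 50), cfg)
  b <- sensitivity_analysis(tab, c(25, 50), cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 4)  # 2 sizes x 2 parameters
  expect_setequal(unique(a$parameter), c("d_tref", "z"))
  m <- sensitivity_analysis(tab, cbind(c(20, 40), c(30, 10)), cfg)
  expect_equal(m$n_outer, rep(c(20, 40), each = 2))
  expect_equal(m$n_inner, rep(c(30, 10), each = 2))
})
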