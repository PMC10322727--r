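test_that("case probabilities follow the latent-normal dichotomisation", {
  # symmetry: threshold at the centre of the unexposed score distribution
  pm <- population_model(0.25, dicho_threshold(0), delta = 0)
  expect_equal(case_prob(pm, 0), 0.5, tolerance = 1e-10)

  # a flat logistic link gives probability 1/2 whatever the arm mean
  pm2 <- population_model(0.25, dicho_logistic(0, 1e-8), delta = 1.3)
  expect_equal(case_prob(pm2, 0), 0.5, tolerance = 1e-6)
  expect_equal(case_prob(pm2, 1), 0.5, tolerance = 1e-6)

  # the calibrated default reproduces the 15% marginal prevalence
  pm3 <- ref_pop()
  p <- case_prob(pm3, c(0, 1))
  expect_equal(0.75 * p[1] + 0.25 * p[2], 0.15, tolerance = 1e-8)
  expect_true(all(p > 0 & p < 1))
})

test_that("full-population log OR matches its closed-form construction", {
  pm0 <- population_model(0.4, dicho_threshold(1), delta = 0)
  expect_equal(full_log_or(pm0), 0, tolerance = 1e-12)

  expect_equal(full_log_or(ref_pop()), 0.405, tolerance = 1e-8)

  # frozen oracle: the (c, delta) pair solved by independent Phi arithmetic
  pm <- population_model(0.25, dicho_threshold(ORACLE_C),
                         delta = ORACLE_DELTA)
  expect_equal(full_log_or(pm), 0.405, tolerance = 1e-6)
})

test_that("calibration hits its targets and degenerates correctly", {
  pm <- calibrate_dichotomisation(0.15, 0.405, 0.25, kind = "threshold")
  expect_equal(pm$dicho$c, ORACLE_C, tolerance = 1e-6)
  expect_equal(pm$delta, ORACLE_DELTA, tolerance = 1e-6)

  # null effect: delta = 0 and the threshold is the marginal normal quantile
  pm0 <- calibrate_dichotomisation(0.2, 0, 0.3, kind = "threshold")
  expect_equal(pm0$delta, 0, tolerance = 1e-8)
  expect_equal(pm0$dicho$c, qnorm(0.8), tolerance = 1e-8)

  # round-trips for both kinds, including non-default targets
  for (kind in c("threshold", "logistic")) {
    for (tgt in list(c(0.15, 0.405), c(0.3, -0.5), c(0.08, 1))) {
      pmk <- calibrate_dichotomisation(tgt[1], tgt[2], 0.25, kind = kind)
      p <- case_prob(pmk, c(0, 1))
      expect_equal(0.75 * p[1] + 0.25 * p[2], tgt[1], tolerance = 1e-8)
      expect_equal(full_log_or(pmk), tgt[2], tolerance = 1e-8)
    }
  }
})

test_that("threshold rule is the steep-slope limit of the logistic rule", {
  beta <- 50
  pm_t <- ref_pop()
  c0 <- pm_t$dicho$c
  pm_l <- population_model(0.25, dicho_logistic(-beta * c0, beta),
                           delta = pm_t$delta)
  expect_lt(abs(case_prob(pm_l, 0) - case_prob(pm_t, 0)), 1e-3)
  expect_lt(abs(case_prob(pm_l, 1) - case_prob(pm_t, 1)), 1e-3)
  expect_lt(abs(full_log_or(pm_l) - full_log_or(pm_t)), 1e-3)

  ms <- missingness_model(gy = log(0.75))
  ms$g0 <- solve_missingness_intercept(pm_t, ms, 0.6)
  expect_lt(abs(complete_case_log_or(pm_l, ms)$log_or_cc -
                  complete_case_log_or(pm_t, ms)$log_or_cc), 1e-3)
})

test_that("quadrature matches a wide finite-range rule (truncation check)", {
  pm <- calibrate_dichotomisation(kind = "logistic")
  ms <- missingness_model(g0 = 0.2, gx = 0.3, gy = log(0.8), gxy = 0.1)
  for (lim in c(10, 20)) {
    manual <- sapply(0:1, function(x) {
      mu <- if (x == 1) pm$delta else 0
      num <- integrate(function(y)
        plogis(pm$dicho$alpha + pm$dicho$beta * y) *
          obs_prob(ms, y, x) * dnorm(y, mu),
        mu - lim, mu + lim, rel.tol = 1e-12)$value
      den <- integrate(function(y) obs_prob(ms, y, x) * dnorm(y, mu),
                       mu - lim, mu + lim, rel.tol = 1e-12)$value
      num / den
    })
    b <- complete_case_log_or(pm, ms)
    expect_equal(b$log_or_cc, qlogis(manual[2]) - qlogis(manual[1]),
                 tolerance = 1e-8)
  }
})

test_that("selection on exposure only, or factorising in (x, d), is unbiased", {
  pm <- ref_pop()
  # exposure-only missingness (continuous-outcome model, gy = gxy = 0)
  ms_x <- missingness_model(g0 = -0.5, gx = 1.2)
  bx <- complete_case_log_or(pm, ms_x)
  expect_lt(abs(bx$bias), 1e-6)

  # binary-outcome selection, no interaction, multiplicative (log link):
  # pi(d, x) = exp(g0) exp(gx x) exp(gd d) = a(x) b(d)
  ms_f <- missingness_model(g0 = -2, gx = -0.5, gy = -0.7, link = "log",
                            depends_on = "d")
  expect_lt(abs(complete_case_log_or(pm, ms_f)$bias), 1e-6)

  # binary-outcome selection depending on d alone (any link)
  ms_d <- missingness_model(g0 = 0.3, gy = -1.1, depends_on = "d")
  expect_lt(abs(complete_case_log_or(pm, ms_d)$bias), 1e-6)

  # contrast: the same strength of selection on the *continuous* outcome
  # does bias the complete-case log OR
  ms_y <- missingness_model(g0 = 0.3, gy = -1.1)
  expect_gt(abs(complete_case_log_or(pm, ms_y)$bias), 1e-3)
})

test_that("selection intercept solver matches closed forms and the oracle", {
  pm <- ref_pop()
  expect_equal(solve_missingness_intercept(pm, missingness_model(), 0.8),
               qlogis(0.8), tolerance = 1e-8)
  expect_equal(solve_missingness_intercept(pm, missingness_model(), 0.5),
               0, tolerance = 1e-8)

  ms <- missingness_model(gy = log(0.75))
  g0 <- solve_missingness_intercept(pm, ms, 0.6)
  expect_equal(g0, ORACLE_G0_60, tolerance = 1e-6)
  ms$g0 <- g0
  expect_equal(complete_case_log_or(pm, ms)$frac_observed, 0.6,
               tolerance = 1e-8)
})

test_that("analytic complete-case log OR reproduces frozen quadrature values", {
  pm <- ref_pop()
  ms <- missingness_model(gy = log(0.75))
  ms$g0 <- solve_missingness_intercept(pm, ms, 0.6)
  b40 <- complete_case_log_or(pm, ms)
  expect_equal(b40$log_or_cc, ORACLE_CC_LOR_40, tolerance = 1e-6)
  expect_equal(b40$bias, b40$log_or_cc - b40$log_or_full, tolerance = 1e-12)

  ms$g0 <- solve_missingness_intercept(pm, ms, 0.2)
  expect_equal(complete_case_log_or(pm, ms)$log_or_cc, ORACLE_CC_LOR_80,
               tolerance = 1e-6)
})

test_that("bias curves are zero under MCAR and monotone in both factors", {
  pm <- ref_pop()
  tab <- bias_curve(pm, gy_or = c(1, 0.9, 0.75, 0.6),
                    frac_missing = c(0.2, 0.4, 0.6, 0.8))
  expect_equal(nrow(tab), 16L)
  # MCAR column: no bias anywhere
  expect_true(all(abs(tab$bias[tab$gy_or == 1]) < 1e-8))
  # weak association: small bias at every level of missingness
  expect_true(all(abs(tab$percent_bias[tab$gy_or == 0.9]) < 2))
  # strictly increasing |bias| with fraction missing at fixed strength
  for (g in c(0.9, 0.75, 0.6)) {
    col <- tab$percent_bias[tab$gy_or == g]
    expect_true(all(diff(abs(col)) > 0))
  }
  # non-decreasing |bias| with |log OR_y| in the weak-to-moderate regime
  # (very strong selection at low missingness bends the curve back; see the
  # methods vignette)
  for (f in unique(tab$frac_missing)) {
    row <- abs(tab$percent_bias[tab$frac_missing == f & tab$gy_or >= 0.75])
    expect_true(all(diff(row) >= 0))
  }
  expect_true(all(tab$frac_observed > 0 & tab$frac_observed < 1))
})

test_that("log-link observation probabilities are capped with a warning", {
  ms <- missingness_model(g0 = 0.5, gy = 0.5, link = "log")
  expect_warning(p <- obs_prob(ms, c(-1, 3), c(0, 0)), "capped")
  expect_true(all(p >= 0 & p <= 1))
  # logit link never caps
  expect_silent(obs_prob(missingness_model(g0 = 5, gy = 2), 10, 1))
})

test_that("percent bias is undefined at a null full-population effect", {
  pm <- calibrate_dichotomisation(target_log_or = 0)
  ms <- missingness_model(g0 = 1, gy = log(0.75))
  b <- complete_case_log_or(pm, ms)
  expect_error(percent_bias(b), "undefined")
})
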