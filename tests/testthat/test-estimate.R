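test_that("logistic fits reproduce closed-form grouped results", {
  # balanced 2x2: exposure log OR exactly 0
  f <- fit_logistic(c(0, 0, 1, 1), cbind(1, x = c(0, 1, 0, 1)))
  expect_equal(f$estimate, 0, tolerance = 1e-8)
  expect_true(f$converged)

  # grouped data: the saturated fit equals the log cross-product ratio with
  # the Woolf standard error, for several tables
  tables <- list(c(3012, 72, 199, 71),   # tn, fp, fn, tp
                 c(2500, 640, 126, 156),
                 c(40, 10, 7, 23))
  for (ct in tables) {
    # rows: (a, d) in (0,0), (1,0), (0,1), (1,1)
    y <- c(0, 0, 1, 1); a <- c(0, 1, 0, 1)
    w <- c(ct[1], ct[2], ct[3], ct[4])
    f <- fit_logistic(y, cbind(1, x = a), weights = w)
    expect_equal(f$estimate, log(ct[4] * ct[1] / (ct[2] * ct[3])),
                 tolerance = 1e-7)
    expect_equal(f$se, sqrt(sum(1 / ct)), tolerance = 1e-5)
  }
  # the first table is the packaged current-proxy cross-tabulation:
  # its log OR is about 2.70
  f1 <- fit_logistic(c(0, 0, 1, 1), cbind(1, x = c(0, 1, 0, 1)),
                     weights = tables[[1]])
  expect_equal(f1$estimate, 2.70, tolerance = 0.005)
})

test_that("complete-case estimate equals an independent record-level glm", {
  sp <- scenario_spec(n = 4000, seed = 17, frac_missing = 0.4)
  coh <- impose_missingness(draw_cohort(sp))
  f <- complete_case_estimate(coh)
  g <- glm(d ~ x, family = binomial, data = coh[coh$r == 1, ],
           control = glm.control(epsilon = 1e-12))
  expect_equal(f$estimate, unname(coef(g)["x"]), tolerance = 1e-7)
  expect_equal(f$se, unname(sqrt(diag(vcov(g)))["x"]), tolerance = 1e-7)
  expect_equal(f$n_used, sum(coh$r == 1))

  # no missingness: identical to the full-data fit
  full <- draw_cohort(sp)
  ff <- complete_case_estimate(full)
  gg <- glm(d ~ x, family = binomial, data = full)
  expect_equal(ff$estimate, unname(coef(gg)["x"]), tolerance = 1e-7)
})

test_that("separation is reported, never silent", {
  f <- fit_logistic(c(0, 0, 1, 1), cbind(1, x = c(0, 0, 1, 1)))
  expect_false(f$converged)
  expect_match(f$message, "separation|converge")
})

test_that("single imputation is proper, deterministic, and a no-op without missing data", {
  sp <- scenario_spec(n = 3000, seed = 23, frac_missing = 0.4)
  full <- draw_cohort(sp)
  expect_identical(impute_once(full), full$d)

  coh <- impose_missingness(full)
  d1 <- impute_once(coh, seed = 99)
  d2 <- impute_once(coh, seed = 99)
  expect_identical(d1, d2)
  expect_false(anyNA(d1))
  # observed values are never altered
  obs <- !is.na(coh$d)
  expect_identical(d1[obs], coh$d[obs])

  # missing auxiliary is refused (chained equations handle that case)
  coh2 <- impose_aux_missingness(coh, frac = 0.25)
  expect_error(impute_once(coh2), "chained")
})

test_that("MI recovers the truth when missingness is MAR given the auxiliary", {
  # selection depends on the always-observed proxy (and exposure), so the
  # mechanism is exactly MAR given (x, a), and with binary x and a the
  # logistic imputation model for d | x, a is exactly correctly specified:
  # the pooled MI estimate must be consistent for 0.405
  n_rep <- 60
  sp <- scenario_spec(n = 4000, seed = 101, m = 10)
  sp$aux <- aux_model(0.95, 0.95)
  est <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    coh <- draw_cohort(sp, replicate = r)
    set.seed(3000 + r)
    p_obs <- plogis(0.9 + 0.3 * coh$x - 1.4 * coh$a)
    robs <- rbinom(nrow(coh), 1L, p_obs)
    coh$r <- robs
    coh$y[robs == 0L] <- NA_real_
    coh$d[robs == 0L] <- NA_integer_
    est[r] <- mi_estimate(coh, m = 10, seed = 5000 + r)$qbar
  }
  s <- summarise_replicates(est, 0.405)
  expect_lt(abs(s$bias), 3 * s$mc_error)
})

test_that("complete-case analysis is unbiased under MCAR", {
  n_rep <- 100
  est <- numeric(n_rep)
  sp <- scenario_spec(n = 10000, seed = 77, frac_missing = 0.4, gy_or = 1)
  for (r in seq_len(n_rep)) {
    coh <- impose_missingness(draw_cohort(sp, replicate = r))
    est[r] <- complete_case_estimate(coh)$estimate
  }
  s <- summarise_replicates(est, 0.405)
  expect_lt(abs(s$bias), 3 * s$mc_error)
})

test_that("chained imputation completes both variables and respects structure", {
  sp <- scenario_spec(n = 3000, seed = 29, frac_missing = 0.4,
                      frac_missing_aux = 0.25)
  coh <- impose_aux_missingness(impose_missingness(draw_cohort(sp)))
  set.seed(1)
  comp <- chained_imputation(coh, burn_in = 5)
  expect_false(anyNA(comp$d))
  expect_false(anyNA(comp$a))
  obs_d <- !is.na(coh$d); obs_a <- !is.na(coh$a)
  expect_identical(comp$d[obs_d], coh$d[obs_d])
  expect_identical(comp$a[obs_a], coh$a[obs_a])

  # fully observed auxiliary: the auxiliary is returned untouched
  coh2 <- impose_missingness(draw_cohort(sp))
  comp2 <- chained_imputation(coh2, seed = 3)
  expect_identical(comp2$a, coh2$a)
  expect_false(anyNA(comp2$d))

  # fully observed outcome, partially observed auxiliary: single a-step
  coh3 <- impose_aux_missingness(draw_cohort(sp), frac = 0.25)
  comp3 <- chained_imputation(coh3, seed = 4)
  expect_identical(comp3$d, coh3$d)
  expect_false(anyNA(comp3$a))
})

test_that("Rubin's rules match the worked example and the pooling identity", {
  p <- pool_rubin(c(0.4, 0.6), c(0.01, 0.01))
  expect_equal(p$qbar, 0.5, tolerance = 1e-12)
  expect_equal(p$w, 0.01, tolerance = 1e-12)
  expect_equal(p$b, 0.02, tolerance = 1e-12)
  expect_equal(p$t, 0.04, tolerance = 1e-12)
  expect_equal(p$se, 0.2, tolerance = 1e-12)

  # degenerate pooling: identical imputations carry no missing information
  p0 <- pool_rubin(rep(0.3, 5), rep(0.02, 5))
  expect_equal(p0$t, p0$w, tolerance = 1e-15)
  expect_lt(p0$fmi, 1e-12)

  # identity and FMI bounds on random pools
  set.seed(4)
  for (k in 1:20) {
    m <- sample(2:50, 1)
    p <- pool_rubin(rnorm(m), runif(m, 0.001, 0.1))
    expect_identical(p$t, p$w + (1 + 1 / p$m) * p$b)
    expect_gte(p$fmi, 0); expect_lte(p$fmi, 1)
    expect_gte(p$fmi_simple, 0); expect_lte(p$fmi_simple, 1)
  }
})

test_that("MI equals the complete-case fit when nothing is missing", {
  sp <- scenario_spec(n = 2000, seed = 37)
  full <- draw_cohort(sp)
  p <- mi_estimate(full, m = 5)
  f <- complete_case_estimate(full)
  expect_identical(p$qbar, f$estimate)
  expect_equal(p$b, 0)
  expect_equal(p$se, f$se, tolerance = 1e-12)
})

test_that("MI estimates are reproducible from the stage seed", {
  sp <- scenario_spec(n = 2000, seed = 41, frac_missing = 0.4)
  coh <- impose_missingness(draw_cohort(sp))
  p1 <- mi_estimate(coh, m = 5)
  p2 <- mi_estimate(coh, m = 5)
  expect_identical(p1$qbar, p2$qbar)
  expect_identical(p1$t, p2$t)
})
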