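test_that("saturated fit matches the closed-form group-odds oracle", {
  # diseased: 6 exposed, 4 unexposed; non-diseased base: 9 exposed, 21
  # unexposed; 1 + 1 diseased also in the base sample (n1 = 2, n_D = 10)
  ds <- casebase_table_dataset(6, 4, 9 + 1, 21 + 1, 1, 1)
  fit <- fit_casebase(ds, ~ x)
  expect_equal(exp(fit$logistic$alpha_star), 4 / 21, tolerance = 1e-10)
  expect_equal(exp(fit$logistic$alpha_star + fit$logistic$beta_hat[["x"]]),
               6 / 9, tolerance = 1e-10)
  expect_equal(fit$rho$rho_hat, 0.2)
  expect_equal(exp(fit$alpha_hat), (4 / 21) * 0.2, tolerance = 1e-10)
  r <- estimate_risk(fit, data.frame(x = 0))
  oracle_odds <- (4 / 21) * 0.2
  expect_equal(r$point, oracle_odds / (1 + oracle_odds), tolerance = 1e-10)
})

test_that("rho and gamma estimates follow the binomial formulas", {
  est <- estimate_rho_gamma(list(n_D = 500L, n1 = 50L, n11 = 5L))
  expect_equal(est$rho_hat, 0.1)
  expect_equal(est$var_rho, 0.1 * 0.9 / 500)
  expect_equal(est$var_log_rho, 0.018)
  expect_equal(est$gamma_hat, 0.1)

  # census of the diseased: rho = 1 and var(log rho) = 0
  census <- estimate_rho_gamma(list(n_D = 120L, n1 = 120L, n11 = 40L))
  expect_equal(census$rho_hat, 1)
  expect_equal(census$var_log_rho, 0)

  # n1 = 0: not estimable
  none <- estimate_rho_gamma(list(n_D = 80L, n1 = 0L, n11 = 0L))
  expect_false(none$estimable)

  # n11 = 0: gamma unavailable, rho unaffected
  nog <- estimate_rho_gamma(list(n_D = 80L, n1 = 10L, n11 = 0L))
  expect_true(nog$estimable)
  expect_true(is.na(nog$gamma_hat))
  expect_equal(nog$rho_hat, 10 / 80)
})

test_that("without diseased base members only odds ratios are available", {
  ds <- casebase_table_dataset(6, 4, 9, 21, 0, 0)
  fit <- fit_casebase(ds, ~ x)
  expect_false(fit$rho$estimable)
  or <- estimate_or(fit, "x")
  expect_equal(or$transformed, log((6 / 9) / (4 / 21)), tolerance = 1e-10)
  expect_error(estimate_risk(fit, data.frame(x = 0)), "not estimable")
  expect_error(estimate_rr(fit, data.frame(x = 1), data.frame(x = 0)),
               "not estimable")
})

test_that("a full census (rho = 1) reproduces a plain cohort analysis", {
  m <- scenario1_model()
  pop <- simulate_population(m, 4000, seed = 61)
  ds <- draw_case_base_sample(pop, sampling_design(4000, 0, 1), seed = 62)
  fit <- fit_casebase(ds, ~ x)
  expect_equal(fit$rho$rho_hat, 1)
  expect_equal(fit$alpha_hat, fit$logistic$alpha_star)

  ref <- glm(disease ~ x, family = binomial(), data = as.data.frame(ds),
             control = glm.control(epsilon = 1e-12))
  expect_equal(unname(fit$logistic$coefficients), unname(coef(ref)),
               tolerance = 1e-10)
  expect_equal(unname(fit$logistic$vcov), unname(vcov(ref)),
               tolerance = 1e-8)
  # risks equal empirical group proportions in the saturated census fit
  r <- estimate_risk(fit, data.frame(x = c(0, 1)))
  prop <- tapply(ds$disease, ds$x, mean)
  expect_equal(r$point, as.vector(prop), tolerance = 1e-10)
})

test_that("separation and rank deficiency are reported as errors", {
  ds <- casebase_table_dataset(6, 4, 9, 21, 1, 1)
  all_dis <- ds[ds$disease == 1L, ]
  expect_error(fit_sample_logistic(all_dis, ~ x), "diseased and non-diseased")

  sep <- ds
  sep$disease <- as.integer(sep$x == 1)  # exposure predicts disease exactly
  sep$in_case_sample <- sep$disease * sep$in_case_sample
  expect_error(fit_sample_logistic(sep, ~ x), "separation")

  dup <- ds
  dup$x2 <- dup$x
  expect_error(fit_sample_logistic(dup, ~ x + x2), "rank deficient")
})

test_that("relative risk equals the ratio of risks and is 1 for x1 = x0", {
  ds <- scenario1_dataset()
  fit <- fit_casebase(ds, ~ x)
  r <- estimate_risk(fit, data.frame(x = c(0, 1)))
  rr <- estimate_rr(fit, data.frame(x = 1), data.frame(x = 0))
  expect_equal(rr$point, r$point[2] / r$point[1], tolerance = 1e-12)
  same <- estimate_rr(fit, data.frame(x = 1), data.frame(x = 1))
  expect_equal(same$point, 1)
  expect_equal(same$se, 0)
})

test_that("delta-method log RR variance matches a numerical gradient", {
  m3 <- scenario3_model()
  des <- sampling_design(100000, 0.05, 0.005)
  set.seed(71)
  seeds <- sample.int(1e6, 6)
  x1 <- data.frame(x1 = 1, x2 = 1); x0 <- data.frame(x1 = 0, x2 = 0)
  for (s in seeds) {
    pop <- simulate_population(m3, 30000, seed = s)
    ds <- draw_case_base_sample(pop, sampling_design(30000, 0.05, 0.02),
                                seed = s + 1L)
    fit <- fit_casebase(ds, ~ x1 + x2)
    if (!fit$rho$estimable) next
    rr <- estimate_rr(fit, x1, x0)
    f <- function(th) {
      lp1 <- th[1] + th[2] + th[3] + th[4]
      lp0 <- th[1] + th[4]
      log(plogis(lp1)) - log(plogis(lp0))
    }
    th <- c(fit$logistic$alpha_star, fit$logistic$beta_hat,
            log(fit$rho$rho_hat))
    g <- vapply(1:4, function(i) {
      e <- replace(rep(0, 4), i, 1e-6)
      (f(th + e) - f(th - e)) / 2e-6
    }, 0)
    Sig <- rbind(cbind(fit$logistic$vcov, 0), 0)
    Sig[4, 4] <- fit$rho$var_log_rho
    expect_equal(rr$se^2, drop(t(g) %*% Sig %*% g), tolerance = 1e-7)
  }
})

test_that("odds ratio contrasts use the coefficient covariance", {
  ds <- scenario1_dataset()
  fit <- fit_casebase(ds, ~ x)
  or <- estimate_or(fit, c(x = 2))
  expect_equal(or$transformed, 2 * fit$logistic$beta_hat[["x"]])
  expect_equal(or$se, 2 * sqrt(fit$logistic$vcov["x", "x"]))
  null <- estimate_or(fit, c(x = 0))
  expect_equal(null$point, 1)
  expect_equal(null$se, 0)
  expect_error(estimate_or(fit, c(bogus = 1)), "unknown")
})

test_that("confidence intervals back-transform a symmetric Wald interval", {
  ds <- scenario1_dataset()
  fit <- fit_casebase(ds, ~ x)
  rr <- estimate_rr(fit, data.frame(x = 1), data.frame(x = 0), level = 0.9)
  z <- qnorm(0.95)
  expect_equal(rr$ci_low, exp(rr$transformed - z * rr$se))
  expect_equal(rr$ci_high, exp(rr$transformed + z * rr$se))
  expect_true(rr$ci_low <= rr$point && rr$point <= rr$ci_high)
})
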