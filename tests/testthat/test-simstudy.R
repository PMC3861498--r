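# A small, fast scenario used for unit-level checks of the study runner:
# same structure as the single-binary-exposure study, scaled down.
small_scenario <- function() {
  scenario_config(
    name = "small", covariates = list(cb_binary("x", 0.3)),
    beta = c(x = 0.9163), prevalence = 0.1,
    population_size = 20000L, gamma = 0.1, tau = 0.02,
    quantities = list(
      q_or("logOR", c(x = 1)),
      q_rr("logRR", data.frame(x = 1), data.frame(x = 0),
           dup_contrast = c(x = 1)),
      q_risk("logit(risk_0)", data.frame(x = 0))),
    replicates = 60L)
}

test_that("built-in scenarios carry the published designs and truths", {
  sc <- builtin_scenarios()
  expect_setequal(names(sc),
                  c("table1", "table2", "table2_saturated", "table3",
                    "continuous", "interaction", "confounder",
                    "low_prev_005", "low_prev_001"))
  t1 <- sc$table1
  expect_equal(t1$design$gamma, 0.05)
  expect_equal(t1$design$tau, 0.005)
  expect_equal(t1$design$population_size, 100000L)
  expect_equal(t1$prevalence, 0.1)
  # scenario truths propagate to the tracked quantities
  labs <- vapply(t1$quantities, `[[`, "", "label")
  truths <- vapply(t1$quantities, `[[`, 0, "truth")
  expect_equal(unname(truths[labs == "logOR"]), log(2.5))
  expect_equal(unname(truths[labs == "logRR"]), 0.8128, tolerance = 1e-4)
  expect_equal(unname(truths[labs == "logit(risk_0)"]), -2.5465,
               tolerance = 1e-4)
  # the saturated variant shares the population truth with table2
  tr2 <- vapply(sc$table2$quantities, `[[`, 0, "truth")
  tr2s <- vapply(sc$table2_saturated$quantities, `[[`, 0, "truth")
  l2 <- vapply(sc$table2$quantities, `[[`, "", "label")
  l2s <- vapply(sc$table2_saturated$quantities, `[[`, "", "label")
  expect_equal(tr2[match(l2s, l2)], tr2s, ignore_attr = TRUE)
  # reconstructed configurations are labelled as such
  expect_match(sc$continuous$note, "reconstruction")
  expect_match(sc$confounder$note, "reconstruction")
})

test_that("run_scenario is deterministic in the master seed", {
  cfg <- small_scenario()
  r1 <- run_scenario(cfg, replicates = 25, seed = 7)
  r2 <- run_scenario(cfg, replicates = 25, seed = 7)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  r3 <- run_scenario(cfg, replicates = 25, seed = 8)
  expect_false(isTRUE(all.equal(r1$mean, r3$mean)))
})

test_that("study reports are well-formed and account for every replicate", {
  cfg <- small_scenario()
  rep <- run_scenario(cfg, replicates = 60, seed = 9,
                      methods = c("present", "sato", "miettinen",
                                  "duplication"))
  expect_s3_class(rep, "cb_study_report")
  expect_true(all(rep$coverage >= 0 & rep$coverage <= 1))
  expect_true(all(rep$var100 >= 0))
  expect_true(all(rep$n_used + rep$n_dropped == rep$n_total))
  # comparator methods report only relative risks
  expect_setequal(rep$quantity[rep$method == "sato"], "logRR")
  expect_setequal(rep$quantity[rep$method == "miettinen"], "logRR")
  # Monte-Carlo standard errors are attached to every cell
  expect_true(all(is.finite(rep$mc_se_mean)))
  expect_true(all(is.finite(rep$mc_se_coverage)))
})

test_that("study estimates recover the scenario truth", {
  cfg <- small_scenario()
  rep <- run_scenario(cfg, replicates = 150, seed = 10)
  pres <- rep[rep$method == "present", ]
  expect_true(all(abs(pres$bias) <= 4 * pres$mc_se_mean + 0.02))
  expect_true(all(pres$coverage > 0.89 & pres$coverage < 0.99))
})

test_that("a single replicate yields estimates but no variance", {
  cfg <- small_scenario()
  rep <- run_scenario(cfg, replicates = 1, seed = 11)
  expect_true(all(rep$n_total == 1))
  expect_true(all(is.na(rep$var100)))
  expect_true(all(is.finite(rep$mean)))
})

test_that("plan() reproduces the binomial design oracles", {
  # base sample of 500 at prevalence 0.1: 450 non-diseased, E[n1] = 50
  p <- casebase_plan(900, 0.1, frac_diseased = 0.5)
  expect_equal(p$expected_n1, 50)
  expect_equal(p$ci_ratio, exp(2 * qnorm(0.975) * sqrt(1 / 50 + 1 / 450)))
  # common disease, 200 distinct subjects (100/100): expected n1 above 5
  p2 <- casebase_plan(200, 0.05)
  expect_gt(p2$expected_n1, 5)
  # precision improves to a degenerate interval as n1 grows
  big <- casebase_plan(1e8, 0.1)
  # n1 = 5e6, n0 = 4.5e7: ci_ratio = exp(2z * 4.7e-4) ~ 1.0018
  expect_equal(big$ci_ratio, 1, tolerance = 5e-3)
  expect_warning(p3 <- casebase_plan(20, 0.01), "n1")
  expect_true(p3$low_n1)
})
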