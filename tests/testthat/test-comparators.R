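test_that("sato_rr is the exact specialization of the regression estimator", {
  set.seed(83)
  for (i in 1:50) {
    tb <- random_binary_table()
    ds <- casebase_table_dataset(tb$a1, tb$a0, tb$b1 + tb$d1, tb$b0 + tb$d0,
                                 tb$d1, tb$d0)
    tab <- binary_table_from_profiles(ds, data.frame(x = 1), data.frame(x = 0))
    s <- sato_rr(tab)
    rr <- estimate_rr(fit_casebase(ds, ~ x), data.frame(x = 1),
                      data.frame(x = 0))
    expect_lt(abs(s$transformed - rr$transformed), 1e-13)
    expect_lt(abs(s$se^2 - rr$se^2), 1e-13)
  }
})

test_that("sato_rr point matches the closed-form oracle and null tables", {
  tab <- binary_table(20, 10, 150 + 4, 350 + 6, 4, 6)
  s <- sato_rr(tab)
  o <- saturated_oracle(20, 10, 150, 350, 10, 30)
  expect_equal(s$transformed, o$log_rr, tolerance = 1e-12)
  # equal exposure odds among diseased and non-diseased base: RR = 1
  null_tab <- binary_table(30, 60, 100 + 5, 200 + 10, 5, 10)
  expect_equal(sato_rr(null_tab)$point, 1, tolerance = 1e-12)
})

test_that("miettinen_rr point is the crude ratio, invariant to overlap", {
  tab <- binary_table(20, 10, 150, 350, 2, 3)
  mi <- miettinen_rr(tab)
  expect_equal(mi$point, (20 / 10) / (150 / 350), tolerance = 1e-12)
  expect_equal(mi$point, 4.6667, tolerance = 1e-4)
  tab2 <- binary_table(20, 10, 150, 350, 0, 0)
  expect_equal(miettinen_rr(tab2)$point, mi$point)
  # equal exposure distribution: RR = 1
  null_tab <- binary_table(30, 60, 100, 200, 5, 10)
  expect_equal(miettinen_rr(null_tab)$point, 1)
  # variance variants: overlap correction can only shrink the variance
  expect_lte(miettinen_rr(tab)$se, miettinen_rr(tab, variance = "independent")$se)
  expect_equal(miettinen_rr(tab2)$se,
               miettinen_rr(tab2, variance = "independent")$se)
})

test_that("zero cells are errors, not continuity-corrected", {
  expect_error(miettinen_rr(binary_table(0, 10, 150, 350, 0, 3)), "zero cell")
  expect_error(sato_rr(binary_table(5, 10, 0, 350, 0, 3)))
  expect_error(sato_rr(binary_table(5, 10, 150, 350, 0, 0)), "n1 = 0")
})

test_that("duplication expands exactly the diseased base-sample rows", {
  tb <- list(a1 = 25, a0 = 30, b1 = 80, b0 = 150, d1 = 3, d0 = 4)
  ds <- casebase_table_dataset(tb$a1, tb$a0, tb$b1 + tb$d1, tb$b0 + tb$d0,
                               tb$d1, tb$d0)
  # expanded dataset has k = n1 extra rows, relabeled non-diseased: the fitted
  # coefficient equals the log odds ratio of the manually expanded data
  dup <- duplication_rr(ds, ~ x)
  manual <- rbind(as.data.frame(ds),
                  transform(as.data.frame(ds)[ds$disease == 1L &
                                              ds$in_base_sample == 1L, ],
                            disease = 0L))
  expect_equal(nrow(manual), nrow(ds) + tb$d1 + tb$d0)
  ref <- glm(disease ~ x, family = binomial(), data = manual,
             control = glm.control(epsilon = 1e-12))
  expect_equal(dup$transformed, unname(coef(ref)["x"]), tolerance = 1e-9)

  # the single-binary duplication point estimate is Miettinen's crude ratio
  tab <- binary_table_from_profiles(ds, data.frame(x = 1), data.frame(x = 0))
  expect_equal(dup$transformed, miettinen_rr(tab)$transformed,
               tolerance = 1e-9)
})

test_that("duplication requires diseased base-sample members", {
  ds <- casebase_table_dataset(6, 4, 9, 21, 0, 0)
  expect_error(duplication_rr(ds, ~ x), "n1 = 0")
})

test_that("profile-based tables restrict to the two compared profiles", {
  m3 <- scenario3_model()
  pop <- simulate_population(m3, 20000, seed = 91)
  ds <- draw_case_base_sample(pop, sampling_design(20000, 0.2, 0.05),
                              seed = 92)
  tab <- binary_table_from_profiles(ds, data.frame(x1 = 1, x2 = 0),
                                    data.frame(x1 = 0, x2 = 0))
  manual_e <- ds$x1 == 1 & ds$x2 == 0
  manual_u <- ds$x1 == 0 & ds$x2 == 0
  expect_equal(tab$diseased_exposed, sum(ds$disease == 1 & manual_e))
  expect_equal(tab$base_unexposed, sum(ds$in_base_sample == 1 & manual_u))
})
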