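# Shared fixtures and independent oracles for the test suite.

# Scenario truth models, built in code.
scenario1_model <- function() {
  solve_baseline_odds(list(cb_binary("x", 0.3)), ~ x, c(x = log(2.5)), 0.1)
}

scenario3_model <- function() {
  solve_baseline_odds(list(cb_binary("x1", 0.3), cb_binary("x2", 0.4)),
                      ~ x1 + x2, c(x1 = log(2.5), x2 = log(3)), 0.1)
}

# One simulated scenario-1 case-base dataset under the published design.
scenario1_dataset <- function(seed = 20131212) {
  m <- scenario1_model()
  des <- sampling_design(100000L, 0.05, 0.005)
  pop <- simulate_population(m, 100000L, seed = seed)
  draw_case_base_sample(pop, des, seed = seed + 1L)
}

# Saturated single-binary-exposure MLE oracle: closed-form group odds.
saturated_oracle <- function(a1, a0, b1, b0, n1, n_D) {
  rho <- n1 / n_D
  odds1 <- rho * a1 / b1
  odds0 <- rho * a0 / b0
  p1 <- odds1 / (1 + odds1)
  p0 <- odds0 / (1 + odds0)
  list(alpha_star = log(a0 / b0), beta = log((a1 / b1) / (a0 / b0)),
       p1 = p1, p0 = p0, log_rr = log(p1 / p0))
}

# Random valid binary case-base tables with all positive cells.
random_binary_table <- function() {
  repeat {
    a1 <- rpois(1L, 40) + 2L; a0 <- rpois(1L, 40) + 2L
    d1 <- rbinom(1L, a1, 0.25); d0 <- rbinom(1L, a0, 0.25)
    b1 <- rpois(1L, 120) + 5L; b0 <- rpois(1L, 200) + 5L
    if (d1 + d0 >= 1L)
      return(list(a1 = a1, a0 = a0, b1 = b1, b0 = b0, d1 = d1, d0 = d0))
  }
}

# Monte-Carlo study reports are expensive; compute them once per session.
.study_cache <- new.env(parent = emptyenv())

cached_study <- function(key, expr) {
  if (!exists(key, .study_cache)) assign(key, force(expr), .study_cache)
  get(key, .study_cache)
}

table1_study <- function() {
  cached_study("table1", run_scenario(
    "table1", replicates = 2000L, seed = 101L,
    methods = c("present", "sato", "miettinen", "duplication")))
}

table2_study <- function() {
  cached_study("table2", run_scenario("table2", replicates = 2000L,
                                      seed = 202L))
}

table3_study <- function() {
  cached_study("table3", run_scenario("table3", replicates = 2000L,
                                      seed = 303L))
}

report_cell <- function(report, quantity, method, col) {
  i <- report$quantity == quantity & report$method == method
  stopifnot(sum(i) == 1L)
  report[[col]][i]
}
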