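#' Quantities tracked in a Monte-Carlo study
#'
#' Constructors describing the quantities a [run_scenario()] report tracks:
#' log odds ratios (a contrast over fitted coefficients), logit absolute risks
#' (an exposure profile) and log relative risks (a pair of profiles).
#'
#' @param label Row label used in the report.
#' @param contrast Named numeric contrast over non-intercept coefficients of
#'   the fitted model.
#' @param profile,x1,x0 Single-row data frames (or named lists) of covariate
#'   values.
#' @param dup_contrast Optional contrast expressing this log RR in the
#'   case-duplication model's coefficients; required for the `"duplication"`
#'   method to report the quantity.
#' @return A `cb_quantity` object.
#' @name cb_quantity
NULL

#' @rdname cb_quantity
#' @export
q_or <- function(label, contrast) {
  structure(list(label = label, type = "logOR", contrast = contrast),
            class = "cb_quantity")
}

#' @rdname cb_quantity
#' @export
q_risk <- function(label, profile) {
  structure(list(label = label, type = "logit_risk",
                 profile = as.data.frame(profile)),
            class = "cb_quantity")
}

#' @rdname cb_quantity
#' @export
q_rr <- function(label, x1, x0, dup_contrast = NULL) {
  structure(list(label = label, type = "logRR", x1 = as.data.frame(x1),
                 x0 = as.data.frame(x0), dup_contrast = dup_contrast),
            class = "cb_quantity")
}

#' Monte-Carlo scenario configuration
#'
#' Bundles a synthetic-population truth (covariate distributions, log odds
#' ratios, target marginal prevalence), a case-base sampling design, a fitted
#' model formula and the quantities and methods to track. The baseline odds is
#' solved at construction so that the marginal prevalence matches
#' `prevalence`, and true values for every quantity are derived from the
#' resulting model.
#'
#' @param name Scenario name.
#' @param covariates List of [covariate_spec] objects.
#' @param beta Named vector of true log odds ratios (columns of
#'   `truth_formula`).
#' @param prevalence Target marginal disease prevalence.
#' @param truth_formula One-sided formula for the population model; defaults
#'   to all covariates, additively.
#' @param fit_formula Formula fitted to each simulated dataset; defaults to
#'   `truth_formula`.
#' @param population_size,gamma,tau Sampling design (see [sampling_design()]).
#' @param quantities List of [cb_quantity] objects.
#' @param replicates Default number of Monte-Carlo replicates.
#' @param methods Methods evaluated by default: subset of `"present"`,
#'   `"sato"`, `"miettinen"`, `"duplication"`.
#' @param note Free-text provenance note (e.g. marking a configuration as a
#'   reconstruction).
#' @return A `cb_scenario` object; component `truth` holds the solved
#'   `cb_population` model and each quantity carries its true value.
#' @export
scenario_config <- function(name, covariates, beta, prevalence,
                            truth_formula = NULL, fit_formula = NULL,
                            population_size = 100000L, gamma = 0.05,
                            tau = 0.005, quantities, replicates = 10000L,
                            methods = c("present", "sato", "miettinen"),
                            note = NULL) {
  if (is.null(truth_formula))
    truth_formula <- stats::reformulate(covariate_names(covariates))
  if (is.null(fit_formula)) fit_formula <- truth_formula
  stopifnot(replicates >= 1L,
            all(vapply(quantities, inherits, TRUE, "cb_quantity")))
  model <- solve_baseline_odds(covariates, truth_formula, beta, prevalence)
  quantities <- lapply(quantities, function(q) {
    q$truth <- switch(q$type,
      logOR = {
        miss <- setdiff(names(q$contrast), names(model$beta))
        if (length(miss)) NA_real_
        else sum(q$contrast * model$beta[names(q$contrast)])
      },
      logit_risk = stats::qlogis(logistic_risk(model, q$profile)),
      logRR = log(logistic_risk(model, q$x1) / logistic_risk(model, q$x0)))
    q
  })
  structure(list(name = name, covariates = covariates, beta = beta,
                 prevalence = prevalence, truth_formula = truth_formula,
                 fit_formula = fit_formula,
                 design = sampling_design(population_size, gamma, tau),
                 quantities = quantities, replicates = replicates,
                 methods = methods, note = note, truth = model),
            class = "cb_scenario")
}

method_applies <- function(method, q) {
  switch(method,
         present = TRUE,
         sato = q$type == "logRR",
         miettinen = q$type == "logRR",
         duplication = q$type == "logRR" && !is.null(q$dup_contrast),
         FALSE)
}

replicate_estimates <- function(config, methods, level, pop_seed, smp_seed) {
  design <- config$design
  pop <- simulate_population(config$truth, design$population_size,
                             seed = pop_seed)
  ds <- suppressWarnings(draw_case_base_sample(pop, design, seed = smp_seed))
  qs <- config$quantities
  nq <- length(qs); nm <- length(methods)
  est <- len <- matrix(NA_real_, nq, nm, dimnames = list(NULL, methods))
  if (nrow(ds) == 0L) return(list(est = est, len = len))

  fit <- if ("present" %in% methods)
    tryCatch(fit_casebase(ds, config$fit_formula), error = function(e) NULL)
  dup_fit <- if ("duplication" %in% methods)
    tryCatch(duplication_rr(ds, config$fit_formula,
                            contrasts = stats::setNames(
                              lapply(qs, function(q) q$dup_contrast),
                              vapply(qs, `[[`, "", "label"))[
                                !vapply(qs, function(q)
                                  is.null(q$dup_contrast), TRUE)],
                            level = level),
             error = function(e) NULL)

  for (qi in seq_along(qs)) {
    q <- qs[[qi]]
    for (mi in seq_along(methods)) {
      m <- methods[mi]
      if (!method_applies(m, q)) next
      eff <- tryCatch(switch(m,
        present = {
          if (is.null(fit)) NULL
          else switch(q$type,
            logOR = estimate_or(fit, q$contrast, level = level),
            logit_risk = estimate_risk(fit, q$profile, level = level),
            logRR = estimate_rr(fit, q$x1, q$x0, level = level))
        },
        sato = sato_rr(binary_table_from_profiles(ds, q$x1, q$x0),
                       level = level),
        miettinen = miettinen_rr(binary_table_from_profiles(ds, q$x1, q$x0),
                                 level = level),
        duplication = {
          if (is.null(dup_fit)) NULL
          else dup_fit[dup_fit$label == q$label, , drop = FALSE]
        }), error = function(e) NULL)
      if (!is.null(eff) && nrow(eff) == 1L && is.finite(eff$transformed)) {
        est[qi, mi] <- eff$transformed
        len[qi, mi] <- 2 * z95(level) * eff$se
      }
    }
  }
  list(est = est, len = len)
}

#' Run a Monte-Carlo case-base simulation study
#'
#' For each replicate: simulate a population from the scenario truth, draw a
#' case-base sample, apply each method and record the estimate and its Wald
#' confidence interval. The report aggregates, per quantity and method, the
#' mean estimate (log or logit scale), the sample variance of the estimates
#' (times 100), the coverage probability of the confidence intervals against
#' the analytic truth, and the average interval length, together with
#' Monte-Carlo standard errors. Replicates for which a quantity is not
#' estimable (e.g. `n1 = 0`, zero comparator cells, separation) are dropped
#' from that cell and counted in `n_dropped`.
#'
#' @param config A [scenario_config()] (or a name from
#'   [builtin_scenarios()]).
#' @param replicates Number of replicates; defaults to the scenario's.
#' @param seed Master seed; per-replicate seeds are derived from it, so
#'   results do not depend on execution order.
#' @param methods Methods to evaluate; defaults to the scenario's.
#' @param level Confidence level.
#' @return A data frame of class `cb_study_report` with columns `scenario`,
#'   `quantity`, `method`, `truth`, `mean`, `bias`, `var100`, `coverage`,
#'   `ci_length`, `mc_se_mean`, `mc_se_var100`, `mc_se_coverage`, `n_used`,
#'   `n_dropped`, `n_total`.
#' @export
run_scenario <- function(config, replicates = NULL, seed = 1L,
                         methods = NULL, level = 0.95) {
  if (is.character(config)) config <- builtin_scenarios()[[config]]
  stopifnot(inherits(config, "cb_scenario"))
  if (is.null(replicates)) replicates <- config$replicates
  if (is.null(methods)) methods <- config$methods
  qs <- config$quantities
  nq <- length(qs); nm <- length(methods); R <- replicates
  set.seed(seed)
  rep_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * R), ncol = 2L)
  est <- len <- array(NA_real_, c(R, nq, nm))
  for (r in seq_len(R)) {
    one <- replicate_estimates(config, methods, level,
                               pop_seed = rep_seeds[r, 1L],
                               smp_seed = rep_seeds[r, 2L])
    est[r, , ] <- one$est
    len[r, , ] <- one$len
  }
  zq <- z95(level)
  rows <- list()
  for (qi in seq_len(nq)) for (mi in seq_len(nm)) {
    if (!method_applies(methods[mi], qs[[qi]])) next
    e <- est[, qi, mi]; l <- len[, qi, mi]
    ok <- is.finite(e)
    n <- sum(ok)
    truth <- qs[[qi]]$truth
    covered <- abs(e[ok] - truth) <= l[ok] / 2
    v <- if (n >= 2L) stats::var(e[ok]) else NA_real_
    cv <- mean(covered)
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = config$name,
      quantity = qs[[qi]]$label,
      method = methods[mi],
      truth = truth,
      mean = mean(e[ok]),
      bias = mean(e[ok]) - truth,
      var100 = 100 * v,
      coverage = cv,
      ci_length = mean(l[ok]),
      mc_se_mean = if (n >= 2L) stats::sd(e[ok]) / sqrt(n) else NA_real_,
      mc_se_var100 = if (n >= 2L) 100 * v * sqrt(2 / (n - 1)) else NA_real_,
      mc_se_coverage = sqrt(cv * (1 - cv) / n),
      n_used = n, n_dropped = R - n, n_total = R)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "level") <- level
  attr(out, "note") <- config$note
  class(out) <- c("cb_study_report", "data.frame")
  out
}

#' @export
print.cb_study_report <- function(x, digits = 4, ...) {
  cat("Monte-Carlo case-base study:", x$scenario[1L], "\n")
  if (!is.null(attr(x, "note"))) cat("note:", attr(x, "note"), "\n")
  cat(sprintf("replicates: %d, seed: %s\n\n", x$n_total[1L],
              format(attr(x, "seed"))))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Built-in simulation scenarios
#'
#' Named [scenario_config()] objects for the main study conditions (a single
#' binary exposure; a four-level exposure with constant odds ratio per level,
#' plus a saturated-model variant; two independent binary exposures) and
#' supplementary variants (a standard-normal continuous exposure, a two-way
#' interaction, a binary confounder, lower disease prevalences). All use a
#' population of 100,000 subjects, case sampling probability 0.05 and base
#' sampling probability 0.005, and 10,000 replicates by default.
#'
#' Parameter details for the supplementary variants (`continuous`,
#' `interaction`, `confounder`) are not fully specified by the study they
#' emulate; these configurations are reconstructions (see their `note`).
#'
#' @return Named list of `cb_scenario` objects: `table1`, `table2`,
#'   `table2_saturated`, `table3`, `continuous`, `interaction`, `confounder`,
#'   `low_prev_005`, `low_prev_001`.
#' @export
builtin_scenarios <- function() {
  lor <- log(2.5)
  lor2 <- log(3)

  table1 <- scenario_config(
    name = "table1",
    covariates = list(cb_binary("x", 0.3)),
    beta = c(x = lor), prevalence = 0.1,
    quantities = list(
      q_or("logOR", c(x = 1)),
      q_rr("logRR", data.frame(x = 1), data.frame(x = 0),
           dup_contrast = c(x = 1)),
      q_risk("logit(risk_0)", data.frame(x = 0)),
      q_risk("logit(risk_1)", data.frame(x = 1))))

  lvl <- function(j) data.frame(x = j)
  table2 <- scenario_config(
    name = "table2",
    covariates = list(cb_categorical("x", c(0.5, 0.3, 0.1, 0.1))),
    beta = c(x = lor), prevalence = 0.1,
    quantities = c(
      list(q_or("logOR adjacent", c(x = 1))),
      lapply(1:3, function(j)
        q_rr(paste0("logRR_", j), lvl(j), lvl(0),
             dup_contrast = c(x = j))),
      lapply(0:3, function(j)
        q_risk(paste0("logit(risk_", j, ")"), lvl(j)))))

  table2_saturated <- scenario_config(
    name = "table2_saturated",
    covariates = list(cb_categorical("x", c(0.5, 0.3, 0.1, 0.1))),
    beta = c(x = lor), prevalence = 0.1,
    truth_formula = ~ x, fit_formula = ~ factor(x),
    quantities = c(
      lapply(1:3, function(j)
        q_rr(paste0("logRR_", j), lvl(j), lvl(0),
             dup_contrast = stats::setNames(1, paste0("factor(x)", j)))),
      lapply(0:3, function(j)
        q_risk(paste0("logit(risk_", j, ")"), lvl(j)))),
    note = "saturated fit: no constant-OR assumption")

  pr2 <- function(a, b) data.frame(x1 = a, x2 = b)
  table3 <- scenario_config(
    name = "table3",
    covariates = list(cb_binary("x1", 0.3), cb_binary("x2", 0.4)),
    beta = c(x1 = lor, x2 = lor2), prevalence = 0.1,
    quantities = list(
      q_or("logOR_1", c(x1 = 1)),
      q_or("logOR_2", c(x2 = 1)),
      q_rr("logRR_10", pr2(1, 0), pr2(0, 0), dup_contrast = c(x1 = 1)),
      q_rr("logRR_01", pr2(0, 1), pr2(0, 0), dup_contrast = c(x2 = 1)),
      q_rr("logRR_11", pr2(1, 1), pr2(0, 0),
           dup_contrast = c(x1 = 1, x2 = 1)),
      q_risk("logit(risk_00)", pr2(0, 0)),
      q_risk("logit(risk_10)", pr2(1, 0)),
      q_risk("logit(risk_01)", pr2(0, 1)),
      q_risk("logit(risk_11)", pr2(1, 1))))

  continuous <- scenario_config(
    name = "continuous",
    covariates = list(cb_normal("x")),
    beta = c(x = lor), prevalence = 0.1,
    quantities = list(
      q_or("logOR per unit", c(x = 1)),
      q_rr("logRR 1 vs 0", data.frame(x = 1), data.frame(x = 0),
           dup_contrast = c(x = 1)),
      q_risk("logit(risk at 0)", data.frame(x = 0)),
      q_risk("logit(risk at 1)", data.frame(x = 1))),
    methods = "present",
    note = "reconstruction: standard-normal exposure, per-unit logOR 0.9163")

  interaction <- scenario_config(
    name = "interaction",
    covariates = list(cb_binary("x1", 0.3), cb_binary("x2", 0.4)),
    beta = c(x1 = lor, x2 = lor2, `x1:x2` = log(2)), prevalence = 0.1,
    truth_formula = ~ x1 * x2, fit_formula = ~ x1 * x2,
    quantities = list(
      q_or("logOR_1", c(x1 = 1)),
      q_or("logOR_2", c(x2 = 1)),
      q_or("logOR interaction", c(`x1:x2` = 1)),
      q_rr("logRR_10", pr2(1, 0), pr2(0, 0), dup_contrast = c(x1 = 1)),
      q_rr("logRR_01", pr2(0, 1), pr2(0, 0), dup_contrast = c(x2 = 1)),
      q_rr("logRR_11", pr2(1, 1), pr2(0, 0),
           dup_contrast = c(x1 = 1, x2 = 1, `x1:x2` = 1)),
      q_risk("logit(risk_00)", pr2(0, 0)),
      q_risk("logit(risk_11)", pr2(1, 1))),
    note = "reconstruction: interaction OR set to 2")

  conf_support <- expand.grid(c = c(0, 1), x = c(0, 1))
  conf_probs <- c(0.6 * 0.8, 0.4 * 0.6, 0.6 * 0.2, 0.4 * 0.4)
  prc <- function(x, c) data.frame(x = x, c = c)
  confounder <- scenario_config(
    name = "confounder",
    covariates = list(cb_discrete("xc", conf_support, conf_probs)),
    beta = c(x = lor, c = lor2), prevalence = 0.1,
    truth_formula = ~ x + c, fit_formula = ~ x + c,
    quantities = list(
      q_or("logOR exposure", c(x = 1)),
      q_or("logOR confounder", c(c = 1)),
      q_rr("logRR exposure | c=0", prc(1, 0), prc(0, 0),
           dup_contrast = c(x = 1)),
      q_risk("logit(risk_00)", prc(0, 0)),
      q_risk("logit(risk_10)", prc(1, 0))),
    note = paste("reconstruction: confounder prevalence 0.4, disease logOR",
                 "1.0986, exposure prevalence 0.2/0.4 by stratum"))

  low_prev <- function(p, nm) scenario_config(
    name = nm,
    covariates = list(cb_binary("x", 0.3)),
    beta = c(x = lor), prevalence = p,
    quantities = list(
      q_or("logOR", c(x = 1)),
      q_rr("logRR", data.frame(x = 1), data.frame(x = 0),
           dup_contrast = c(x = 1)),
      q_risk("logit(risk_0)", data.frame(x = 0)),
      q_risk("logit(risk_1)", data.frame(x = 1))))

  list(table1 = table1, table2 = table2,
       table2_saturated = table2_saturated, table3 = table3,
       continuous = continuous, interaction = interaction,
       confounder = confounder,
       low_prev_005 = low_prev(0.05, "low_prev_005"),
       low_prev_001 = low_prev(0.01, "low_prev_001"))
}

#' Design-precision calculator for the base sample
#'
#' The precision of risk and relative risk estimates is driven by `n1`, the
#' number of diseased subjects recruited in the base sample. For a design
#' targeting `n_distinct` distinct subjects split between diseased and
#' non-diseased, the non-diseased recruits all come from the base sample, so
#' the implied base sample contains about `n0 = n_distinct * (1 -
#' frac_diseased)` non-diseased members and `E[n1] = n0 * prevalence / (1 -
#' prevalence)` diseased ones. The prevalence-odds estimate `n1 / n0` then has
#' `se(log odds) = sqrt(1/E[n1] + 1/n0)`, and the ratio of the upper to the
#' lower 95% confidence bound is `exp(2 z se)`.
#'
#' @param n_distinct Total number of distinct recruited subjects.
#' @param prevalence Disease prevalence in the study population.
#' @param frac_diseased Fraction of distinct subjects that are diseased.
#' @param level Confidence level.
#' @return List with `expected_n1`, `se_log_odds`, `ci_ratio` and logical
#'   `low_n1` (`TRUE`, with a warning, when `expected_n1 < 1`).
#' @export
casebase_plan <- function(n_distinct, prevalence, frac_diseased = 0.5,
                          level = 0.95) {
  stopifnot(n_distinct >= 2, prevalence > 0, prevalence < 1,
            frac_diseased > 0, frac_diseased < 1)
  n0 <- n_distinct * (1 - frac_diseased)
  n1 <- n0 * prevalence / (1 - prevalence)
  se <- sqrt(1 / n1 + 1 / n0)
  low <- n1 < 1
  if (low)
    warning("expected n1 < 1: risks and relative risks will rarely be ",
            "estimable at this design", call. = FALSE)
  list(expected_n1 = n1, se_log_odds = se,
       ci_ratio = exp(2 * z95(level) * se), low_n1 = low)
}
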