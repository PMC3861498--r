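#' Population disease model
#'
#' The disease risk in the study population is assumed to follow a logistic
#' model: for a subject with exposure profile row vector `x`,
#' `logit P(D = 1 | x) = log(q) + x %*% beta`, where `q` is the baseline
#' disease odds (the disease odds at the reference profile, all model columns
#' zero) and `beta` is the vector of log odds ratios.
#'
#' @param covariates List of [covariate_spec] objects describing the joint
#'   covariate distribution.
#' @param formula One-sided formula mapping covariates to model columns
#'   (e.g. `~ x`, `~ x1 + x2`, `~ x1 * x2`). Terms must be evaluable row by
#'   row (no data-dependent bases); categorical scores are treated numerically.
#' @param beta Named numeric vector of log odds ratios; names must match the
#'   non-intercept columns of the model matrix implied by `formula`.
#' @param baseline_odds Positive baseline disease odds `q`.
#' @return An object of class `cb_population`.
#' @seealso [solve_baseline_odds()] to obtain `baseline_odds` from a target
#'   marginal prevalence, [truth_table()], [simulate_population()].
#' @export
population_model <- function(covariates, formula, beta, baseline_odds) {
  stopifnot(inherits(formula, "formula"), length(formula) == 2L,
            is.numeric(baseline_odds), length(baseline_odds) == 1L,
            baseline_odds > 0, all(is.finite(beta)))
  support <- covariate_support(covariates, gh_points = 8L)
  X <- design_matrix(formula, support)
  if (!setequal(colnames(X), names(beta)))
    stop("`beta` names must match model columns: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  structure(list(covariates = covariates, formula = formula,
                 beta = beta[colnames(X)],
                 log_baseline_odds = log(baseline_odds)),
            class = "cb_population")
}

# Non-intercept model matrix for a one-sided formula evaluated on `data`.
design_matrix <- function(formula, data) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  X <- stats::model.matrix(formula, mf)
  X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
}

linear_predictor <- function(model, newdata) {
  X <- design_matrix(model$formula, newdata)
  missing <- setdiff(names(model$beta), colnames(X))
  if (length(missing))
    stop("profile cannot be encoded; missing model columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  drop(model$log_baseline_odds + X[, names(model$beta), drop = FALSE] %*% model$beta)
}

#' Disease risk under the population model
#'
#' @param model A `cb_population` model.
#' @param newdata Data frame of exposure profiles (one row per profile).
#' @return Numeric vector of risks in (0, 1).
#' @export
logistic_risk <- function(model, newdata) {
  stopifnot(inherits(model, "cb_population"))
  stats::plogis(linear_predictor(model, newdata))
}

#' Marginal disease prevalence implied by a population model
#'
#' Probability-weighted mean of the risk over the covariate support
#' (Gauss-Hermite quadrature for normal covariates).
#'
#' @inheritParams logistic_risk
#' @param gh_points Gauss-Hermite nodes per normal covariate.
#' @return Marginal prevalence in (0, 1).
#' @export
marginal_prevalence <- function(model, gh_points = 40L) {
  support <- covariate_support(model$covariates, gh_points = gh_points)
  sum(support$.weight * logistic_risk(model, support))
}

#' Solve the baseline disease odds for a target marginal prevalence
#'
#' The simulation scenarios state the covariate distribution, the odds ratios
#' and the marginal disease prevalence; the baseline odds `q` is implied. This
#' solves `E_x[plogis(log q + x beta)] = target_prevalence` for `log q` by
#' bracketed root finding on `[-40, 10]` (the risk is strictly increasing in
#' the intercept, so the root is unique).
#'
#' @inheritParams population_model
#' @param target_prevalence Marginal disease prevalence in (0, 1).
#' @param tol Absolute solver tolerance on `log q`.
#' @param gh_points Gauss-Hermite nodes per normal covariate.
#' @return A `cb_population` model whose [marginal_prevalence()] equals
#'   `target_prevalence` within tolerance.
#' @examples
#' m <- solve_baseline_odds(list(cb_binary("x", 0.3)), ~ x,
#'                          c(x = log(2.5)), 0.1)
#' logistic_risk(m, data.frame(x = c(0, 1)))  # 0.0727, 0.1638
#' @export
solve_baseline_odds <- function(covariates, formula, beta, target_prevalence,
                                tol = 1e-12, gh_points = 40L) {
  if (!is.numeric(target_prevalence) || target_prevalence <= 0 ||
      target_prevalence >= 1)
    stop("`target_prevalence` must be in (0, 1)", call. = FALSE)
  support <- covariate_support(covariates, gh_points = gh_points)
  X <- design_matrix(formula, support)
  if (!setequal(colnames(X), names(beta)))
    stop("`beta` names must match model columns: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  eta <- drop(X[, names(beta), drop = FALSE] %*% beta)
  f <- function(lq) sum(support$.weight * stats::plogis(lq + eta)) -
    target_prevalence
  lo <- -40; hi <- 10
  if (f(lo) > 0 || f(hi) < 0)
    stop("no root for log baseline odds in [-40, 10]: f(-40) = ", f(lo),
         ", f(10) = ", f(hi), call. = FALSE)
  root <- stats::uniroot(f, c(lo, hi), tol = tol)$root
  population_model(covariates, formula, beta, baseline_odds = exp(root))
}

#' True risks and relative risks for a set of exposure profiles
#'
#' @param model A `cb_population` model.
#' @param profiles Data frame of exposure profiles; must include the reference
#'   profile.
#' @param reference Row index of the reference profile in `profiles`.
#' @return Data frame with one row per profile: `risk`, `logit_risk`, `rr`
#'   (risk relative to the reference profile) and `log_rr`; the marginal
#'   prevalence is attached as attribute `"marginal_prevalence"`.
#' @export
truth_table <- function(model, profiles, reference = 1L) {
  stopifnot(inherits(model, "cb_population"), is.data.frame(profiles),
            reference >= 1L, reference <= nrow(profiles))
  risk <- logistic_risk(model, profiles)
  out <- cbind(profiles,
               data.frame(risk = risk,
                          logit_risk = stats::qlogis(risk),
                          rr = risk / risk[reference],
                          log_rr = log(risk / risk[reference])))
  attr(out, "marginal_prevalence") <- marginal_prevalence(model)
  class(out) <- c("cb_truth_table", "data.frame")
  out
}

#' @export
print.cb_population <- function(x, ...) {
  cat("Population logistic disease model\n")
  cat("  logit P(D=1|x) =", format(x$log_baseline_odds, digits = 6), "+ x'beta\n")
  cat("  baseline odds q =", format(exp(x$log_baseline_odds), digits = 6), "\n")
  cat("  log odds ratios:\n")
  print(x$beta)
  invisible(x)
}
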