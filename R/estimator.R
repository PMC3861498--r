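#' Fit the sample logistic model to case-base data
#'
#' Among recruited subjects, disease status follows a logistic model with the
#' same log odds ratios as the population model but a shifted intercept
#' `alpha* = log(q) - log(rho)`, where `rho` is the probability that a
#' diseased recruit is in the base sample. The model is fitted by maximum
#' likelihood (iteratively reweighted least squares) with disease as the 0/1
#' response, regardless of recruitment route; the covariance matrix is the
#' inverse observed information.
#'
#' @param dataset A `cb_dataset` (or data frame with a 0/1 `disease` column).
#' @param formula One-sided model formula over the covariate columns, e.g.
#'   `~ x`, `~ x1 + x2`, `~ x1 * x2`, `~ factor(x)`.
#' @param epsilon,maxit IRLS convergence tolerance (relative deviance change)
#'   and iteration cap. After IRLS, Newton steps polish the solution until the
#'   score step is below machine precision, so closed-form special cases are
#'   matched exactly.
#' @return An object of class `cb_logistic`: list with `alpha_star`,
#'   `beta_hat` (named), `coefficients` (intercept first), `vcov`,
#'   `converged`, `iterations`, `n`, and the terms/levels metadata needed to
#'   encode new profiles.
#' @export
fit_sample_logistic <- function(dataset, formula, epsilon = 1e-12,
                                maxit = 100L) {
  stopifnot(is.data.frame(dataset), "disease" %in% names(dataset))
  y <- dataset$disease
  if (!all(y %in% c(0L, 1L))) stop("`disease` must be 0/1", call. = FALSE)
  if (all(y == 1L) || all(y == 0L))
    stop("dataset must contain both diseased and non-diseased subjects",
         call. = FALSE)
  mt <- stats::terms(formula)
  mf <- stats::model.frame(mt, data = dataset, na.action = stats::na.fail)
  X <- stats::model.matrix(mt, mf)
  if ("(Intercept)" %in% colnames(X) == FALSE)
    X <- cbind(`(Intercept)` = 1, X)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = epsilon,
                                                maxit = maxit)))
  p <- fit$rank
  if (p < ncol(X)) {
    aliased <- colnames(X)[fit$qr$pivot[-seq_len(p)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  big <- abs(fit$coefficients) > 30
  if (any(big))
    stop("complete or quasi-complete separation suspected for column(s): ",
         paste(names(fit$coefficients)[big], collapse = ", "), call. = FALSE)
  coefs <- fit$coefficients[colnames(X)]
  # Newton polish to machine precision; V = inverse observed information
  info <- NULL
  for (it in seq_len(5L)) {
    mu <- stats::plogis(drop(X %*% coefs))
    info <- crossprod(X, X * (mu * (1 - mu)))
    step <- solve(info, crossprod(X, y - mu))
    coefs <- coefs + drop(step)
    if (max(abs(step)) < 1e-12) break
  }
  mu <- stats::plogis(drop(X %*% coefs))
  info <- crossprod(X, X * (mu * (1 - mu)))
  V <- chol2inv(chol(info))
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(list(alpha_star = unname(coefs["(Intercept)"]),
                 beta_hat = coefs[setdiff(names(coefs), "(Intercept)")],
                 coefficients = coefs,
                 vcov = V,
                 converged = fit$converged,
                 iterations = fit$iter,
                 n = nrow(X),
                 terms = stats::delete.response(mt),
                 xlevels = stats::.getXlevels(mt, mf)),
            class = "cb_logistic")
}

#' Estimate rho and gamma from recruitment counts
#'
#' The likelihood of the recruited subjects factorizes into three terms whose
#' parameter sets are orthogonal; two are binomial, giving maximum likelihood
#' estimates `rho_hat = n1 / n_D` (probability that a diseased recruit is in
#' the base sample) and `gamma_hat = n11 / n1` (case sampling probability).
#' `var(log rho_hat)` is obtained from the binomial variance by the delta
#' method and is the extra variance component carried by risk and relative
#' risk estimates.
#'
#' @param counts A `cb_counts` object from [tabulate_counts()], or a list with
#'   `n_D`, `n1`, `n11`.
#' @return An object of class `cb_rho`: list with `rho_hat`, `var_rho`,
#'   `var_log_rho`, `gamma_hat`, `var_gamma` and logical `estimable`. When
#'   `n1 = 0`, `rho_hat` is not estimable (risks and relative risks are then
#'   unavailable, odds ratios remain valid); when `n11 = 0`, `gamma_hat` is
#'   unavailable, which has no bearing on risk estimation.
#' @export
estimate_rho_gamma <- function(counts) {
  n_D <- counts$n_D; n1 <- counts$n1; n11 <- counts$n11
  stopifnot(n_D >= 1L, n1 >= 0L, n11 >= 0L, n11 <= n1, n1 <= n_D)
  if (n1 == 0L) {
    return(structure(list(rho_hat = NA_real_, var_rho = NA_real_,
                          var_log_rho = NA_real_, gamma_hat = NA_real_,
                          var_gamma = NA_real_, estimable = FALSE,
                          n_D = n_D, n1 = n1, n11 = n11),
                     class = "cb_rho"))
  }
  rho <- n1 / n_D
  gamma_hat <- if (n11 > 0L) n11 / n1 else NA_real_
  var_gamma <- if (n11 > 0L) gamma_hat * (1 - gamma_hat) / n1 else NA_real_
  structure(list(rho_hat = rho,
                 var_rho = rho * (1 - rho) / n_D,
                 var_log_rho = (1 - rho) / (n_D * rho),
                 gamma_hat = gamma_hat,
                 var_gamma = var_gamma,
                 estimable = TRUE,
                 n_D = n_D, n1 = n1, n11 = n11),
            class = "cb_rho")
}

#' Fit the case-base risk model
#'
#' Fits the sample logistic model ([fit_sample_logistic()]), estimates `rho`
#' from the recruitment counts ([estimate_rho_gamma()]) and corrects the
#' intercept: `alpha_hat = alpha* + log(rho_hat)` estimates the log baseline
#' disease odds of the population model. The three parameter blocks (`gamma`;
#' `rho`; `alpha*`, `beta`) are orthogonal, so their variances combine
#' additively in downstream delta-method calculations.
#'
#' @inheritParams fit_sample_logistic
#' @param formula One-sided model formula; defaults to all covariate columns,
#'   additively.
#' @return An object of class `cb_fit`: list with components `logistic`
#'   (the `cb_logistic` fit), `rho` (the `cb_rho` estimate), `alpha_hat`,
#'   `counts` and `formula`.
#' @examples
#' ds <- casebase_table_dataset(diseased_exposed = 6, diseased_unexposed = 4,
#'                              base_exposed = 9, base_unexposed = 21,
#'                              diseased_in_base_exposed = 1,
#'                              diseased_in_base_unexposed = 1)
#' fit <- fit_casebase(ds, ~ x)
#' estimate_risk(fit, data.frame(x = 0))
#' @export
fit_casebase <- function(dataset, formula = NULL) {
  if (is.null(formula))
    formula <- stats::reformulate(casebase_covariates(dataset))
  validate_casebase(dataset)
  logistic <- fit_sample_logistic(dataset, formula)
  counts <- tabulate_counts(dataset)
  rho <- estimate_rho_gamma(counts)
  alpha_hat <- if (rho$estimable) logistic$alpha_star + log(rho$rho_hat)
               else NA_real_
  structure(list(logistic = logistic, rho = rho, alpha_hat = alpha_hat,
                 counts = counts, formula = formula),
            class = "cb_fit")
}

# Encode profiles with the fitted model's terms and factor levels; returns the
# full design matrix including the intercept column.
encode_profiles <- function(fit, newdata) {
  mt <- fit$logistic$terms
  mf <- stats::model.frame(mt, data = newdata, na.action = stats::na.fail,
                           xlev = fit$logistic$xlevels)
  X <- stats::model.matrix(mt, mf)
  want <- names(fit$logistic$coefficients)
  miss <- setdiff(want, colnames(X))
  if (length(miss))
    stop("profile cannot be encoded; missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  X[, want, drop = FALSE]
}

z95 <- function(level) stats::qnorm(1 - (1 - level) / 2)

new_effect <- function(kind, label, transformed, se, level,
                       transform = exp) {
  z <- z95(level)
  data.frame(kind = kind, label = label,
             point = transform(transformed),
             transformed = transformed,
             se = se,
             ci_low = transform(transformed - z * se),
             ci_high = transform(transformed + z * se),
             level = level,
             row.names = NULL)
}

require_rho <- function(fit) {
  if (!fit$rho$estimable)
    stop("rho is not estimable (no diseased subject in the base sample, ",
         "n1 = 0); risks and relative risks are unavailable, only odds ",
         "ratios can be estimated", call. = FALSE)
}

#' Absolute risk estimates with delta-method confidence intervals
#'
#' The logit of the population risk at profile `x` is estimated by
#' `alpha_hat + x beta_hat`; its variance is `z V z' + var(log rho_hat)` with
#' `z = (1, x)` and `V` the covariance of `(alpha*, beta_hat)`. Wald intervals
#' are formed on the logit scale and back-transformed.
#'
#' @param fit A `cb_fit` from [fit_casebase()].
#' @param newdata Data frame of exposure profiles, one row per estimate.
#' @param level Confidence level.
#' @return A data frame of class `cb_effect` with columns `kind` ("risk"),
#'   `label`, `point` (risk scale), `transformed` (logit), `se` (logit scale),
#'   `ci_low`, `ci_high` (risk scale) and `level`.
#' @export
estimate_risk <- function(fit, newdata, level = 0.95) {
  stopifnot(inherits(fit, "cb_fit"))
  require_rho(fit)
  Z <- encode_profiles(fit, newdata)
  logit <- drop(Z %*% fit$logistic$coefficients) + log(fit$rho$rho_hat)
  v <- rowSums((Z %*% fit$logistic$vcov) * Z) + fit$rho$var_log_rho
  lab <- if (!is.null(rownames(newdata))) rownames(newdata)
         else as.character(seq_len(nrow(newdata)))
  new_effect("risk", lab, logit, sqrt(v), level, transform = stats::plogis)
}

#' Relative risk estimates with delta-method confidence intervals
#'
#' Estimates `RR = risk(x1) / risk(x0)` from a case-base fit. The variance of
#' `log RR` combines the logistic-model covariance with the uncertainty in
#' `log rho_hat`: `var(log RR) = h V h' + c^2 var(log rho_hat)` where, with
#' fitted risks `p1`, `p0`,
#' `h = ((1-p1) - (1-p0), (1-p1) x1 - (1-p0) x0)` is the gradient of `log RR`
#' with respect to `(alpha*, beta)` and `c = (1-p1) - (1-p0)` its derivative
#' with respect to `log rho`.
#'
#' @inheritParams estimate_risk
#' @param newdata1,newdata0 Data frames of comparison and reference profiles;
#'   rows are matched pairwise (single-row inputs are recycled).
#' @return A `cb_effect` data frame with `kind = "RR"`; `transformed` is the
#'   log relative risk.
#' @export
estimate_rr <- function(fit, newdata1, newdata0, level = 0.95) {
  stopifnot(inherits(fit, "cb_fit"))
  require_rho(fit)
  Z1 <- encode_profiles(fit, newdata1)
  Z0 <- encode_profiles(fit, newdata0)
  if (nrow(Z1) == 1L && nrow(Z0) > 1L) Z1 <- Z1[rep(1L, nrow(Z0)), , drop = FALSE]
  if (nrow(Z0) == 1L && nrow(Z1) > 1L) Z0 <- Z0[rep(1L, nrow(Z1)), , drop = FALSE]
  stopifnot(nrow(Z1) == nrow(Z0))
  co <- fit$logistic$coefficients
  lrho <- log(fit$rho$rho_hat)
  lp1 <- drop(Z1 %*% co) + lrho
  lp0 <- drop(Z0 %*% co) + lrho
  p1 <- stats::plogis(lp1); p0 <- stats::plogis(lp0)
  log_rr <- lp1 - lp0 + log1p(-p1) - log1p(-p0)
  # gradient rows: (1 - p1) z1 - (1 - p0) z0 over (alpha*, beta)
  H <- Z1 * (1 - p1) - Z0 * (1 - p0)
  cc <- (1 - p1) - (1 - p0)
  v <- rowSums((H %*% fit$logistic$vcov) * H) + cc^2 * fit$rho$var_log_rho
  v <- pmax(v, 0)
  lab <- paste0(apply(as.data.frame(newdata1), 1L, paste, collapse = ","),
                " vs ",
                apply(as.data.frame(newdata0), 1L, paste, collapse = ","))
  new_effect("RR", lab, log_rr, sqrt(v), level)
}

#' Odds ratio estimates from a case-base fit
#'
#' Odds ratios come directly from the sample logistic model and remain valid
#' even when `rho` is not estimable (`n1 = 0`).
#'
#' @inheritParams estimate_risk
#' @param contrast Either the name of a coefficient, or a named numeric vector
#'   of contrast weights over the non-intercept coefficients.
#' @return A `cb_effect` data frame with `kind = "OR"`; `transformed` is the
#'   log odds ratio.
#' @export
estimate_or <- function(fit, contrast, level = 0.95) {
  stopifnot(inherits(fit, "cb_fit"))
  beta <- fit$logistic$beta_hat
  if (is.character(contrast)) {
    lab <- contrast
    w <- stats::setNames(rep(0, length(beta)), names(beta))
    miss <- setdiff(contrast, names(beta))
    if (length(miss))
      stop("unknown coefficient(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    w[contrast] <- 1
    lab <- paste(contrast, collapse = "+")
  } else {
    miss <- setdiff(names(contrast), names(beta))
    if (length(miss))
      stop("unknown coefficient(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    w <- stats::setNames(rep(0, length(beta)), names(beta))
    w[names(contrast)] <- contrast
    lab <- paste(names(contrast), collapse = "+")
  }
  Vb <- fit$logistic$vcov[names(beta), names(beta), drop = FALSE]
  est <- sum(w * beta)
  v <- drop(t(w) %*% Vb %*% w)
  new_effect("OR", lab, est, sqrt(max(v, 0)), level)
}

#' @export
print.cb_fit <- function(x, digits = 4, ...) {
  cat("Case-base logistic risk model\n\n")
  print(x$counts)
  cat("\nSample model (intercept alpha*):\n")
  co <- x$logistic$coefficients
  se <- sqrt(diag(x$logistic$vcov))
  print(round(cbind(estimate = co, se = se), digits))
  if (x$rho$estimable) {
    cat(sprintf("\nrho_hat = %.*f (var(log rho_hat) = %.*g)\n", digits,
                x$rho$rho_hat, digits, x$rho$var_log_rho))
    cat(sprintf("corrected intercept alpha_hat = %.*f\n", digits, x$alpha_hat))
    if (!is.na(x$rho$gamma_hat))
      cat(sprintf("gamma_hat = %.*f\n", digits, x$rho$gamma_hat))
  } else {
    cat("\nrho is not estimable (n1 = 0): only odds ratios are available\n")
  }
  invisible(x)
}
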