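#' Binary-exposure case-base table
#'
#' Sufficient counts for the single-binary-exposure closed-form estimators:
#' distinct diseased recruits by exposure, base-sample members by exposure
#' (any disease status) and the diseased-in-base overlap counts.
#'
#' @param diseased_exposed,diseased_unexposed Distinct diseased recruits by
#'   exposure status.
#' @param base_exposed,base_unexposed Base-sample members by exposure status,
#'   regardless of disease.
#' @param diseased_in_base_exposed,diseased_in_base_unexposed Diseased
#'   base-sample members by exposure status.
#' @return An object of class `cb_binary_table`.
#' @export
binary_table <- function(diseased_exposed, diseased_unexposed,
                         base_exposed, base_unexposed,
                         diseased_in_base_exposed,
                         diseased_in_base_unexposed) {
  x <- list(diseased_exposed = diseased_exposed,
            diseased_unexposed = diseased_unexposed,
            base_exposed = base_exposed,
            base_unexposed = base_unexposed,
            diseased_in_base_exposed = diseased_in_base_exposed,
            diseased_in_base_unexposed = diseased_in_base_unexposed)
  if (any(unlist(x) < 0) || any(unlist(x) != round(unlist(x))))
    stop("all counts must be nonnegative integers", call. = FALSE)
  if (diseased_in_base_exposed > min(diseased_exposed, base_exposed) ||
      diseased_in_base_unexposed > min(diseased_unexposed, base_unexposed))
    stop("overlap counts cannot exceed diseased or base counts", call. = FALSE)
  structure(x, class = "cb_binary_table")
}

#' Collapse a case-base dataset to a binary-exposure table
#'
#' Rows whose covariate profile matches `x1` are treated as exposed, rows
#' matching `x0` as unexposed; all other rows are dropped. With a single
#' binary covariate and `x1 = 1`, `x0 = 0` this is the usual 2x2-plus-overlap
#' reduction.
#'
#' @param dataset A `cb_dataset`.
#' @param x1,x0 Single-row data frames (or named lists) giving the exposed and
#'   reference covariate profiles.
#' @return A [binary_table()].
#' @export
binary_table_from_profiles <- function(dataset, x1, x0) {
  validate_casebase(dataset)
  covs <- names(as.data.frame(x1))
  stopifnot(setequal(covs, names(as.data.frame(x0))))
  match_profile <- function(profile) {
    m <- rep(TRUE, nrow(dataset))
    for (v in covs) m <- m & dataset[[v]] == as.data.frame(profile)[[v]][1L]
    m
  }
  e <- match_profile(x1)
  u <- match_profile(x0)
  d <- dataset$disease == 1L
  b <- dataset$in_base_sample == 1L
  binary_table(diseased_exposed = sum(d & e),
               diseased_unexposed = sum(d & u),
               base_exposed = sum(b & e),
               base_unexposed = sum(b & u),
               diseased_in_base_exposed = sum(d & b & e),
               diseased_in_base_unexposed = sum(d & b & u))
}

#' Expand a binary table into a unit-record case-base dataset
#'
#' Utility mainly used for testing and small worked examples: reconstructs a
#' `cb_dataset` (with a 0/1 covariate `x`) whose [tabulate_counts()] and
#' [binary_table_from_profiles()] reproduce the given counts. Case-sample
#' membership is assigned to diseased subjects outside the base sample and to
#' the first overlap subjects within it.
#'
#' @inheritParams binary_table
#' @return A `cb_dataset`.
#' @export
casebase_table_dataset <- function(diseased_exposed, diseased_unexposed,
                                   base_exposed, base_unexposed,
                                   diseased_in_base_exposed,
                                   diseased_in_base_unexposed) {
  tab <- binary_table(diseased_exposed, diseased_unexposed, base_exposed,
                      base_unexposed, diseased_in_base_exposed,
                      diseased_in_base_unexposed)
  one_arm <- function(x, a, m, d1b) {
    # a diseased total, m base total, d1b diseased in base
    non_dis_base <- m - d1b
    dis_case_only <- a - d1b
    data.frame(x = x,
               disease = c(rep(1L, a), rep(0L, non_dis_base)),
               in_case_sample = c(rep(1L, dis_case_only), rep(0L, d1b),
                                  rep(0L, non_dis_base)),
               in_base_sample = c(rep(0L, dis_case_only), rep(1L, d1b),
                                  rep(1L, non_dis_base)))
  }
  out <- rbind(one_arm(1, tab$diseased_exposed, tab$base_exposed,
                       tab$diseased_in_base_exposed),
               one_arm(0, tab$diseased_unexposed, tab$base_unexposed,
                       tab$diseased_in_base_unexposed))
  out <- cbind(data.frame(subject_id = seq_len(nrow(out))), out)
  new_cb_dataset(out, "x")
}

check_positive_cells <- function(tab, cells) {
  zero <- cells[unlist(tab[cells]) == 0]
  if (length(zero))
    stop("zero cell(s): ", paste(zero, collapse = ", "),
         " (no continuity correction is applied)", call. = FALSE)
}

#' Sato's relative risk estimator for a single binary exposure
#'
#' Closed-form maximum likelihood estimator of the relative risk in a
#' case-base study with one binary exposure. It is the algebraic
#' specialization of the general regression estimator ([estimate_rr()]) to a
#' saturated one-covariate model: with `a_j` diseased recruits, `b_j`
#' non-diseased base members and fitted risks
#' `p_j = rho_hat a_j / (b_j + rho_hat a_j)` in exposure group `j`,
#' `log RR = log(p_1 / p_0)` and
#' `var(log RR) = (1-p_1)^2 (1/a_1 + 1/b_1) + (1-p_0)^2 (1/a_0 + 1/b_0) +
#'   ((1-p_1) - (1-p_0))^2 (1 - rho_hat) / (n_D rho_hat)`.
#' The two routes agree to machine precision.
#'
#' @param table A [binary_table()].
#' @param level Confidence level.
#' @return A `cb_effect` data frame with `kind = "RR"`.
#' @export
sato_rr <- function(table, level = 0.95) {
  stopifnot(inherits(table, "cb_binary_table"))
  a1 <- table$diseased_exposed; a0 <- table$diseased_unexposed
  b1 <- table$base_exposed - table$diseased_in_base_exposed
  b0 <- table$base_unexposed - table$diseased_in_base_unexposed
  n1 <- table$diseased_in_base_exposed + table$diseased_in_base_unexposed
  n_D <- a1 + a0
  if (n1 == 0L)
    stop("no diseased subject in the base sample (n1 = 0): RR not estimable",
         call. = FALSE)
  if (a1 == 0L || a0 == 0L || b1 == 0L || b0 == 0L)
    stop("zero cell(s) in the saturated logistic fit ",
         "(diseased or non-diseased base count is zero in one exposure group)",
         call. = FALSE)
  rho <- n1 / n_D
  odds1 <- rho * a1 / b1
  odds0 <- rho * a0 / b0
  p1 <- odds1 / (1 + odds1)
  p0 <- odds0 / (1 + odds0)
  log_rr <- log(p1 / p0)
  var_log_rho <- (1 - rho) / (n_D * rho)
  v <- (1 - p1)^2 * (1 / a1 + 1 / b1) + (1 - p0)^2 * (1 / a0 + 1 / b0) +
    ((1 - p1) - (1 - p0))^2 * var_log_rho
  out <- new_effect("RR", "exposed vs unexposed (Sato)", log_rr, sqrt(v), level)
  out
}

#' Miettinen's crude relative risk estimator (reconstruction)
#'
#' The crude case-base ratio `RR = (a_1 / a_0) / (m_1 / m_0)` of the diseased
#' exposure odds to the base-sample exposure odds, with `m_j` the base-sample
#' counts including diseased members. The original variance algebra is not
#' reproduced here; this implementation is a documented reconstruction. The
#' default `"overlap"` variance subtracts the covariance induced by the
#' diseased subjects shared between the numerator and denominator counts:
#' `var(log RR) = 1/a_1 + 1/a_0 + 1/m_1 + 1/m_0 -
#'   2 (d_1 / (a_1 m_1) + d_0 / (a_0 m_0))`,
#' with `d_j` the diseased-in-base counts. `"independent"` keeps only the four
#' reciprocal terms (treats the two ratios as independent binomials).
#'
#' @inheritParams sato_rr
#' @param variance `"overlap"` (default) or `"independent"`.
#' @return A `cb_effect` data frame with `kind = "RR"`. The point estimate
#'   does not use the overlap counts.
#' @export
miettinen_rr <- function(table, level = 0.95,
                         variance = c("overlap", "independent")) {
  stopifnot(inherits(table, "cb_binary_table"))
  variance <- match.arg(variance)
  check_positive_cells(table, c("diseased_exposed", "diseased_unexposed",
                                "base_exposed", "base_unexposed"))
  a1 <- table$diseased_exposed; a0 <- table$diseased_unexposed
  m1 <- table$base_exposed; m0 <- table$base_unexposed
  d1 <- table$diseased_in_base_exposed; d0 <- table$diseased_in_base_unexposed
  log_rr <- log((a1 / a0) / (m1 / m0))
  v <- 1 / a1 + 1 / a0 + 1 / m1 + 1 / m0
  if (variance == "overlap")
    v <- v - 2 * (d1 / (a1 * m1) + d0 / (a0 * m0))
  new_effect("RR", "exposed vs unexposed (Miettinen)", log_rr,
             sqrt(max(v, 0)), level)
}

#' Case-duplication relative risk estimator
#'
#' Regression route to relative risks by data expansion: each diseased subject
#' recruited in the base sample is duplicated and the duplicate re-labeled
#' non-diseased; a logistic model fitted to the expanded data then estimates
#' log relative risks by its coefficients. On a census dataset (`rho = 1`,
#' every subject in the base sample) this reduces to the cohort duplication
#' method.
#'
#' @inheritParams fit_sample_logistic
#' @param contrasts Optional named list of contrast vectors (as in
#'   [estimate_or()]) defining the log RR estimates to report; defaults to one
#'   per model coefficient.
#' @param level Confidence level.
#' @return A `cb_effect` data frame with `kind = "RR"`, one row per contrast.
#' @export
duplication_rr <- function(dataset, formula, contrasts = NULL, level = 0.95) {
  validate_casebase(dataset)
  dup <- dataset$disease == 1L & dataset$in_base_sample == 1L
  if (!any(dup))
    stop("no diseased subject in the base sample (n1 = 0): ",
         "the duplication method is unavailable", call. = FALSE)
  extra <- dataset[dup, , drop = FALSE]
  extra$disease <- 0L
  expanded <- rbind(as.data.frame(dataset), as.data.frame(extra))
  fit <- fit_sample_logistic(expanded, formula)
  beta <- fit$beta_hat
  Vb <- fit$vcov[names(beta), names(beta), drop = FALSE]
  if (is.null(contrasts))
    contrasts <- stats::setNames(lapply(names(beta), function(nm)
      stats::setNames(1, nm)), names(beta))
  rows <- lapply(names(contrasts), function(lab) {
    w <- stats::setNames(rep(0, length(beta)), names(beta))
    w[names(contrasts[[lab]])] <- contrasts[[lab]]
    est <- sum(w * beta)
    v <- drop(t(w) %*% Vb %*% w)
    new_effect("RR", lab, est, sqrt(max(v, 0)), level)
  })
  do.call(rbind, rows)
}
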