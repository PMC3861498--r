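#' Case-base sampling design
#'
#' In a case-base study, cases are sampled with probability `gamma` from the
#' incident diseased subjects, and the base (control) sample is a simple
#' random sample of the whole population with probability `tau`, regardless
#' of disease status. The two sampling schemes are independent. A subject is
#' recruited if selected by either scheme (or both); recruited subjects are
#' counted once ("distinct subjects").
#'
#' @param population_size Number of subjects in the study population.
#' @param gamma Case sampling probability among diseased subjects, in `[0, 1]`.
#' @param tau Base sampling probability for all subjects, in `[0, 1]`.
#' @return An object of class `cb_design`.
#' @export
sampling_design <- function(population_size, gamma, tau) {
  stopifnot(population_size >= 1, gamma >= 0, gamma <= 1, tau >= 0, tau <= 1)
  if (gamma == 0 && tau == 0)
    stop("`gamma` and `tau` cannot both be zero", call. = FALSE)
  structure(list(population_size = as.integer(population_size),
                 gamma = gamma, tau = tau),
            class = "cb_design")
}

#' The probability that a diseased recruit is in the base sample
#'
#' `rho = tau / (gamma + tau - gamma * tau)` is the conditional probability
#' that a recruited diseased subject belongs to the base sample. It links the
#' sample-model intercept to the population intercept and is estimated from
#' the data as `n1 / n_D`.
#'
#' @param gamma,tau Sampling probabilities (see [sampling_design()]).
#' @return `rho` in `(0, 1]`.
#' @export
sampling_rho <- function(gamma, tau) {
  stopifnot(gamma >= 0, gamma <= 1, tau >= 0, tau <= 1, gamma + tau > 0)
  tau / (gamma + tau - gamma * tau)
}

# Two independent sub-streams derived from one master seed, so each sampling
# stage is reproducible in isolation.
stage_seeds <- function(seed, k) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

#' Simulate a study population
#'
#' Draws `n` subjects i.i.d. from the covariate specifications of the model
#' and assigns disease status as Bernoulli draws of [logistic_risk()]. The
#' master seed is split into separate streams for the covariate draws and the
#' disease draws.
#'
#' @param model A `cb_population` model.
#' @param n Population size.
#' @param seed Integer master seed.
#' @return Data frame with the covariate columns and a 0/1 `disease` column.
#' @export
simulate_population <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "cb_population"), n >= 1)
  if (!is.null(seed)) {
    ss <- stage_seeds(seed, 2L)
    set.seed(ss[1L])
  }
  pop <- draw_covariates(model$covariates, n)
  risk <- logistic_risk(model, pop)
  if (!is.null(seed)) set.seed(ss[2L])
  pop$disease <- as.integer(stats::runif(n) < risk)
  pop
}

new_cb_dataset <- function(df, covariates) {
  attr(df, "covariates") <- covariates
  class(df) <- c("cb_dataset", "data.frame")
  df
}

#' Covariate column names of a case-base dataset
#' @param dataset A `cb_dataset`.
#' @return Character vector of covariate column names.
#' @export
casebase_covariates <- function(dataset) {
  cv <- attr(dataset, "covariates")
  if (is.null(cv))
    cv <- setdiff(names(dataset),
                  c("subject_id", "disease", "in_case_sample", "in_base_sample"))
  cv
}

#' Draw a case-base sample from a simulated population
#'
#' Applies independent Bernoulli case sampling (probability `gamma`, diseased
#' subjects only) and base sampling (probability `tau`, all subjects) and
#' returns the distinct recruited subjects. A subject selected by both schemes
#' contributes one row carrying both flags.
#'
#' @param population Data frame from [simulate_population()] (covariates plus
#'   0/1 `disease`).
#' @param design A [sampling_design()]; its `population_size` is ignored in
#'   favour of `nrow(population)`.
#' @param seed Integer master seed, split into case- and base-sampling streams.
#' @return A `cb_dataset`: data frame with columns `subject_id`, the
#'   covariates, `disease`, `in_case_sample`, `in_base_sample`. An empty
#'   sample is returned as a zero-row dataset with attribute `empty = TRUE`.
#' @export
draw_case_base_sample <- function(population, design, seed = NULL) {
  stopifnot(is.data.frame(population), nrow(population) >= 1L,
            inherits(design, "cb_design"))
  n <- nrow(population)
  if (!is.null(seed)) {
    ss <- stage_seeds(seed, 2L)
    set.seed(ss[1L])
  }
  s_case <- as.integer(stats::runif(n) < design$gamma & population$disease == 1L)
  if (!is.null(seed)) set.seed(ss[2L])
  s_base <- as.integer(stats::runif(n) < design$tau)
  keep <- s_case + s_base >= 1L
  covs <- setdiff(names(population), "disease")
  out <- cbind(data.frame(subject_id = which(keep)),
               population[keep, covs, drop = FALSE],
               data.frame(disease = population$disease[keep],
                          in_case_sample = s_case[keep],
                          in_base_sample = s_base[keep]))
  rownames(out) <- NULL
  out <- new_cb_dataset(out, covs)
  if (nrow(out) == 0L) {
    attr(out, "empty") <- TRUE
    warning("no subjects were recruited (empty case-base sample)",
            call. = FALSE)
  }
  out
}

#' Recruitment counts of a case-base dataset
#'
#' Tabulates the counts entering the binomial likelihood factors: `n_D`, the
#' distinct diseased recruits; `n1`, the diseased recruits in the base sample;
#' and `n11`, the diseased recruits selected by both schemes. Also returns the
#' disease-by-membership cross-tabulation.
#'
#' @param dataset A `cb_dataset`.
#' @return An object of class `cb_counts`: list with `n`, `n_D`, `n1`, `n11`,
#'   `n_base`, `n_case` and `crosstab`.
#' @export
tabulate_counts <- function(dataset) {
  validate_casebase(dataset)
  d <- dataset$disease == 1L
  b <- dataset$in_base_sample == 1L
  k <- dataset$in_case_sample == 1L
  out <- list(n = nrow(dataset),
              n_D = sum(d),
              n1 = sum(d & b),
              n11 = sum(d & b & k),
              n_base = sum(b),
              n_case = sum(k),
              crosstab = table(disease = dataset$disease,
                               in_base_sample = dataset$in_base_sample,
                               in_case_sample = dataset$in_case_sample))
  stopifnot(out$n11 <= out$n1, out$n1 <= out$n_D)
  structure(out, class = "cb_counts")
}

validate_casebase <- function(dataset) {
  need <- c("disease", "in_case_sample", "in_base_sample")
  miss <- setdiff(need, names(dataset))
  if (length(miss))
    stop("dataset is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in need) {
    v <- dataset[[col]]
    if (!all(v %in% c(0L, 1L)))
      stop("column `", col, "` must be 0/1", call. = FALSE)
  }
  bad <- which(dataset$in_case_sample == 1L & dataset$disease == 0L)
  if (length(bad))
    stop("in_case_sample = 1 requires disease = 1; offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  un <- dataset$in_case_sample + dataset$in_base_sample
  if (any(un < 1L))
    stop("every row must be in the case sample, the base sample or both",
         call. = FALSE)
  if ("subject_id" %in% names(dataset) && anyDuplicated(dataset$subject_id))
    stop("`subject_id` must be unique (distinct subjects)", call. = FALSE)
  invisible(dataset)
}

#' @export
print.cb_counts <- function(x, ...) {
  cat("Case-base recruitment counts\n")
  cat(sprintf("  recruited subjects:        %d\n", x$n))
  cat(sprintf("  distinct diseased (n_D):   %d\n", x$n_D))
  cat(sprintf("  diseased in base (n1):     %d\n", x$n1))
  cat(sprintf("  diseased in both (n11):    %d\n", x$n11))
  cat(sprintf("  base sample size:          %d\n", x$n_base))
  cat(sprintf("  case sample size:          %d\n", x$n_case))
  invisible(x)
}
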