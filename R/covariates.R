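#' Covariate specifications
#'
#' A covariate specification describes the marginal (or joint, for
#' [cb_discrete()]) distribution of one exposure or confounder in the study
#' population. Specifications are used to enumerate the covariate support when
#' solving for the baseline disease odds and to draw i.i.d. covariate values
#' when simulating a population.
#'
#' * `cb_binary()`: a 0/1 exposure with `P(X = 1) = prevalence`.
#' * `cb_categorical()`: an ordinal exposure coded as integer scores
#'   `0, 1, ..., k - 1` with level probabilities `probs`. Level 0 is the
#'   reference. A model formula may use the score directly (`~ x`, constant
#'   odds ratio per level) or saturate it (`~ factor(x)`).
#' * `cb_normal()`: a continuous exposure, normally distributed.
#' * `cb_discrete()`: a joint discrete distribution over several named
#'   columns, for dependent covariates (e.g. an exposure whose prevalence
#'   differs by confounder stratum).
#'
#' @param name Column name of the covariate.
#' @param prevalence Probability that the binary covariate equals 1; in (0,1).
#' @param probs Vector of level probabilities (levels `0:(k-1)`); must sum to 1.
#' @param mean,sd Parameters of the normal distribution.
#' @param values Data frame of joint support points, one column per covariate.
#'
#' @return An object of class `cb_covariate` (and a subclass identifying the
#'   family), suitable for [solve_baseline_odds()] and [simulate_population()].
#' @examples
#' cb_binary("x", 0.3)
#' cb_categorical("x", c(0.5, 0.3, 0.1, 0.1))
#' @name covariate_spec
NULL

new_covariate <- function(type, name, ...) {
  structure(list(name = name, ...),
            class = c(paste0("cb_cov_", type), "cb_covariate"))
}

#' @rdname covariate_spec
#' @export
cb_binary <- function(name, prevalence) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      prevalence <= 0 || prevalence >= 1)
    stop("`prevalence` must be a single number in (0, 1)", call. = FALSE)
  new_covariate("binary", name, prevalence = prevalence)
}

#' @rdname covariate_spec
#' @export
cb_categorical <- function(name, probs) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(probs) || length(probs) < 2L || any(probs <= 0) ||
      any(probs >= 1))
    stop("`probs` must be two or more probabilities in (0, 1)", call. = FALSE)
  if (abs(sum(probs) - 1) > 1e-8)
    stop("`probs` must sum to 1", call. = FALSE)
  new_covariate("categorical", name, probs = probs / sum(probs))
}

#' @rdname covariate_spec
#' @export
cb_normal <- function(name, mean = 0, sd = 1) {
  stopifnot(is.character(name), length(name) == 1L,
            is.finite(mean), is.finite(sd), sd > 0)
  new_covariate("normal", name, mean = mean, sd = sd)
}

#' @rdname covariate_spec
#' @param probs For `cb_discrete()`, one probability per row of `values`.
#' @export
cb_discrete <- function(name, values, probs) {
  stopifnot(is.data.frame(values), nrow(values) >= 1L)
  if (length(probs) != nrow(values))
    stop("`probs` must have one entry per row of `values`", call. = FALSE)
  if (any(probs <= 0) || abs(sum(probs) - 1) > 1e-8)
    stop("`probs` must be positive and sum to 1", call. = FALSE)
  new_covariate("discrete", name, values = values, probs = probs / sum(probs))
}

covariate_names <- function(covariates) {
  unlist(lapply(covariates, function(cv) {
    if (inherits(cv, "cb_cov_discrete")) names(cv$values) else cv$name
  }), use.names = FALSE)
}

#' Support points and weights of one covariate
#'
#' @param spec A `cb_covariate` specification.
#' @param gh_points Number of Gauss-Hermite nodes used for normal covariates.
#' @return A data frame with the covariate column(s) and a `.weight` column.
#' @keywords internal
cov_support <- function(spec, gh_points = 40L) {
  UseMethod("cov_support")
}

#' @export
cov_support.cb_cov_binary <- function(spec, gh_points = 40L) {
  out <- data.frame(value = c(0, 1),
                    .weight = c(1 - spec$prevalence, spec$prevalence))
  names(out)[1L] <- spec$name
  out
}

#' @export
cov_support.cb_cov_categorical <- function(spec, gh_points = 40L) {
  out <- data.frame(value = seq_along(spec$probs) - 1, .weight = spec$probs)
  names(out)[1L] <- spec$name
  out
}

#' @export
cov_support.cb_cov_normal <- function(spec, gh_points = 40L) {
  gh <- pracma::gaussHermite(gh_points)
  out <- data.frame(value = spec$mean + sqrt(2) * spec$sd * gh$x,
                    .weight = gh$w / sqrt(pi))
  names(out)[1L] <- spec$name
  out
}

#' @export
cov_support.cb_cov_discrete <- function(spec, gh_points = 40L) {
  out <- spec$values
  out$.weight <- spec$probs
  out
}

cov_draw <- function(spec, n) UseMethod("cov_draw")

#' @export
cov_draw.cb_cov_binary <- function(spec, n) {
  out <- data.frame(value = as.numeric(stats::runif(n) < spec$prevalence))
  names(out) <- spec$name
  out
}

#' @export
cov_draw.cb_cov_categorical <- function(spec, n) {
  k <- length(spec$probs)
  out <- data.frame(value = sample.int(k, n, replace = TRUE,
                                       prob = spec$probs) - 1)
  names(out) <- spec$name
  out
}

#' @export
cov_draw.cb_cov_normal <- function(spec, n) {
  out <- data.frame(value = stats::rnorm(n, spec$mean, spec$sd))
  names(out) <- spec$name
  out
}

#' @export
cov_draw.cb_cov_discrete <- function(spec, n) {
  idx <- sample.int(nrow(spec$values), n, replace = TRUE, prob = spec$probs)
  spec$values[idx, , drop = FALSE]
}

#' Joint support grid of a covariate list
#'
#' Enumerates the joint support of independent covariate specifications
#' (continuous covariates are represented by Gauss-Hermite nodes) with product
#' weights in column `.weight`.
#'
#' @param covariates List of `cb_covariate` specifications.
#' @param gh_points Gauss-Hermite nodes per normal covariate.
#' @return Data frame of support points with a `.weight` column summing to 1.
#' @export
covariate_support <- function(covariates, gh_points = 40L) {
  stopifnot(length(covariates) >= 1L,
            all(vapply(covariates, inherits, TRUE, "cb_covariate")))
  parts <- lapply(covariates, cov_support, gh_points = gh_points)
  grid <- parts[[1L]]
  for (p in parts[-1L]) {
    w <- outer(grid$.weight, p$.weight)
    i <- rep(seq_len(nrow(grid)), times = nrow(p))
    j <- rep(seq_len(nrow(p)), each = nrow(grid))
    grid <- cbind(grid[i, setdiff(names(grid), ".weight"), drop = FALSE],
                  p[j, setdiff(names(p), ".weight"), drop = FALSE])
    grid$.weight <- as.vector(w)
    rownames(grid) <- NULL
  }
  grid
}

#' Draw covariate rows from their specifications
#'
#' @param covariates List of `cb_covariate` specifications.
#' @param n Number of rows to draw.
#' @return Data frame with `n` rows, one column per covariate.
#' @export
draw_covariates <- function(covariates, n) {
  stopifnot(n >= 1L)
  parts <- lapply(covariates, cov_draw, n = n)
  out <- do.call(cbind, parts)
  rownames(out) <- NULL
  out
}
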