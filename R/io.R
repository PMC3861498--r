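#' Read a case-base dataset from CSV
#'
#' Expects a comma-separated, UTF-8 file with header
#' `subject_id,<covariate columns>,disease,in_case_sample,in_base_sample`;
#' `disease` and the two membership flags must be 0/1 integers and a row in
#' the case sample must be diseased. Violations are reported with row numbers.
#'
#' @param path Path to the CSV file.
#' @return A `cb_dataset`.
#' @export
read_casebase <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty dataset: ", path, call. = FALSE)
  need <- c("subject_id", "disease", "in_case_sample", "in_base_sample")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  covs <- setdiff(names(df), need)
  ds <- new_cb_dataset(df[c("subject_id", covs, "disease", "in_case_sample",
                            "in_base_sample")], covs)
  validate_casebase(ds)
  ds
}

#' Write a case-base dataset to CSV
#'
#' @param dataset A `cb_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_casebase <- function(dataset, path) {
  validate_casebase(dataset)
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a scenario configuration from YAML
#'
#' Schema (keys at top level): `name`; `covariates`, a list of maps with
#' `name` and `type` (`binary`: `prevalence`; `categorical`: `probs`;
#' `normal`: `mean`, `sd`); `beta`, a map of log odds ratios keyed by model
#' column (set `or: true` to give them as odds ratios instead); `prevalence`;
#' optional `formula` (string, default all covariates additive);
#' `population_size`, `gamma`, `tau`, `replicates`; optional `profiles`, a
#' list of covariate maps whose first entry is the reference profile.
#' Quantities are derived automatically: one log OR per coefficient, one
#' logit risk per profile and one log RR per non-reference profile.
#'
#' @param path Path to the YAML file.
#' @return A [scenario_config()].
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("name", "covariates", "beta", "prevalence")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("scenario config is missing key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  covs <- lapply(cfg$covariates, function(cv) {
    if (is.null(cv$name) || is.null(cv$type))
      stop("each covariate needs `name` and `type`", call. = FALSE)
    switch(cv$type,
           binary = cb_binary(cv$name, cv$prevalence),
           categorical = cb_categorical(cv$name, unlist(cv$probs)),
           normal = cb_normal(cv$name, cv$mean %||% 0, cv$sd %||% 1),
           stop("unknown covariate type: ", cv$type, call. = FALSE))
  })
  beta <- unlist(cfg$beta)
  if (isTRUE(cfg$or)) beta <- log(beta)
  form <- if (!is.null(cfg$formula)) stats::as.formula(cfg$formula)
          else stats::reformulate(covariate_names(covs))
  profiles <- lapply(cfg$profiles, as.data.frame)
  quantities <- lapply(names(beta), function(nm)
    q_or(paste0("logOR_", nm), stats::setNames(1, nm)))
  if (length(profiles)) {
    ref <- profiles[[1L]]
    plab <- vapply(profiles, function(p) paste(unlist(p), collapse = ","), "")
    quantities <- c(quantities,
      lapply(seq_along(profiles), function(i)
        q_risk(paste0("logit(risk_", plab[i], ")"), profiles[[i]])),
      lapply(seq_along(profiles)[-1L], function(i)
        q_rr(paste0("logRR_", plab[i]), profiles[[i]], ref)))
  }
  scenario_config(name = cfg$name, covariates = covs, beta = beta,
                  prevalence = cfg$prevalence, truth_formula = form,
                  fit_formula = form,
                  population_size = cfg$population_size %||% 100000L,
                  gamma = cfg$gamma %||% 0.05, tau = cfg$tau %||% 0.005,
                  quantities = quantities,
                  replicates = cfg$replicates %||% 10000L,
                  note = cfg$note)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a study report or effect table
#'
#' CSV output mirrors the published table layout: one block of rows per
#' summary measure (mean estimate, empirical variance times 100, coverage
#' probability, average CI length), quantities as rows and methods as
#' columns, rounded to 4 decimal places. JSON output keeps full precision,
#' including the Monte-Carlo standard errors and the dropped-replicate
#' tallies.
#'
#' @param report A `cb_study_report` (or any data frame for JSON output).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(as.data.frame(report), path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
    return(invisible(path))
  }
  df <- as.data.frame(report)
  if (nrow(df) == 0L) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  measures <- c(mean = "Mean estimate", var100 = "Variance (x100)",
                coverage = "Coverage probability of CI",
                ci_length = "Average length of CI")
  methods <- unique(df$method)
  quantities <- unique(df$quantity)
  blocks <- lapply(names(measures), function(ms) {
    block <- data.frame(measure = measures[[ms]], quantity = quantities)
    for (m in methods) {
      v <- vapply(quantities, function(q) {
        i <- df$quantity == q & df$method == m
        if (any(i)) df[[ms]][i][1L] else NA_real_
      }, 0)
      block[[m]] <- ifelse(is.na(v), "-", sprintf("%.4f", v))
    }
    block
  })
  utils::write.csv(do.call(rbind, blocks), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Captures everything needed to reproduce a command-line run bit for bit:
#' the command, its arguments, the master seed, the package version and a
#' hash of the configuration file (when one was used).
#'
#' @param command Subcommand name.
#' @param args Named list of parsed arguments.
#' @param seed Master seed.
#' @param config_path Optional path of the configuration file to hash.
#' @return A list of class `cb_manifest`.
#' @export
run_manifest <- function(command, args, seed, config_path = NULL) {
  structure(list(
    command = command,
    args = args,
    seed = seed,
    config_md5 = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NULL,
    package = "cbrisk",
    version = as.character(utils::packageVersion("cbrisk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "cb_manifest")
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
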