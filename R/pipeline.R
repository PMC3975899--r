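#' Build a pipeline run configuration
#'
#' Collects every tunable of the five-stage pipeline (generate, calibrate,
#' match, model, impact) with production defaults. All randomness is governed
#' by the seeds recorded here, so a config fully determines a run.
#'
#' @param spec A [population_spec()]; its `seed` drives the survey draw.
#' @param n_donors Donor records to generate.
#' @param seeds Named list: `donors`, `match`.
#' @param strata Margins for [generate_benchmarks()].
#' @param bounds,tol,max_iter Calibration settings ([calibrate_weights()]).
#' @param priority Matching priority ([impute_economics()]).
#' @param offsets Named list of log offsets per outcome.
#' @param preventable_fraction Sensitivity-scenario fraction.
#' @param gdp_params A [gdp_parameters()].
#' @param counterfactual Optional [counterfactual_spec()]; the default
#'   (`NULL`) derives the employment shares from the calibrated
#'   reference population via [reference_shares()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(spec = default_population_spec(),
                       n_donors = 20000L,
                       seeds = list(donors = spec$seed + 1L,
                                    match = spec$seed + 2L),
                       strata = list("group", c("age_group", "sex")),
                       bounds = c(0.3, 3), tol = 1e-6, max_iter = 50L,
                       priority = match_variables(),
                       offsets = list(income = 0, welfare = 1, tax = 1),
                       preventable_fraction = 0.89,
                       gdp_params = gdp_parameters(),
                       counterfactual = NULL) {
  validate_population_spec(spec)
  stopifnot(n_donors > 0, is.numeric(seeds$donors), is.numeric(seeds$match))
  structure(list(spec = spec, n_donors = as.integer(n_donors), seeds = seeds,
                 strata = strata, bounds = bounds, tol = tol,
                 max_iter = as.integer(max_iter), priority = priority,
                 offsets = offsets,
                 preventable_fraction = preventable_fraction,
                 gdp_params = gdp_params, counterfactual = counterfactual),
            class = "run_config")
}

# Stable md5 of an R object via its deparsed representation.
object_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x, control = "all"), f)
  unname(tools::md5sum(f))
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
}

#' Run the full microsimulation pipeline
#'
#' Executes generate -> calibrate -> match -> model -> impact, writing every
#' stage output as plain CSV/JSON to `out_dir` together with a manifest
#' (config hash, seeds, output checksums). Re-running the same config
#' reproduces identical outputs.
#'
#' Outputs: `survey.csv`, `donors.csv`, `benchmarks.csv`,
#' `calibration.json`, `matched.csv`, `match_report.json`, `table1.csv/json`
#' (weighted descriptives), `table2.csv/json` (adjusted percent differences),
#' `table3.csv/json` (national impact, base and preventable scenarios),
#' `manifest.json`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  survey <- stage("synth", generate_survey(config$spec))
  donors <- stage("synth", generate_donors(config$spec, config$n_donors,
                                           seed = config$seeds$donors))
  benchmarks <- stage("synth", generate_benchmarks(config$spec,
                                                   config$strata))
  utils::write.csv(survey, file.path(out_dir, "survey.csv"),
                   row.names = FALSE)
  utils::write.csv(donors, file.path(out_dir, "donors.csv"),
                   row.names = FALSE)
  utils::write.csv(benchmarks$cells, file.path(out_dir, "benchmarks.csv"),
                   row.names = FALSE)

  cal <- stage("calibrate",
               calibrate_weights(survey, benchmarks, bounds = config$bounds,
                                 tol = config$tol,
                                 max_iter = config$max_iter))
  write_json_file(list(iterations = cal$iterations,
                       converged = cal$converged,
                       max_constraint_violation =
                         cal$max_constraint_violation,
                       truncated_count = cal$truncated_count),
                  file.path(out_dir, "calibration.json"))

  matched <- stage("match",
                   impute_economics(survey, donors,
                                    priority = config$priority,
                                    seed = config$seeds$match))
  data <- matched$data
  data$weight <- cal$weights
  utils::write.csv(data, file.path(out_dir, "matched.csv"),
                   row.names = FALSE)
  write_json_file(list(exact_match_rate = matched$report$exact_match_rate,
                       relaxation_histogram =
                         as.list(matched$report$relaxation_histogram)),
                  file.path(out_dir, "match_report.json"))

  table1 <- stage("model",
                  summarize_by_group(data, groups = analysis_groups()))
  utils::write.csv(table1, file.path(out_dir, "table1.csv"),
                   row.names = FALSE)
  write_json_file(table1, file.path(out_dir, "table1.json"))

  analysis <- data[data$group %in% analysis_groups(), ]
  models <- stage("model", lapply(
    stats::setNames(nm = c("income", "welfare", "tax")),
    function(y) fit_log_model(analysis, outcome = y,
                              offset = config$offsets[[y]])))
  table2 <- do.call(rbind, lapply(models, group_effects))
  rownames(table2) <- NULL
  utils::write.csv(table2, file.path(out_dir, "table2.csv"),
                   row.names = FALSE)
  write_json_file(table2, file.path(out_dir, "table2.json"))

  cf_spec <- if (is.null(config$counterfactual))
    reference_shares(data, data$weight) else config$counterfactual
  nilf <- data[data$group == "NILF-diabetes", ]
  losses <- stage("impact",
                  counterfactual_economics(nilf, models, cf_spec))
  base <- national_losses(losses, nilf$weight, scenario = "base")
  base$gdp_loss <- gdp_loss(base$n_out_of_lf, config$gdp_params)
  prevent <- apply_preventable_fraction(base,
                                        config$preventable_fraction)
  table3 <- rbind(as.data.frame(base), as.data.frame(prevent))
  utils::write.csv(table3, file.path(out_dir, "table3.csv"),
                   row.names = FALSE)
  write_json_file(table3, file.path(out_dir, "table3.json"))

  outputs <- c("survey.csv", "donors.csv", "benchmarks.csv",
               "calibration.json", "matched.csv", "match_report.json",
               "table1.csv", "table1.json", "table2.csv", "table2.json",
               "table3.csv", "table3.json")
  manifest <- list(
    config_md5 = object_md5(config),
    seeds = list(survey = config$spec$seed, donors = config$seeds$donors,
                 match = config$seeds$match),
    package_version = as.character(utils::packageVersion("retiresim")),
    checksums = as.list(tools::md5sum(file.path(out_dir, outputs))))
  names(manifest$checksums) <- outputs
  write_json_file(manifest, file.path(out_dir, "manifest.json"))

  invisible(list(survey = survey, donors = donors, benchmarks = benchmarks,
                 calibration = cal, matched = matched, table1 = table1,
                 models = models, table2 = table2,
                 counterfactual = cf_spec, losses = losses, base = base,
                 preventable = prevent, manifest = manifest))
}
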