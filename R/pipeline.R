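#' Run the exposure-assessment pipeline
#'
#' Chains the assessment stages over one configuration and seed, writing
#' every stage's output plus a JSON run manifest to `out_dir`. Stages run
#' in dependency order regardless of the order given:
#'
#' 1. `"point-estimate"` — [exposure_breakdown()] on the food table ->
#'    `breakdown.csv`;
#' 2. `"synth-cohort"` — [generate_cohort()] -> `cohort.csv`;
#' 3. `"biostats"` — [biomonitoring_stats()] on the cohort ->
#'    `biostats.json` (requires a cohort: either the `synth-cohort` stage
#'    or `cohort_file`);
#' 4. `"simulate"` — [simulate_exposure()] on the total-population model
#'    -> `simulation.json`;
#' 5. `"sensitivity"` — [contribution_to_variance()] on the simulation
#'    draws -> `sensitivity.csv` (requires the `simulate` stage in the
#'    same run, since input draws are kept in memory only).
#'
#' The manifest records the configuration snapshot, MD5 digests of file
#' inputs and outputs, the seed, the stages run and the package version,
#' so a rerun from the same manifest is bit-identical.
#'
#' @param stages Character vector of stage names (see above).
#' @param out_dir Output directory, created if needed.
#' @param config An [exposure_config()] or a path to a YAML/JSON config.
#' @param food_table A `food_table` or a path to one; defaults to the
#'   shipped survey table.
#' @param cohort_file Optional path to an existing cohort CSV for
#'   `biostats`.
#' @param seed Integer seed applied to the stochastic stages.
#' @param n_iterations Monte Carlo iterations; defaults to the config
#'   value.
#' @param quiet Suppress per-stage log lines.
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
#' @examples
#' \donttest{
#' out <- tempfile("cadexpo-run-")
#' run_pipeline(c("point-estimate", "synth-cohort", "biostats"),
#'              out_dir = out, seed = 1)
#' list.files(out)
#' }
run_pipeline <- function(stages = c("point-estimate", "synth-cohort",
                                    "biostats", "simulate", "sensitivity"),
                         out_dir = ".", config = exposure_config(),
                         food_table = NULL, cohort_file = NULL,
                         seed = NULL, n_iterations = NULL, quiet = FALSE) {
  known <- c("point-estimate", "synth-cohort", "biostats", "simulate",
             "sensitivity")
  unknown <- setdiff(stages, known)
  if (length(unknown) > 0L) {
    stop_domain("unknown stage name(s): ", paste(unknown, collapse = ", "))
  }
  stages <- known[known %in% stages]
  if (is.character(config)) {
    config_path <- config
    config <- read_exposure_config(config)
  } else {
    config_path <- NULL
  }
  stopifnot(inherits(config, "exposure_config"))
  if (is.character(food_table)) {
    food_path <- food_table
    food_table <- read_food_table(food_table)
  } else if (is.null(food_table)) {
    food_path <- system.file("extdata", "shanghai_food_cadmium.csv",
                             package = "cadexpo")
    food_table <- shanghai_food_table()
  } else {
    food_path <- NULL
  }
  if (is.null(seed)) seed <- config$seed
  if (is.null(n_iterations)) n_iterations <- config$n_iterations
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) if (!quiet) message("[cadexpo] ", ...)

  digest_of <- function(path) unname(tools::md5sum(path))
  manifest <- list(
    tool = "cadexpo",
    version = as.character(utils::packageVersion("cadexpo")),
    seed = seed,
    n_iterations = n_iterations,
    stages = stages,
    config = config[setdiff(names(config), "seed")],
    inputs = list(),
    outputs = list()
  )
  if (!is.null(config_path)) {
    manifest$inputs$config <- list(path = config_path,
                                   md5 = digest_of(config_path))
  }
  if (!is.null(food_path)) {
    manifest$inputs$food_table <- list(path = food_path,
                                       md5 = digest_of(food_path))
  }

  add_output <- function(stage, path) {
    manifest$outputs[[stage]] <<- list(path = path, md5 = digest_of(path))
  }
  cohort <- NULL
  sim <- NULL

  if ("point-estimate" %in% stages) {
    log_msg("point-estimate: ", nrow(food_table), " foods, PTDI ",
            config$ptdi, " ug/day")
    bd <- exposure_breakdown(food_table, config)
    path <- file.path(out_dir, "breakdown.csv")
    write_exposure_breakdown(bd, path)
    add_output("point-estimate", path)
  }
  if ("synth-cohort" %in% stages) {
    log_msg("synth-cohort: n = 207, seed = ", seed)
    cohort <- generate_cohort(cohort_spec(records = food_table,
                                          config = config), seed = seed)
    path <- file.path(out_dir, "cohort.csv")
    write_cohort_table(cohort, path)
    add_output("synth-cohort", path)
  }
  if ("biostats" %in% stages) {
    if (is.null(cohort)) {
      if (is.null(cohort_file)) {
        stop_domain("stage 'biostats' needs a cohort: run 'synth-cohort' ",
                    "first or supply cohort_file")
      }
      manifest$inputs$cohort <- list(path = cohort_file,
                                     md5 = digest_of(cohort_file))
      cohort <- read_cohort_table(cohort_file)
    }
    log_msg("biostats: ", nrow(cohort), " participants")
    bs <- biomonitoring_stats(cohort, food_table, config)
    path <- file.path(out_dir, "biostats.json")
    write_biomonitoring_stats(bs, path)
    add_output("biostats", path)
  }
  if ("simulate" %in% stages) {
    log_msg("simulate: n = ", n_iterations, ", seed = ", seed)
    model <- build_population_model(food_table, config)
    sim <- simulate_exposure(model, n = n_iterations, seed = seed)
    path <- file.path(out_dir, "simulation.json")
    write_simulation_result(sim, path, ptdi = config$ptdi)
    add_output("simulate", path)
  }
  if ("sensitivity" %in% stages) {
    if (is.null(sim)) {
      stop_domain("stage 'sensitivity' needs the retained input draws of ",
                  "a 'simulate' stage in the same run")
    }
    log_msg("sensitivity: ", length(sim$input_draws), " inputs")
    sens <- contribution_to_variance(sim$input_draws, sim$draws)
    path <- file.path(out_dir, "sensitivity.csv")
    write_sensitivity_result(sens, path)
    add_output("sensitivity", path)
  }
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  log_msg("manifest written to ", manifest_path)
  invisible(manifest)
}
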