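#' Build a pipeline run configuration
#'
#' Drives one end-to-end run: residues in (simulated or from CSV), risk
#' quotients and exceedance report out, then the profit scenario grid and
#' sensitivity analysis, all written to an output directory together with a
#' JSON run summary carrying the configuration hash and headline numbers.
#'
#' @param input_mode `"synthetic"` (simulate residues) or `"csv"` (load them).
#' @param synthetic a [synthetic_config()], required in synthetic mode.
#' @param residues_path path to a residue CSV, required in csv mode.
#' @param toxicity_path path to a toxicity CSV; `NULL` uses the packaged
#'   synthetic placeholder table ([default_toxicity_reference()]).
#' @param thresholds a [rq_thresholds()] object.
#' @param censoring_policy,chronic_policy see [compute_site_rqs()].
#' @param profit_params a [profit_parameters()] object.
#' @param sensitivity_overrides see [sensitivity_analysis()].
#' @param output_dir directory for output tables (created if absent).
#' @return A list of class `beecotox_run_config`.
#' @export
run_config <- function(input_mode = c("synthetic", "csv"),
                       synthetic = synthetic_config(),
                       residues_path = NULL,
                       toxicity_path = NULL,
                       thresholds = rq_thresholds(),
                       censoring_policy = "zero",
                       chronic_policy = "min",
                       profit_params = profit_parameters(),
                       sensitivity_overrides = default_sensitivity_overrides(),
                       output_dir = tempfile("beecotox_run_")) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "csv" && is.null(residues_path)) {
    abort_config("residues_path", "is required when input_mode = 'csv'")
  }
  if (input_mode == "synthetic") {
    synthetic <- validate_synthetic_config(synthetic)
  }
  structure(
    list(input_mode = input_mode, synthetic = synthetic,
         residues_path = residues_path, toxicity_path = toxicity_path,
         thresholds = thresholds, censoring_policy = censoring_policy,
         chronic_policy = chronic_policy, profit_params = profit_params,
         sensitivity_overrides = sensitivity_overrides,
         output_dir = output_dir),
    class = "beecotox_run_config"
  )
}

#' Run the full exposure-to-profit pipeline
#'
#' Simulates (or loads) the residue table, computes per-compound acute and
#' chronic risk quotients and their site/time-point totals, counts threshold
#' exceedances per compound, flags sites whose chronic RQ exceeds the chronic
#' level of concern for scenario evaluation, and evaluates the profit
#' scenario grid and sensitivity analysis. All tables are written as CSV to
#' `config$output_dir`, plus `run_summary.json` with the configuration hash,
#' package version and headline numbers. Fully deterministic for a fixed
#' configuration (including the synthetic seed).
#'
#' @param config a [run_config()] object.
#' @param write_outputs write the CSV/JSON artifacts (default TRUE); the run
#'   report is returned either way.
#' @return Invisibly, a list with elements `residues`, `rq_results`,
#'   `total_acute`, `exceedances`, `flagged_sites`, `skipped_compounds`,
#'   `scenario_grid`, `sensitivity`, and `summary` (the run-summary list).
#' @export
run_pipeline <- function(config, write_outputs = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s",
                           name, conditionMessage(e)),
                   class = "beecotox_pipeline_error", parent = e)
    })
  }

  residues <- stage("residues", {
    if (config$input_mode == "synthetic") {
      generate_residues(config$synthetic)
    } else {
      read_residue_csv(config$residues_path)
    }
  })
  tox <- stage("toxicity", {
    if (is.null(config$toxicity_path)) default_toxicity_reference()
    else read_toxicity_csv(config$toxicity_path)
  })
  rq_results <- stage("risk_quotients", compute_site_rqs(
    residues, tox,
    registry = config$thresholds,
    censoring_policy = config$censoring_policy,
    chronic_policy = config$chronic_policy
  ))
  total_acute <- stage("total_rq", total_rq(
    dplyr::filter(rq_results, .data$kind == "acute"), kind = "acute"))
  exceed <- stage("exceedance_report",
                  exceedance_report(rq_results, config$thresholds))
  flagged <- flag_sites_for_scenarios(rq_results,
                                      config$thresholds$chronic)
  grid <- stage("scenario_grid", scenario_grid(config$profit_params))
  sens <- stage("sensitivity", sensitivity_analysis(
    config$profit_params, config$sensitivity_overrides))

  baseline <- grid$profit_h0[grid$effect == "none"]
  summary <- list(
    config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
    package_version = as.character(utils::packageVersion("beecotox")),
    input_mode = config$input_mode,
    seed = if (config$input_mode == "synthetic") config$synthetic$seed else NULL,
    n_residue_records = nrow(residues),
    n_rq_results = nrow(rq_results),
    skipped_compounds = attr(rq_results, "skipped"),
    n_sites_flagged = length(flagged),
    flagged_sites = flagged,
    headline = list(
      baseline_profit = baseline,
      worst_case_profit = min(grid$profit_h1, na.rm = TRUE),
      max_total_acute_rq = if (nrow(total_acute)) max(total_acute$total_rq) else NULL
    )
  )

  if (write_outputs) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(name) file.path(config$output_dir, name)
    if (config$input_mode == "synthetic") {
      write_residue_csv(residues, out("residues.csv"))
    }
    utils::write.csv(rq_results, out("rq_results.csv"), row.names = FALSE)
    utils::write.csv(total_acute, out("total_rq_acute.csv"), row.names = FALSE)
    utils::write.csv(exceed, out("exceedance_report.csv"), row.names = FALSE)
    utils::write.csv(grid, out("scenario_grid.csv"), row.names = FALSE)
    utils::write.csv(sens, out("sensitivity.csv"), row.names = FALSE)
    jsonlite::write_json(summary, out("run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(residues = residues, rq_results = rq_results,
                 total_acute = total_acute, exceedances = exceed,
                 flagged_sites = flagged,
                 skipped_compounds = attr(rq_results, "skipped"),
                 scenario_grid = grid, sensitivity = sens,
                 summary = summary))
}

#' Read a pipeline configuration from YAML
#'
#' A YAML file mirroring the [run_config()] arguments: top-level keys
#' `input_mode`, `residues_path`, `toxicity_path`, `output_dir`,
#' `censoring_policy`, `chronic_policy`, and optional mappings `synthetic`
#' (keys `n_near_sites`, `n_far_sites`, `time_points`, `years`, `seed`),
#' `thresholds` (`acute_cage`, `acute_field`, `chronic`) and `profit`
#' (any [profit_parameters()] argument). Omitted keys take the package
#' defaults.
#'
#' @param path path to a YAML config file.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("cannot read config: no file at '%s'", path),
                 class = "beecotox_io_error")
  }
  y <- yaml::read_yaml(path)
  syn <- do.call(synthetic_config, y$synthetic %||% list())
  thr <- do.call(rq_thresholds, y$thresholds %||% list())
  prof <- do.call(profit_parameters, y$profit %||% list())
  run_config(
    input_mode = y$input_mode %||% "synthetic",
    synthetic = syn,
    residues_path = y$residues_path,
    toxicity_path = y$toxicity_path,
    thresholds = thr,
    censoring_policy = y$censoring_policy %||% "zero",
    chronic_policy = y$chronic_policy %||% "min",
    profit_params = prof,
    output_dir = y$output_dir %||% tempfile("beecotox_run_")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate input files before a pipeline run
#'
#' Schema-checks a residue CSV and a toxicity CSV without running anything:
#' column and enum conformance, non-negative concentrations, censoring-flag
#' consistency and duplicate (site, year, time point, compound, matrix)
#' records are fatal errors; detected compounds missing from the toxicity
#' table (which the RQ stage would skip) are warnings.
#'
#' @param residues_path,toxicity_path file paths.
#' @return A list with character vectors `errors` and `warnings`, plus
#'   `ok = TRUE/FALSE`.
#' @export
validate_inputs <- function(residues_path, toxicity_path) {
  errors <- character(0)
  warnings <- character(0)
  residues <- tryCatch(read_residue_csv(residues_path), error = function(e) {
    errors <<- c(errors, conditionMessage(e)); NULL
  })
  tox <- tryCatch(read_toxicity_csv(toxicity_path), error = function(e) {
    errors <<- c(errors, conditionMessage(e)); NULL
  })
  if (!is.null(residues)) {
    dup <- residues |>
      dplyr::count(.data$site_id, .data$year, .data$time_point,
                   .data$compound, .data$matrix) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      errors <- c(errors, sprintf(
        "duplicate matrix record(s), e.g. site %s / %s / %s / %s",
        dup$site_id[1], dup$year[1], dup$time_point[1], dup$compound[1]))
    }
  }
  if (!is.null(residues) && !is.null(tox)) {
    detected <- unique(residues$compound[residues$censoring != "below_lod"])
    uncovered <- setdiff(detected, tox$compound)
    if (length(uncovered) > 0) {
      warnings <- c(warnings, sprintf(
        "detected compound(s) absent from toxicity table: %s",
        paste(sort(uncovered), collapse = ", ")))
    }
  }
  list(ok = length(errors) == 0, errors = errors, warnings = warnings)
}
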