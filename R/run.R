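#' Read a run configuration
#'
#' A run configuration is a YAML (or JSON) file tying the pipeline
#' together: input paths, currency rates, annualization and overhead
#' choices, bootstrap settings, prevalence inputs and scenario
#' definitions. See the package vignette for a full example.
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "pmscost_io_error")
  }
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg, dir = dirname(path))
}

as_run_config <- function(cfg, dir = ".") {
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$annualization <- cfg$annualization %||% "eac"
  if (!cfg$annualization %in% c("eac", "straight_line")) {
    abort("annualization must be 'eac' or 'straight_line'",
          class = "pmscost_validation_error")
  }
  cfg$overhead <- cfg$overhead %||% "from_ledger"
  if (!cfg$overhead %in% c("from_ledger", "from_rule")) {
    abort("overhead must be 'from_ledger' or 'from_rule'",
          class = "pmscost_validation_error")
  }
  cfg$overhead_rate <- cfg$overhead_rate %||% 0.10
  cfg$basis <- cfg$basis %||% "financial"
  # resolve relative input paths against the config file's directory
  for (key in c("ledger", "fieldwork_log", "outcomes")) {
    p <- cfg[[key]]
    if (!is.null(p) && !grepl("^(/|~|[A-Za-z]:)", p)) {
      cfg[[key]] <- file.path(dir, p)
    }
  }
  structure(cfg, class = "run_config")
}

config_rates <- function(cfg) {
  rates <- unlist(cfg$currency_rates %||% list(USD = 1))
  currency_rates(rates, period = cfg$currency_rates_period %||% "")
}

config_bootstrap <- function(cfg) {
  b <- cfg$bootstrap
  if (is.null(b)) {
    abort("config has no bootstrap block", class = "pmscost_validation_error")
  }
  bootstrap_config(
    targets = unlist(b$targets),
    per_day_cost = unlist(b$per_day_cost),
    fixed_cost = b$fixed_cost %||% 0,
    iterations = b$iterations %||% 500,
    ci_level = b$ci_level %||% 0.95,
    seed = cfg$seed,
    week_days = b$week_days %||% 5
  )
}

config_prevalence <- function(cfg) {
  p <- cfg$prevalence
  if (is.null(p)) {
    abort("config has no prevalence block", class = "pmscost_validation_error")
  }
  crude_prevalence(p$n_substandard, p$n_tested,
                   adjusted_p = p$adjusted_p %||% NULL)
}

config_scenarios <- function(cfg) {
  purrr::map(cfg$scenarios %||% list(), function(s) {
    scenario(s$name,
             medicine_price_multiplier = s$medicine_price_multiplier %||% 1,
             preparation_cost_multiplier = s$preparation_cost_multiplier %||% 1,
             prevalence_override = s$prevalence_override %||% NULL)
  })
}

load_config_ledger <- function(cfg) {
  ledger <- read_ledger(cfg$ledger)
  ledger <- convert_to_usd(ledger, config_rates(cfg))
  if (cfg$overhead == "from_rule") {
    ledger <- cost_ledger(dplyr::bind_rows(
      ledger, apply_overhead(ledger, rate = cfg$overhead_rate)))
  }
  ledger
}

run_stamp <- function(cfg) {
  list(seed = cfg$seed,
       config_hash = sum(utf8ToInt(paste(
         names(unlist(cfg)), unlist(cfg), collapse = "|"))))
}

#' Run the costing stage of the pipeline
#'
#' Reads the ledger named in the configuration, converts to USD, applies
#' the overhead rule if requested, summarises by component and phase, and
#' writes the summary tables (CSV and JSON, with the seed and a config
#' hash embedded) to the output directory.
#'
#' @param cfg A `run_config` (see [read_run_config()]).
#' @param out_dir Output directory; defaults to `cfg$output_dir` or `"."`.
#' @return The `cost_summary`, invisibly.
#' @export
run_costing <- function(cfg, out_dir = cfg$output_dir %||% ".") {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ledger <- load_config_ledger(cfg)
  summary <- summarize_costs(ledger, basis = cfg$basis)
  write_summary(summary, file.path(out_dir, "cost_summary.csv"), "csv")
  jsonlite::write_json(
    c(run_stamp(cfg), list(summary = summary_as_table(summary))),
    file.path(out_dir, "cost_summary.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(summary)
}

#' Run the unit-cost bootstrap stage
#'
#' Reads the fieldwork log, runs the stratified bootstrap and writes the
#' unit-cost report (JSON with mean, percentile CI, iterations and seed
#' per quantity).
#'
#' @inheritParams run_costing
#' @return The `unit_cost_estimates` tibble, invisibly.
#' @export
run_bootstrap <- function(cfg, out_dir = cfg$output_dir %||% ".") {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- read_fieldwork_log(cfg$fieldwork_log)
  est <- bootstrap_unit_costs(log, config_bootstrap(cfg),
                              config_prevalence(cfg))
  jsonlite::write_json(
    c(run_stamp(cfg), list(estimates = est)),
    file.path(out_dir, "unit_costs.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(est)
}

#' Run the one-way sensitivity stage
#'
#' Runs the scenario list from the configuration against the base ledger
#' and bootstrap settings, reusing the same seed for every scenario, and
#' writes the long-format scenario table as CSV.
#'
#' @inheritParams run_costing
#' @return The scenario table, invisibly.
#' @export
run_scenarios <- function(cfg, out_dir = cfg$output_dir %||% ".") {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ledger <- load_config_ledger(cfg)
  log <- read_fieldwork_log(cfg$fieldwork_log)
  tab <- run_one_way(ledger, log, config_bootstrap(cfg),
                     config_prevalence(cfg), config_scenarios(cfg))
  readr::write_csv(tab, file.path(out_dir, "scenarios.csv"))
  invisible(tab)
}

#' Generate a synthetic input bundle from a run configuration
#'
#' Convenience wrapper around [simulate_inputs()] driven by the
#' `synthetic` block of a run configuration (falling back to the
#' generator defaults), writing ledger, fieldwork log and outcomes into
#' the output directory.
#'
#' @inheritParams run_costing
#' @return Named vector of written paths, invisibly.
#' @export
run_simulate <- function(cfg, out_dir = cfg$output_dir %||% ".") {
  stopifnot(inherits(cfg, "run_config"))
  syn <- cfg$synthetic %||% list()
  args <- list(seed = cfg$seed)
  for (key in c("strata", "n_tested", "true_prevalence", "grand_total")) {
    if (!is.null(syn[[key]])) args[[key]] <- syn[[key]]
  }
  simulate_inputs(do.call(synthetic_config, args), out_dir)
}
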