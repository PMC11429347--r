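#' Reference cost structure of a medicine-quality surveillance exercise
#'
#' The category-by-phase share matrix used as the default template for
#' [simulate_ledger()]. Its category and phase margins reproduce the
#' published cost breakdown of a large Indonesian surveillance exercise
#' (laboratory testing ~70% of a US$690,523 total, analysis and
#' reporting ~72% by phase); the within-cell allocation is a constructed
#' plausible split, since only the margins are published.
#'
#' @return A `cost_categories()` by `study_phases()` matrix of
#'   proportions summing to 1.
#' @export
reference_cost_proportions <- function() {
  m <- reference_cost_matrix()
  m / sum(m)
}

# Category x phase USD cell values whose margins match the published
# component and phase subtotals (grand total 690,523). Cells are a
# constructed allocation; see reference_cost_proportions().
reference_cost_matrix <- function() {
  m <- matrix(0, nrow = length(cost_categories()),
              ncol = length(study_phases()),
              dimnames = list(cost_categories(), study_phases()))
  m["salaries", ] <- c(8000, 8000, 10000, 6503)
  m["equipment", ] <- c(1000, 1000, 975, 0)
  m["consumables", ] <- c(0, 5000, 12747, 0)
  m["travel", ] <- c(0, 5000, 16660, 0)
  m["laboratory", ] <- c(0, 0, 0, 481704)
  m["other_direct", ] <- c(20000, 30000, 32734, 0)
  m["indirect", ] <- c(8296, 5356, 27392, 10156)
  m
}

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the shape of the reference surveillance exercise:
#' three outlet strata with sample targets summing to 1333 (327 online),
#' 1274 samples tested, a true substandard prevalence of 105/1274, and
#' day-to-day variation in collection counts from weather, stock-outs
#' and other field shocks, modelled as zero-inflated negative binomial
#' counts (mean `mu`, dispersion `k`, extra zero-day probability).
#'
#' @param seed Integer seed for all generation.
#' @param strata Named list, one element per stratum, each a list with
#'   `mu` (> 0), `k` (> 0), `zero_day_prob` (in `[0, 1)`) and `target`
#'   (>= 1).
#' @param n_tested Number of samples sent for laboratory testing.
#' @param true_prevalence True probability a tested sample is
#'   substandard.
#' @param grand_total Grand total (USD) of the simulated ledger.
#' @param proportions Category-by-phase proportion matrix for the
#'   simulated ledger (default [reference_cost_proportions()]).
#' @param start_date First fieldwork day.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1,
    strata = list(
      urban = list(mu = 12, k = 5, zero_day_prob = 0.05, target = 600),
      rural = list(mu = 8, k = 5, zero_day_prob = 0.05, target = 406),
      online = list(mu = 6, k = 5, zero_day_prob = 0.05, target = 327)
    ),
    n_tested = 1274,
    true_prevalence = 105 / 1274,
    grand_total = 690523,
    proportions = reference_cost_proportions(),
    start_date = as.Date("2022-02-13")) {
  stopifnot(length(strata) >= 1, !is.null(names(strata)),
            n_tested >= 1, true_prevalence >= 0, true_prevalence <= 1,
            grand_total >= 0)
  for (s in names(strata)) {
    p <- strata[[s]]
    stopifnot(p$mu > 0, p$k > 0, p$zero_day_prob >= 0, p$zero_day_prob < 1,
              p$target >= 1)
  }
  if (abs(sum(proportions) - 1) > 1e-6) {
    abort("ledger proportions must sum to 1",
          class = "pmscost_validation_error")
  }
  structure(list(seed = as.integer(seed), strata = strata,
                 n_tested = as.integer(n_tested),
                 true_prevalence = true_prevalence,
                 grand_total = grand_total, proportions = proportions,
                 start_date = as.Date(start_date)),
            class = "synthetic_config")
}

# Zero-inflated negative binomial daily counts.
rzinb <- function(n, mu, k, zero_day_prob) {
  counts <- rnbinom(n, mu = mu, size = k)
  if (zero_day_prob > 0) {
    counts[runif(n) < zero_day_prob] <- 0L
  }
  counts
}

#' Simulate a fieldwork log
#'
#' Draws daily collection counts per stratum from a zero-inflated
#' negative binomial until each stratum's cumulative count reaches its
#' target, emulating a fieldwork campaign run to completion. Strata use
#' independent RNG streams derived from the seed and the stratum name, so
#' a stratum's log is invariant to the presence of other strata.
#'
#' @param cfg A [synthetic_config()].
#' @return A [fieldwork_log()].
#' @export
#' @examples
#' log <- simulate_fieldwork_log(synthetic_config(seed = 42))
#' dplyr::count(log, stratum, wt = samples_collected)
simulate_fieldwork_log <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  logs <- purrr::map(sort(names(cfg$strata)), function(s) {
    p <- cfg$strata[[s]]
    counts <- with_seed_if(stream_seed(cfg$seed, s), {
      acc <- integer(0)
      while (sum(acc) < p$target) {
        block <- max(8L, ceiling(1.5 * p$target / p$mu))
        acc <- c(acc, rzinb(block, p$mu, p$k, p$zero_day_prob))
      }
      acc[seq_len(which(cumsum(acc) >= p$target)[1])]
    })
    tibble::tibble(date = cfg$start_date + seq_along(counts) - 1,
                   stratum = s, samples_collected = as.integer(counts))
  })
  fieldwork_log(dplyr::bind_rows(logs))
}

#' Simulate laboratory test outcomes
#'
#' Independent substandard indicators at a fixed true prevalence, one
#' per tested sample.
#'
#' @param n_tested Number of tested samples.
#' @param p True substandard probability in `[0, 1]`.
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @return A tibble with columns `sample_id`, `substandard` (logical).
#' @export
simulate_test_outcomes <- function(n_tested, p, seed = NULL) {
  stopifnot(n_tested >= 0, p >= 0, p <= 1)
  fails <- with_seed_if(seed, rbinom(n_tested, 1, p) == 1)
  tibble::tibble(sample_id = sprintf("S%05d", seq_len(n_tested)),
                 substandard = fails)
}

#' Simulate a cost ledger matching a share template
#'
#' Emits line items whose category and phase subtotals match
#' `proportions * grand_total` to within a dollar of rounding per cell.
#' The data-collection cell of other direct costs is split so that part
#' of it is tagged `medicine_purchase`, keeping the medicine-price
#' scenario exercisable on simulated data.
#'
#' @param cfg A [synthetic_config()].
#' @return A [cost_ledger()] in USD, financial basis.
#' @export
simulate_ledger <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  cells <- cfg$proportions * cfg$grand_total
  rows <- list()
  for (cat in rownames(cells)) {
    for (ph in colnames(cells)) {
      amt <- cells[cat, ph]
      if (amt <= 0) next
      if (cat == "other_direct" && ph == "data_collection") {
        med <- round_half_up(amt * 0.6, 2)
        rows <- c(rows, list(
          cost_item(paste0("syn_med_", ph), "medicine purchases at outlets",
                    cat, ph, med, sub_category = "medicine_purchase"),
          cost_item(paste0("syn_", cat, "_", ph),
                    "field services and collector allowances", cat, ph,
                    amt - med)
        ))
      } else {
        rows <- c(rows, list(
          cost_item(paste0("syn_", cat, "_", ph),
                    paste0("synthetic ", cat, " (", ph, ")"), cat, ph, amt)
        ))
      }
    }
  }
  if (length(rows) == 0) {
    return(cost_ledger(tibble::tibble(
      item_id = character(), description = character(),
      category = character(), phase = character(),
      sub_category = character(), amount = numeric(),
      currency = character(), cost_basis = character(), date = as.Date(NA)[0]
    )))
  }
  cost_ledger(dplyr::bind_rows(rows))
}

#' Write a complete synthetic input bundle
#'
#' Generates and writes the three analysis inputs — cost ledger,
#' fieldwork log and test outcomes — plus the configuration used, into a
#' directory, so a full pipeline run needs no external data.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written file paths, invisibly.
#' @export
simulate_inputs <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(ledger = file.path(dir, "ledger.csv"),
             fieldwork_log = file.path(dir, "fieldwork_log.csv"),
             outcomes = file.path(dir, "test_outcomes.csv"),
             config = file.path(dir, "synthetic_config.yaml"))
  write_ledger(simulate_ledger(cfg), paths[["ledger"]])
  readr::write_csv(simulate_fieldwork_log(cfg), paths[["fieldwork_log"]])
  readr::write_csv(simulate_test_outcomes(cfg$n_tested, cfg$true_prevalence,
                                          seed = stream_seed(cfg$seed, "outcomes")),
                   paths[["outcomes"]])
  yaml::write_yaml(list(
    seed = cfg$seed,
    strata = cfg$strata,
    n_tested = cfg$n_tested,
    true_prevalence = cfg$true_prevalence,
    grand_total = cfg$grand_total,
    start_date = as.character(cfg$start_date)
  ), paths[["config"]])
  invisible(paths)
}
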