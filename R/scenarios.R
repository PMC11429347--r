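#' Define a one-way sensitivity scenario
#'
#' A scenario perturbs exactly one input while all others are held
#' constant. The three canonical scenarios of a medicine-quality costing
#' analysis are: (A) medicine purchase prices multiplied (more expensive
#' molecules sampled), (B) preparation-phase costs scaled down
#' (preparation becomes cheaper with repetition), and (C) a different
#' substandard prevalence (laboratory cost per sample held constant).
#'
#' @param name Scenario name.
#' @param medicine_price_multiplier Multiplier applied to items tagged
#'   `sub_category == "medicine_purchase"` (scenario A uses 10).
#' @param preparation_cost_multiplier Multiplier applied to all items in
#'   the preparation phase (scenario B uses 0.5).
#' @param prevalence_override Optional prevalence in `(0, 1]` replacing
#'   the base prevalence (scenario C uses 0.20).
#' @return An object of class `scenario`.
#' @export
#' @examples
#' scenario("A", medicine_price_multiplier = 10)
#' scenario("C", prevalence_override = 0.20)
scenario <- function(name, medicine_price_multiplier = 1,
                     preparation_cost_multiplier = 1,
                     prevalence_override = NULL) {
  stopifnot(medicine_price_multiplier > 0, preparation_cost_multiplier > 0)
  if (!is.null(prevalence_override)) {
    stopifnot(prevalence_override > 0, prevalence_override <= 1)
  }
  n_perturbed <- (medicine_price_multiplier != 1) +
    (preparation_cost_multiplier != 1) + (!is.null(prevalence_override))
  if (n_perturbed > 1) {
    abort("a one-way scenario may perturb at most one input",
          class = "pmscost_validation_error")
  }
  structure(list(name = name,
                 medicine_price_multiplier = medicine_price_multiplier,
                 preparation_cost_multiplier = preparation_cost_multiplier,
                 prevalence_override = prevalence_override),
            class = "scenario")
}

#' Apply a scenario's ledger perturbation
#'
#' Returns a new ledger in which only the scenario's targeted items are
#' scaled; all other items are identical to the input. Medicine purchases
#' are identified by `sub_category == "medicine_purchase"`; preparation
#' costs by `phase == "preparation"`.
#'
#' @param ledger A [cost_ledger()].
#' @param scn A [scenario()].
#' @return The perturbed [cost_ledger()].
#' @export
apply_scenario <- function(ledger, scn) {
  ledger <- cost_ledger(ledger)
  stopifnot(inherits(scn, "scenario"))
  if (scn$medicine_price_multiplier != 1) {
    is_med <- ledger$sub_category == "medicine_purchase"
    if (!any(is_med)) {
      abort("scenario scales medicine purchases but the ledger has no items ",
            class = "pmscost_validation_error")
    }
    ledger$amount[is_med] <- ledger$amount[is_med] *
      scn$medicine_price_multiplier
  }
  if (scn$preparation_cost_multiplier != 1) {
    is_prep <- ledger$phase == "preparation"
    ledger$amount[is_prep] <- ledger$amount[is_prep] *
      scn$preparation_cost_multiplier
  }
  cost_ledger(ledger)
}

#' Run a one-way sensitivity analysis
#'
#' Re-runs the unit-cost bootstrap under each scenario, holding
#' everything else constant: the same fieldwork log, the same bootstrap
#' seed (so differences between rows reflect only the perturbation), and
#' the base prevalence unless a scenario overrides it. Ledger
#' perturbations enter the bootstrap through the duration-independent
#' fixed cost, shifted by the scenario's change in ledger total. The base
#' case is included as the first row.
#'
#' @param ledger The base [cost_ledger()] (USD, phase-allocated).
#' @param log A [fieldwork_log()].
#' @param cfg A [bootstrap_config()] describing the base case.
#' @param base_prevalence A [crude_prevalence()] object or a number in
#'   `(0, 1]`.
#' @param scenarios A list of [scenario()] objects.
#' @return A long-format tibble with columns `scenario`, `quantity`,
#'   `mean`, `ci_low`, `ci_high`, `iterations`, `seed`.
#' @export
run_one_way <- function(ledger, log, cfg, base_prevalence, scenarios) {
  ledger <- cost_ledger(ledger)
  if (inherits(base_prevalence, "prevalence_estimate")) {
    base_prevalence <- base_prevalence$p
  }
  scenarios <- c(list(scenario("base")), scenarios)
  base_total <- sum(ledger$amount)
  rows <- purrr::map(scenarios, function(scn) {
    led2 <- apply_scenario(ledger, scn)
    cfg2 <- cfg
    cfg2$fixed_cost <- cfg$fixed_cost + (sum(led2$amount) - base_total)
    prev <- scn$prevalence_override %||% base_prevalence
    est <- bootstrap_unit_costs(log, cfg2, prev)
    dplyr::mutate(est, scenario = scn$name, .before = 1)
  })
  dplyr::bind_rows(rows)
}
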