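#' Cost categories, study phases and cost bases
#'
#' The closed vocabularies used throughout the package. Cost components
#' follow the standard breakdown of a medicine-quality surveillance budget:
#' staff salaries, equipment, consumables, travel, laboratory testing,
#' other direct costs (sample purchase, field services, per-diem top-ups)
#' and indirect costs (overheads). Study phases run from initial design
#' through to analysis and reporting; `"unallocated"` is accepted on input
#' but must be resolved before summarisation.
#'
#' @return A character vector of allowed values.
#' @export
#' @examples
#' cost_categories()
#' study_phases()
cost_categories <- function() {
  c("salaries", "equipment", "consumables", "travel", "laboratory",
    "other_direct", "indirect")
}

#' @rdname cost_categories
#' @export
study_phases <- function() {
  c("study_setup", "preparation", "data_collection", "analysis_reporting")
}

#' @rdname cost_categories
#' @export
cost_bases <- function() c("financial", "economic")

ledger_columns <- function() {
  c("item_id", "description", "category", "phase", "sub_category",
    "amount", "currency", "cost_basis", "date")
}

#' Construct a single cost item
#'
#' A cost item is one expenditure line: the unit of all aggregation.
#' Financial items come from expenditure records; economic items value
#' resources consumed without a financial transaction (staff overtime,
#' personally owned equipment).
#'
#' @param item_id Unique identifier within a ledger.
#' @param description Free-text description.
#' @param category One of [cost_categories()].
#' @param phase One of [study_phases()], or `"unallocated"`.
#' @param amount Non-negative amount in `currency` units.
#' @param currency ISO 4217 code, e.g. `"USD"`, `"GBP"`, `"IDR"`.
#' @param cost_basis `"financial"` or `"economic"`.
#' @param sub_category Free-text tag (e.g. `"medicine_purchase"`,
#'   `"per_diem"`) used by the scenario engine to target items.
#' @param date Optional calendar date (coerced with [as.Date()]).
#' @return A one-row [cost_ledger()].
#' @export
#' @examples
#' cost_item("L1", "pharmacopeial testing", "laboratory",
#'           "analysis_reporting", 481704, "USD")
cost_item <- function(item_id, description, category, phase, amount,
                      currency = "USD", cost_basis = "financial",
                      sub_category = "", date = NA) {
  cost_ledger(tibble::tibble(
    item_id = as.character(item_id),
    description = as.character(description),
    category = as.character(category),
    phase = as.character(phase),
    sub_category = as.character(sub_category),
    amount = as.numeric(amount),
    currency = as.character(currency),
    cost_basis = as.character(cost_basis),
    date = as.Date(date)
  ))
}

#' Validate and classify a cost ledger
#'
#' @param x A data frame with the ledger columns (see [read_ledger()]).
#' @return `x` as a tibble with class `cost_ledger`.
#' @export
cost_ledger <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"date" %in% names(x)) x$date <- as.Date(NA)
  if (!"sub_category" %in% names(x)) x$sub_category <- ""
  missing_cols <- setdiff(setdiff(ledger_columns(), c("date", "sub_category")),
                          names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("ledger is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pmscost_validation_error")
  }
  x <- x[, ledger_columns()]
  x$sub_category[is.na(x$sub_category)] <- ""
  x$description[is.na(x$description)] <- ""
  x$amount <- as.numeric(x$amount)
  x$date <- as.Date(x$date)
  validate_ledger(x)
  structure(x, class = c("cost_ledger", class(tibble::tibble())))
}

validate_ledger <- function(x) {
  row_err <- function(rows, what, extra = NULL) {
    msg <- paste0(what, " on row(s) ", paste(rows, collapse = ", "))
    if (!is.null(extra)) msg <- paste0(msg, "; ", extra)
    abort(msg, class = "pmscost_validation_error")
  }
  bad <- which(is.na(x$amount) | x$amount < 0)
  if (length(bad) > 0) row_err(bad, "negative or missing amount")
  bad <- which(!x$category %in% cost_categories())
  if (length(bad) > 0) {
    row_err(bad, paste0("unknown category ",
                        paste(unique(x$category[bad]), collapse = ", ")),
            paste0("allowed values: ",
                   paste(cost_categories(), collapse = ", ")))
  }
  bad <- which(!x$phase %in% c(study_phases(), "unallocated"))
  if (length(bad) > 0) {
    row_err(bad, paste0("unknown phase ",
                        paste(unique(x$phase[bad]), collapse = ", ")),
            paste0("allowed values: ",
                   paste(c(study_phases(), "unallocated"), collapse = ", ")))
  }
  bad <- which(!x$cost_basis %in% cost_bases())
  if (length(bad) > 0) {
    row_err(bad, paste0("unknown cost_basis ",
                        paste(unique(x$cost_basis[bad]), collapse = ", ")),
            paste0("allowed values: ", paste(cost_bases(), collapse = ", ")))
  }
  dup <- x$item_id[duplicated(x$item_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicated item_id: ", paste(unique(dup), collapse = ", ")),
          class = "pmscost_validation_error")
  }
  invisible(x)
}

#' Read a cost ledger from a delimited text file
#'
#' Expects a header row and the columns `item_id`, `description`,
#' `category`, `phase`, `sub_category`, `amount`, `currency`,
#' `cost_basis` and optionally `date` (ISO 8601). Rows with unknown
#' category, phase or cost-basis values are rejected with their row
#' numbers, never silently coerced.
#'
#' @param path Path to the file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(amount = "cost_usd")`.
#' @param delim Field delimiter (default comma).
#' @return A [cost_ledger()].
#' @export
read_ledger <- function(path, schema = NULL, delim = ",") {
  if (!file.exists(path)) {
    abort(paste0("ledger file not found: ", path), class = "pmscost_io_error")
  }
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(x)) {
        abort(paste0("schema column not found in file: ", schema[[canon]]),
              class = "pmscost_validation_error")
      }
      names(x)[names(x) == schema[[canon]]] <- canon
    }
  }
  cost_ledger(x)
}

#' Write a cost ledger to a delimited text file
#'
#' Inverse of [read_ledger()]: reading the written file back reproduces
#' the ledger.
#'
#' @param ledger A [cost_ledger()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  ledger <- cost_ledger(ledger)
  readr::write_csv(ledger, path, na = "")
  invisible(path)
}

#' Define currency-to-USD conversion rates
#'
#' @param rates Named numeric vector of USD-per-unit rates, e.g.
#'   `c(GBP = 1.237, IDR = 6.7e-05)`. `USD` is added automatically and,
#'   if supplied, must equal 1.
#' @param period Label for the reference period, e.g.
#'   `"2022 annual average"`.
#' @return An object of class `currency_rates`.
#' @export
#' @examples
#' currency_rates(c(GBP = 1.237, IDR = 6.7e-05), "2022 annual average")
currency_rates <- function(rates, period = "") {
  rates <- unlist(rates)
  if (is.null(names(rates)) || any(names(rates) == "")) {
    abort("rates must be a named vector of USD-per-unit values",
          class = "pmscost_validation_error")
  }
  if (any(!is.finite(rates) | rates <= 0)) {
    abort("all exchange rates must be positive",
          class = "pmscost_validation_error")
  }
  if ("USD" %in% names(rates) && rates[["USD"]] != 1) {
    abort("the USD rate must be exactly 1", class = "pmscost_validation_error")
  }
  rates[["USD"]] <- 1
  structure(list(rates = rates, period = period), class = "currency_rates")
}

#' Convert ledger amounts to US dollars
#'
#' Multiplies each amount by its currency's USD-per-unit rate and sets
#' the currency to `USD`. Items already in USD are unchanged, so the
#' operation is idempotent.
#'
#' @param ledger A [cost_ledger()].
#' @param rates A [currency_rates()] object.
#' @return The converted [cost_ledger()].
#' @export
convert_to_usd <- function(ledger, rates) {
  ledger <- cost_ledger(ledger)
  stopifnot(inherits(rates, "currency_rates"))
  unknown <- setdiff(unique(ledger$currency), names(rates$rates))
  if (length(unknown) > 0) {
    abort(paste0("no USD exchange rate for currency: ",
                 paste(unknown, collapse = ", ")),
          class = "pmscost_validation_error")
  }
  ledger$amount <- ledger$amount * unname(rates$rates[ledger$currency])
  ledger$currency <- "USD"
  cost_ledger(ledger)
}

#' Annualise a capital purchase
#'
#' Spreads a capital purchase over its useful life. The default is the
#' equivalent annual cost (EAC), the annuity payment `A` that equates the
#' discounted stream of `n` annual payments to the purchase price:
#' `A = P * r / (1 - (1 + r)^-n)`. With `r = 0` this reduces to
#' straight-line depreciation `P / n`, also available explicitly via
#' `method = "straight_line"`. The ledger contribution of an asset that
#' serves only part of the costing horizon is `A * in_service_fraction`.
#'
#' @param purchase_price Non-negative purchase price.
#' @param useful_life_years Useful life in whole years (default 5).
#' @param discount_rate Annual discount rate in `[0, 1)` (default 0.03).
#' @param in_service_fraction Fraction of the costing horizon the asset
#'   serves, in `(0, 1]` (default 1).
#' @param method `"eac"` (annuity factor, default) or `"straight_line"`.
#' @return Annual cost (same currency as `purchase_price`).
#' @export
#' @examples
#' annualize_capital(1000, 5, 0.03) # 218.35 per year
#' annualize_capital(1000, 5, 0)    # 200 per year
annualize_capital <- function(purchase_price, useful_life_years = 5,
                              discount_rate = 0.03, in_service_fraction = 1,
                              method = c("eac", "straight_line")) {
  method <- match.arg(method)
  stopifnot(purchase_price >= 0,
            useful_life_years >= 1,
            useful_life_years == as.integer(useful_life_years),
            discount_rate >= 0, discount_rate < 1,
            in_service_fraction > 0, in_service_fraction <= 1)
  annual <- if (method == "straight_line" || discount_rate == 0) {
    purchase_price / useful_life_years
  } else {
    # 1 - (1+r)^-n written via expm1/log1p so the annuity factor stays
    # accurate as r approaches 0
    purchase_price * discount_rate /
      (-expm1(-useful_life_years * log1p(discount_rate)))
  }
  annual * in_service_fraction
}
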