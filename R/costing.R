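#' Study phase calendar
#'
#' Calendar spans for the four study phases, used to allocate salaries
#' proportionally to calendar days. The default spans reproduce the
#' typical timeline of a one-year surveillance exercise: a setup
#' year, a four-and-a-half-month preparation window, a three-month
#' data-collection window, and a final analysis-and-reporting period.
#' Phases must be ordered and non-overlapping.
#'
#' @param spans Named list of `c(start, end)` date pairs, one per phase,
#'   in [study_phases()] order.
#' @return An object of class `phase_calendar` with a `days` vector.
#' @export
#' @examples
#' phase_calendar()$days
phase_calendar <- function(spans = list(
  study_setup = c("2020-10-01", "2021-09-30"),
  preparation = c("2021-10-01", "2022-02-12"),
  data_collection = c("2022-02-13", "2022-05-09"),
  analysis_reporting = c("2022-05-10", "2022-06-30")
)) {
  stopifnot(all(names(spans) %in% study_phases()), length(spans) >= 1)
  spans <- lapply(spans, as.Date)
  starts <- vapply(spans, `[`, as.Date(NA), 1)
  ends <- vapply(spans, `[`, as.Date(NA), 2)
  days <- as.numeric(ends - starts) + 1
  if (any(days < 1)) {
    abort("each phase span must cover at least one day",
          class = "pmscost_validation_error")
  }
  if (length(spans) > 1 &&
      any(utils::head(ends, -1) >= starts[-1])) {
    abort("phase spans must be ordered and non-overlapping",
          class = "pmscost_validation_error")
  }
  structure(list(spans = spans, days = setNames(days, names(spans))),
            class = "phase_calendar")
}

#' Define a staff member
#'
#' Salary grades follow a civil-service scale where grade I is assistant
#' level and grade IV principal-investigator level; each grade carries a
#' monthly allowance on top of base salary. Full-time equivalent (FTE) is
#' hours worked divided by the hours in a full-time workweek.
#'
#' @param role_label Role, e.g. `"senior investigator"`.
#' @param grade Salary grade, one of `"I"`, `"II"`, `"III"`, `"IV"`.
#' @param base_salary Monthly base salary.
#' @param allowance Monthly allowance (default 0).
#' @param hours_per_week Contracted weekly hours (default 40).
#' @param fulltime_week_hours Hours in a full-time workweek (default 40:
#'   5 days, 09:00 to 17:00).
#' @return An object of class `staff_member` with an `fte` field.
#' @export
#' @examples
#' staff_member("data manager", "II", 900, 150)$fte
staff_member <- function(role_label, grade = c("I", "II", "III", "IV"),
                         base_salary, allowance = 0, hours_per_week = 40,
                         fulltime_week_hours = 40) {
  grade <- match.arg(grade)
  stopifnot(base_salary >= 0, allowance >= 0, hours_per_week > 0,
            fulltime_week_hours > 0, hours_per_week <= fulltime_week_hours)
  structure(list(
    role_label = role_label, grade = grade,
    base_salary = base_salary, allowance = allowance,
    fte = hours_per_week / fulltime_week_hours,
    fulltime_week_hours = fulltime_week_hours
  ), class = "staff_member")
}

# Weekly gross salary (base + allowance) from monthly figures.
weekly_salary <- function(staff) {
  (staff$base_salary + staff$allowance) * 12 / 52
}

#' Allocate a salary total across study phases by calendar days
#'
#' Splits a total salary over the employment span across phases in
#' proportion to the number of calendar days in each. The final phase
#' receives the residual (total minus the other allocations) so the
#' allocations always sum exactly to the total.
#'
#' @param total_salary Total salary over the employment span.
#' @param calendar A [phase_calendar()].
#' @param phases Phases to allocate across (default: all phases in the
#'   calendar).
#' @return Named numeric vector, one amount per phase.
#' @export
#' @examples
#' cal <- phase_calendar(list(
#'   preparation = c("2022-01-01", "2022-01-30"),
#'   data_collection = c("2022-01-31", "2022-03-31"),
#'   analysis_reporting = c("2022-04-01", "2022-04-10")
#' ))
#' allocate_salary_by_calendar_days(1000, cal)
allocate_salary_by_calendar_days <- function(total_salary, calendar,
                                             phases = names(calendar$days)) {
  stopifnot(inherits(calendar, "phase_calendar"), total_salary >= 0)
  if (length(phases) == 0) {
    abort("phase set must be non-empty", class = "pmscost_validation_error")
  }
  missing_ph <- setdiff(phases, names(calendar$days))
  if (length(missing_ph) > 0) {
    abort(paste0("phase(s) not in calendar: ",
                 paste(missing_ph, collapse = ", ")),
          class = "pmscost_validation_error")
  }
  days <- calendar$days[phases]
  alloc <- total_salary * days / sum(days)
  if (length(alloc) > 1) {
    alloc[length(alloc)] <- total_salary - sum(alloc[-length(alloc)])
  }
  alloc
}

#' Value staff overtime as an economic cost item
#'
#' Overtime (hours worked outside 09:00-17:00) is valued at the same
#' hourly rate as full-time employed time: weekly gross salary divided by
#' the hours in a full-time workweek, times the overtime hours. Returns
#' an economic cost item in the salaries category, tagged to the phase in
#' which the overtime occurred.
#'
#' @param staff A [staff_member()].
#' @param overtime_hours Non-negative overtime hours.
#' @param phase Study phase of the overtime.
#' @param item_id Identifier for the generated item.
#' @return A one-row [cost_ledger()] with `cost_basis = "economic"`.
#' @export
value_overtime <- function(staff, overtime_hours, phase,
                           item_id = paste0("ot_", gsub("\\s+", "_", staff$role_label),
                                            "_", phase)) {
  stopifnot(inherits(staff, "staff_member"), overtime_hours >= 0)
  hourly <- weekly_salary(staff) / staff$fulltime_week_hours
  cost_item(item_id,
            paste0("overtime: ", staff$role_label),
            "salaries", phase, hourly * overtime_hours,
            currency = "USD", cost_basis = "economic",
            sub_category = "overtime")
}

#' Apply an overhead (indirect cost) rule to a ledger
#'
#' Computes indirect costs as a flat rate on the sum of the base
#' categories (by default salaries, consumables, travel and other direct
#' costs, at 10%), and allocates the total across phases in proportion to
#' each phase's base-category spend so the category-by-phase matrix stays
#' conservative. The ledger must not already contain indirect items;
#' rule-generated overheads and ledger-recorded overheads are mutually
#' exclusive.
#'
#' @param ledger A [cost_ledger()] with amounts in USD.
#' @param rate Overhead rate in `[0, 1)` (default 0.10).
#' @param base_categories Categories forming the overhead base; must not
#'   include `"indirect"`.
#' @param basis Cost basis to assign to the generated items.
#' @return A [cost_ledger()] of indirect items, one per phase with
#'   non-zero base spend (a single zero item if the base is zero).
#' @export
#' @examples
#' led <- cost_item("s1", "salaries", "salaries", "preparation", 1000)
#' apply_overhead(led, rate = 0.10)$amount # 100
apply_overhead <- function(ledger, rate = 0.10,
                           base_categories = c("salaries", "consumables",
                                               "travel", "other_direct"),
                           basis = "financial") {
  ledger <- cost_ledger(ledger)
  stopifnot(rate >= 0, rate < 1)
  if (length(base_categories) == 0) {
    abort("base_categories must be non-empty",
          class = "pmscost_validation_error")
  }
  if ("indirect" %in% base_categories) {
    abort("the overhead base cannot include the indirect category",
          class = "pmscost_validation_error")
  }
  if (any(ledger$category == "indirect")) {
    abort(paste0("ledger already contains indirect items; rule-generated ",
                 "overheads and ledger-recorded overheads are mutually ",
                 "exclusive"),
          class = "pmscost_validation_error")
  }
  base <- dplyr::filter(ledger, .data$category %in% base_categories)
  total <- rate * sum(base$amount)
  by_phase <- dplyr::summarise(dplyr::group_by(base, .data$phase),
                               spend = sum(.data$amount), .groups = "drop")
  by_phase <- dplyr::filter(by_phase, .data$spend > 0)
  if (nrow(by_phase) == 0 || total == 0) {
    ph <- if (nrow(by_phase) > 0) by_phase$phase[1] else "unallocated"
    return(cost_item("overhead", "overheads (rule-generated)", "indirect",
                     ph, 0, cost_basis = basis, sub_category = "overhead"))
  }
  alloc <- total * by_phase$spend / sum(by_phase$spend)
  if (length(alloc) > 1) {
    alloc[length(alloc)] <- total - sum(alloc[-length(alloc)])
  }
  cost_ledger(tibble::tibble(
    item_id = paste0("overhead_", by_phase$phase),
    description = "overheads (rule-generated)",
    category = "indirect",
    phase = by_phase$phase,
    sub_category = "overhead",
    amount = alloc,
    currency = "USD",
    cost_basis = basis,
    date = as.Date(NA)
  ))
}

#' Summarise a ledger by cost component and study phase
#'
#' Aggregates a fully converted, phase-allocated ledger into the standard
#' reporting table: a category-by-phase matrix of USD totals with
#' per-category and per-phase totals and percentage shares of the grand
#' total. The financial summary uses financial items only; the economic
#' summary additionally includes economic items (overtime, personally
#' owned equipment). Shares are computed before any rounding; at print
#' time they are rounded half-up to whole percent, except shares below 1%
#' which are shown to one decimal.
#'
#' @param ledger A [cost_ledger()] with all amounts in USD and no
#'   unallocated phases.
#' @param basis `"financial"` (default) or `"economic"`; the grand totals
#'   on both bases are always reported.
#' @return An object of class `cost_summary`.
#' @export
summarize_costs <- function(ledger, basis = c("financial", "economic")) {
  basis <- match.arg(basis)
  ledger <- cost_ledger(ledger)
  if (any(ledger$currency != "USD")) {
    abort("all ledger amounts must be converted to USD before summarising",
          class = "pmscost_validation_error")
  }
  bad <- which(ledger$phase == "unallocated")
  if (length(bad) > 0) {
    abort(paste0("unallocated items present: ",
                 paste(ledger$item_id[bad], collapse = ", ")),
          class = "pmscost_validation_error")
  }
  grand_fin <- sum(ledger$amount[ledger$cost_basis == "financial"])
  grand_eco <- sum(ledger$amount)
  items <- if (basis == "financial") {
    dplyr::filter(ledger, .data$cost_basis == "financial")
  } else {
    ledger
  }
  mat <- matrix(0, nrow = length(cost_categories()),
                ncol = length(study_phases()),
                dimnames = list(cost_categories(), study_phases()))
  if (nrow(items) > 0) {
    cell <- dplyr::summarise(
      dplyr::group_by(items, .data$category, .data$phase),
      amount = sum(.data$amount), .groups = "drop")
    mat[cbind(cell$category, cell$phase)] <- cell$amount
  }
  grand <- sum(mat)
  share <- function(x) if (grand > 0) 100 * x / grand else rep(0, length(x))
  structure(list(
    basis = basis,
    matrix = mat,
    category_totals = tibble::tibble(
      category = cost_categories(),
      amount = unname(rowSums(mat)),
      share_pct = share(unname(rowSums(mat)))
    ),
    phase_totals = tibble::tibble(
      phase = study_phases(),
      amount = unname(colSums(mat)),
      share_pct = share(unname(colSums(mat)))
    ),
    grand_total = grand,
    grand_total_financial = grand_fin,
    grand_total_economic = grand_eco
  ), class = "cost_summary")
}

# Format a percentage share for reporting: whole percent, half-up, except
# shares under 1% which get one decimal (so small components do not print
# as 0).
format_share <- function(p) {
  ifelse(p < 1 & p > 0,
         sprintf("%.1f", round_half_up(p, 1)),
         sprintf("%d", as.integer(round_half_up(p, 0))))
}

#' @export
print.cost_summary <- function(x, ...) {
  fmt_usd <- function(v) formatC(round_half_up(v), format = "d", big.mark = " ")
  cat("Cost summary (", x$basis, " basis, USD)\n\n", sep = "")
  cat("By cost component\n")
  ct <- x$category_totals
  for (i in seq_len(nrow(ct))) {
    cat(sprintf("  %-20s US$ %12s  %s%%\n", ct$category[i],
                fmt_usd(ct$amount[i]), format_share(ct$share_pct[i])))
  }
  cat(sprintf("  %-20s US$ %12s  100%%\n", "Total", fmt_usd(x$grand_total)))
  cat("\nBy study phase\n")
  pt <- x$phase_totals
  for (i in seq_len(nrow(pt))) {
    cat(sprintf("  %-20s US$ %12s  %s%%\n", pt$phase[i],
                fmt_usd(pt$amount[i]), format_share(pt$share_pct[i])))
  }
  cat(sprintf("  %-20s US$ %12s  100%%\n", "Total", fmt_usd(x$grand_total)))
  cat(sprintf("\nGrand total, financial basis: US$ %s\n",
              fmt_usd(x$grand_total_financial)))
  cat(sprintf("Grand total, economic basis:  US$ %s\n",
              fmt_usd(x$grand_total_economic)))
  invisible(x)
}

#' Write or read a cost summary
#'
#' `write_summary()` serialises a [summarize_costs()] result to CSV (long
#' format: block, name, amount, share) or JSON; `read_summary()` reads
#' the file back as a tibble whose totals reproduce the summary exactly.
#'
#' @param summary A `cost_summary`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `write_summary()` returns `path` invisibly; `read_summary()`
#'   returns a tibble with columns `block`, `name`, `amount_usd`,
#'   `share_pct`.
#' @export
write_summary <- function(summary, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(summary, "cost_summary"))
  tab <- summary_as_table(summary)
  if (format == "csv") {
    readr::write_csv(tab, path)
  } else {
    jsonlite::write_json(tab, path, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

summary_as_table <- function(summary) {
  dplyr::bind_rows(
    tibble::tibble(block = "component",
                   name = summary$category_totals$category,
                   amount_usd = summary$category_totals$amount,
                   share_pct = summary$category_totals$share_pct),
    tibble::tibble(block = "phase",
                   name = summary$phase_totals$phase,
                   amount_usd = summary$phase_totals$amount,
                   share_pct = summary$phase_totals$share_pct),
    tibble::tibble(block = "total",
                   name = c("grand_total", "grand_total_financial",
                            "grand_total_economic"),
                   amount_usd = c(summary$grand_total,
                                  summary$grand_total_financial,
                                  summary$grand_total_economic),
                   share_pct = c(100, NA, NA))
  )
}

#' @rdname write_summary
#' @export
read_summary <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE,
                    col_types = readr::cols(
                      block = readr::col_character(),
                      name = readr::col_character(),
                      amount_usd = readr::col_double(),
                      share_pct = readr::col_double()
                    ))
  } else {
    tibble::as_tibble(jsonlite::fromJSON(path))
  }
}
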