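#' Validate workload records from a time-and-motion study
#'
#' One record per activity: the team's total hours worked per week
#' (including overtime), the number of weeks the activity ran, and the
#' overtime hours per week (hours outside 09:00-17:00).
#'
#' @param x A data frame with columns `activity`,
#'   `total_hours_per_week`, `weeks_executed`, `overtime_hours_per_week`.
#' @return `x` as a tibble with class `workload_records`.
#' @export
workload_records <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("activity", "total_hours_per_week", "weeks_executed",
            "overtime_hours_per_week")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("workload records missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pmscost_validation_error")
  }
  allowed <- c("preparation", "data_collection", "stakeholder_engagement")
  bad <- which(!x$activity %in% allowed)
  if (length(bad) > 0) {
    abort(paste0("unknown activity on row(s) ",
                 paste(bad, collapse = ", "), "; allowed values: ",
                 paste(allowed, collapse = ", ")),
          class = "pmscost_validation_error")
  }
  if (any(x$total_hours_per_week < 0 | x$weeks_executed < 0 |
          x$overtime_hours_per_week < 0)) {
    abort("hours and weeks must be non-negative",
          class = "pmscost_validation_error")
  }
  if (any(x$overtime_hours_per_week > x$total_hours_per_week)) {
    abort("overtime_hours_per_week cannot exceed total_hours_per_week",
          class = "pmscost_validation_error")
  }
  structure(x[, need], class = c("workload_records",
                                 class(tibble::tibble())))
}

#' Weeks needed to execute an activity without overtime
#'
#' If the weekly total includes `o` overtime hours out of `h`, delivering
#' the same total workload at `h - o` regular hours per week takes
#' `weeks_executed * h / (h - o)` weeks. Total hours are conserved:
#' `weeks_needed * (h - o) = weeks_executed * h`.
#'
#' @param weeks_executed Weeks the activity actually ran.
#' @param total_hours_per_week Total weekly hours including overtime.
#' @param overtime_hours_per_week Weekly overtime hours (strictly less
#'   than the total).
#' @return Weeks needed without overtime.
#' @export
#' @examples
#' weeks_needed_without_overtime(12.9, 30.5, 9.23) # 18.5
weeks_needed_without_overtime <- function(weeks_executed,
                                          total_hours_per_week,
                                          overtime_hours_per_week) {
  stopifnot(all(weeks_executed >= 0), all(total_hours_per_week > 0),
            all(overtime_hours_per_week >= 0))
  if (any(overtime_hours_per_week >= total_hours_per_week)) {
    abort("overtime equals total hours: no regular time remains",
          class = "pmscost_validation_error")
  }
  weeks_executed * total_hours_per_week /
    (total_hours_per_week - overtime_hours_per_week)
}

#' Express total overtime in conventional working weeks
#'
#' @param total_overtime_hours Total overtime hours.
#' @param week_hours Hours in a conventional working week (default 40:
#'   5 days, 09:00-17:00).
#' @return Equivalent number of conventional weeks.
#' @export
#' @examples
#' overtime_in_conventional_weeks(160) # 4 weeks
overtime_in_conventional_weeks <- function(total_overtime_hours,
                                           week_hours = 40) {
  stopifnot(total_overtime_hours >= 0, week_hours > 0)
  total_overtime_hours / week_hours
}

#' Convert workload records to per-phase overtime hours
#'
#' Maps each activity to a study phase and totals overtime hours per
#' phase, ready for economic valuation with [value_overtime()].
#'
#' @param records A [workload_records()] tibble.
#' @param phase_map Named character vector mapping activities to phases;
#'   the default maps preparation and stakeholder engagement to the
#'   preparation phase and data collection to the data-collection phase.
#' @return A tibble with columns `phase`, `overtime_hours`.
#' @export
to_overtime_records <- function(records, phase_map = c(
  preparation = "preparation",
  data_collection = "data_collection",
  stakeholder_engagement = "preparation"
)) {
  records <- workload_records(records)
  unmapped <- setdiff(unique(records$activity), names(phase_map))
  if (length(unmapped) > 0) {
    abort(paste0("no phase mapping for activity: ",
                 paste(unmapped, collapse = ", ")),
          class = "pmscost_validation_error")
  }
  if (nrow(records) == 0) {
    return(tibble::tibble(phase = character(), overtime_hours = numeric()))
  }
  records$phase <- unname(phase_map[records$activity])
  records$overtime_hours <- records$overtime_hours_per_week *
    records$weeks_executed
  dplyr::summarise(dplyr::group_by(records, .data$phase),
                   overtime_hours = sum(.data$overtime_hours),
                   .groups = "drop")
}

#' Operational efficiency indicators for a set of activities
#'
#' Convenience wrapper producing the standard workload table: hours
#' worked per week, weeks executed, and weeks that would have been needed
#' without overtime.
#'
#' @param records A [workload_records()] tibble.
#' @return The records with a `weeks_needed_no_overtime` column added.
#' @export
workload_indicators <- function(records) {
  records <- workload_records(records)
  dplyr::mutate(records, weeks_needed_no_overtime = weeks_needed_without_overtime(
    .data$weeks_executed, .data$total_hours_per_week,
    .data$overtime_hours_per_week))
}
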