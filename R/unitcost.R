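#' Validate a fieldwork log
#'
#' A fieldwork log records, for each day of fieldwork and each outlet
#' stratum (typically urban, rural and online), the number of medicine
#' samples collected. The observed daily counts are the resampling
#' population for the bootstrap.
#'
#' @param x A data frame with columns `date`, `stratum`,
#'   `samples_collected`.
#' @return `x` as a tibble with class `fieldwork_log`.
#' @export
fieldwork_log <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("date", "stratum", "samples_collected")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("fieldwork log is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "pmscost_validation_error")
  }
  x$date <- as.Date(x$date)
  x$samples_collected <- as.numeric(x$samples_collected)
  if (any(is.na(x$samples_collected) | x$samples_collected < 0 |
          x$samples_collected != floor(x$samples_collected))) {
    abort("samples_collected must be non-negative integers",
          class = "pmscost_validation_error")
  }
  structure(x[, need], class = c("fieldwork_log", class(tibble::tibble())))
}

#' Read a fieldwork log from a delimited text file
#'
#' @param path Path to a file with header columns `date`, `stratum`,
#'   `samples_collected`.
#' @param delim Field delimiter (default comma).
#' @return A [fieldwork_log()].
#' @export
read_fieldwork_log <- function(path, delim = ",") {
  if (!file.exists(path)) {
    abort(paste0("fieldwork log not found: ", path),
          class = "pmscost_io_error")
  }
  fieldwork_log(readr::read_delim(path, delim = delim,
                                  show_col_types = FALSE))
}

#' Crude prevalence of substandard samples
#'
#' The crude prevalence is the number of samples failing at least one
#' pharmacopeial test divided by the number tested. A market-size
#' adjusted prevalence, when available from a separate analysis, is
#' carried as an externally supplied value.
#'
#' @param n_substandard Number of substandard samples.
#' @param n_tested Number of samples tested (>= 1).
#' @param adjusted_p Optional externally supplied adjusted prevalence in
#'   `[0, 1]`.
#' @return An object of class `prevalence_estimate` with fields `p`,
#'   `n_substandard`, `n_tested`, `label`, `adjusted_p`.
#' @export
#' @examples
#' crude_prevalence(105, 1274)$p # 0.0824...
crude_prevalence <- function(n_substandard, n_tested, adjusted_p = NULL) {
  stopifnot(n_tested >= 1, n_substandard >= 0)
  if (n_substandard > n_tested) {
    abort("n_substandard cannot exceed n_tested",
          class = "pmscost_validation_error")
  }
  if (!is.null(adjusted_p)) stopifnot(adjusted_p >= 0, adjusted_p <= 1)
  structure(list(p = n_substandard / n_tested,
                 n_substandard = n_substandard, n_tested = n_tested,
                 label = "crude", adjusted_p = adjusted_p),
            class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("%s substandard prevalence: %d/%d = %.1f%%\n", x$label,
              x$n_substandard, x$n_tested, 100 * x$p))
  if (!is.null(x$adjusted_p)) {
    cat(sprintf("adjusted prevalence (external): %.1f%%\n",
                100 * x$adjusted_p))
  }
  invisible(x)
}

#' Cost per sample collected
#'
#' Divides an attributable cost by the number of samples. The cost scope
#' (which components the numerator includes) is recorded alongside the
#' result so unit costs with different scopes are not conflated.
#'
#' @param attributable_cost Non-negative USD cost.
#' @param n_samples Number of samples (>= 1).
#' @param scope Cost scope of the numerator: `"all"`, `"excl_lab"` or
#'   `"excl_indirect"`.
#' @return Numeric cost per sample with attribute `scope`.
#' @export
#' @examples
#' round(cost_per_sample(481704, 1274)) # 378, laboratory scope
cost_per_sample <- function(attributable_cost, n_samples,
                            scope = c("all", "excl_lab", "excl_indirect")) {
  scope <- match.arg(scope)
  stopifnot(attributable_cost >= 0)
  if (n_samples < 1) {
    abort("n_samples must be at least 1", class = "pmscost_validation_error")
  }
  structure(attributable_cost / n_samples, scope = scope)
}

#' Cost per substandard sample detected
#'
#' The expected cost of detecting one substandard sample (collect, test
#' and report) is the cost per sample divided by the substandard
#' prevalence: at prevalence `p`, on average `1/p` samples must be
#' collected and tested per substandard sample found.
#'
#' @param per_sample Cost per sample collected.
#' @param prevalence Substandard prevalence in `(0, 1]`, or a
#'   [crude_prevalence()] object.
#' @return Numeric cost per substandard sample.
#' @export
#' @examples
#' round(cost_per_substandard(479, 105 / 1274)) # 5812
cost_per_substandard <- function(per_sample, prevalence) {
  if (inherits(prevalence, "prevalence_estimate")) prevalence <- prevalence$p
  stopifnot(per_sample >= 0, prevalence <= 1)
  if (prevalence <= 0) {
    abort("no substandard detectable; unit cost undefined",
          class = "pmscost_validation_error")
  }
  as.numeric(per_sample) / prevalence
}

#' Percentile confidence interval
#'
#' Empirical quantile interval with linear interpolation between order
#' statistics (position `h = (n - 1) q + 1`, the default quantile
#' definition in most statistical software).
#'
#' @param values Numeric vector with at least two values.
#' @param level Confidence level in `(0, 1)` (default 0.95).
#' @return Named numeric vector `c(low, high)`.
#' @export
#' @examples
#' percentile_ci(1:1000, 0.95) # 25.975, 975.025
percentile_ci <- function(values, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (length(values) < 2) {
    abort("percentile_ci needs at least two values",
          class = "pmscost_validation_error")
  }
  alpha <- (1 - level) / 2
  q <- quantile(values, probs = c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

# Number of i.i.d. draws (with replacement) from `counts` needed for the
# cumulative sum to reach `target`. Draws by index so that increasing a
# count in the support, holding the RNG stream fixed, can never increase
# the number of days (the coupling used in the monotonicity tests).
draw_days_to_target <- function(counts, target) {
  if (all(counts == 0)) {
    abort("all daily counts are zero: target unreachable",
          class = "pmscost_validation_error")
  }
  block <- max(16L, ceiling(1.5 * target / mean(counts)))
  done <- 0
  remaining <- target
  repeat {
    idx <- sample.int(length(counts), block, replace = TRUE)
    cs <- cumsum(counts[idx])
    pos <- which(cs >= remaining)
    if (length(pos) > 0) return(done + pos[1])
    done <- done + block
    remaining <- remaining - cs[block]
  }
}

#' Bootstrap configuration for unit-cost estimation
#'
#' @param targets Named integer vector: target number of samples per
#'   stratum.
#' @param per_day_cost Named numeric vector: cost per fieldwork day per
#'   stratum (team, per-diems, transport while in the field).
#' @param fixed_cost Cost independent of fieldwork duration (setup,
#'   laboratory, reporting), default 0.
#' @param iterations Bootstrap iterations (default 500).
#' @param ci_level Confidence level for percentile intervals
#'   (default 0.95).
#' @param seed Integer seed; every bootstrap run with the same seed and
#'   inputs is bit-identical.
#' @param week_days Working days per fieldwork week (default 5).
#' @return An object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(targets, per_day_cost, fixed_cost = 0,
                             iterations = 500, ci_level = 0.95, seed = 1,
                             week_days = 5) {
  stopifnot(iterations >= 1, ci_level > 0, ci_level < 1,
            all(targets >= 1), fixed_cost >= 0, week_days >= 1)
  if (is.null(names(targets)) || is.null(names(per_day_cost))) {
    abort("targets and per_day_cost must be named by stratum",
          class = "pmscost_validation_error")
  }
  missing_s <- setdiff(names(targets), names(per_day_cost))
  if (length(missing_s) > 0) {
    abort(paste0("per_day_cost missing stratum: ",
                 paste(missing_s, collapse = ", ")),
          class = "pmscost_validation_error")
  }
  structure(list(targets = targets, per_day_cost = per_day_cost,
                 fixed_cost = fixed_cost, iterations = as.integer(iterations),
                 ci_level = ci_level, seed = as.integer(seed),
                 week_days = week_days),
            class = "bootstrap_config")
}

#' Bootstrap the number of fieldwork days needed to reach targets
#'
#' Resamples the observed daily collection counts with replacement,
#' independently per stratum, and records for each iteration the number
#' of days needed for the cumulative count to reach the stratum's target.
#' Each stratum draws from its own RNG stream, derived from the run seed
#' and the stratum name, so results for a stratum do not change when
#' another stratum is added or removed.
#'
#' @param log A [fieldwork_log()]; every stratum in `cfg$targets` needs
#'   at least one logged day with a positive count.
#' @param cfg A [bootstrap_config()].
#' @return A tibble with columns `iteration`, `stratum`, `days`.
#' @export
bootstrap_days_to_target <- function(log, cfg) {
  log <- fieldwork_log(log)
  stopifnot(inherits(cfg, "bootstrap_config"))
  strata <- sort(names(cfg$targets))
  res <- purrr::map(strata, function(s) {
    counts <- log$samples_collected[log$stratum == s]
    if (length(counts) == 0) {
      abort(paste0("no fieldwork log records for stratum: ", s),
            class = "pmscost_validation_error")
    }
    if (all(counts == 0)) {
      abort(paste0("all daily counts are zero in stratum ", s,
                   ": target unreachable"),
            class = "pmscost_validation_error")
    }
    # one RNG substream per (stratum, iteration): iterations are isolated,
    # so coupled comparisons across inputs stay aligned draw by draw
    s_seed <- stream_seed(cfg$seed, s)
    days <- vapply(seq_len(cfg$iterations), function(i) {
      with_seed_if((s_seed + 7919 * i) %% 2147483647,
                   draw_days_to_target(counts, cfg$targets[[s]]))
    }, numeric(1))
    tibble::tibble(iteration = seq_len(cfg$iterations), stratum = s,
                   days = days)
  })
  dplyr::bind_rows(res)
}

#' Bootstrap unit costs from fieldwork uncertainty
#'
#' Propagates the day-to-day variation in sample collection into unit
#' costs. For each bootstrap iteration the fieldwork cost is
#' `fixed_cost + sum over strata of days * per_day_cost`; the cost per
#' sample divides this by the total sample target, and the cost per
#' substandard sample divides again by the substandard prevalence.
#' Strata are costed independently (teams work in parallel); the calendar
#' fieldwork duration of an iteration is the maximum of the stratum day
#' counts, and per-day and per-week fieldwork costs exclude the fixed
#' (duration-independent) component. Point estimates are means over
#' iterations with percentile confidence intervals.
#'
#' @param log A [fieldwork_log()].
#' @param cfg A [bootstrap_config()].
#' @param prevalence A [crude_prevalence()] object or a number in
#'   `(0, 1]`.
#' @return A tibble of class `unit_cost_estimates` with columns
#'   `quantity`, `mean`, `ci_low`, `ci_high`, `iterations`, `seed`.
#' @export
bootstrap_unit_costs <- function(log, cfg, prevalence) {
  if (inherits(prevalence, "prevalence_estimate")) prevalence <- prevalence$p
  if (prevalence <= 0) {
    abort("no substandard detectable; unit cost undefined",
          class = "pmscost_validation_error")
  }
  days <- bootstrap_days_to_target(log, cfg)
  wide <- tidyr::pivot_wider(days, names_from = "stratum",
                             values_from = "days")
  strata <- sort(names(cfg$targets))
  day_mat <- as.matrix(wide[, strata, drop = FALSE])
  field_cost <- as.vector(day_mat %*% unname(cfg$per_day_cost[strata]))
  total_cost <- cfg$fixed_cost + field_cost
  n_samples <- sum(cfg$targets)
  duration <- apply(day_mat, 1, max)
  per_sample <- total_cost / n_samples
  per_sub <- per_sample / prevalence
  per_day <- field_cost / duration
  per_week <- per_day * cfg$week_days
  est <- function(label, v) {
    ci <- if (length(v) >= 2) percentile_ci(v, cfg$ci_level) else c(v, v)
    tibble::tibble(quantity = label, mean = mean(v),
                   ci_low = ci[[1]], ci_high = ci[[2]],
                   iterations = cfg$iterations, seed = cfg$seed)
  }
  out <- dplyr::bind_rows(
    est("per_sample", per_sample),
    est("per_substandard", per_sub),
    est("per_fieldwork_day", per_day),
    est("per_fieldwork_week", per_week)
  )
  structure(out, class = c("unit_cost_estimates", class(tibble::tibble())))
}

#' Cost per fieldwork day and week
#'
#' @param field_cost_total Total fieldwork cost (excluding laboratory
#'   costs, which accrue after fieldwork).
#' @param n_days Number of fieldwork days (>= 1).
#' @param week_days Working days per week (default 5).
#' @return Named numeric vector `c(per_day, per_week)`.
#' @export
#' @examples
#' cost_per_fieldwork_period(1866 * 54, 54) # 1866 per day, 9330 per week
cost_per_fieldwork_period <- function(field_cost_total, n_days,
                                      week_days = 5) {
  stopifnot(field_cost_total >= 0, week_days >= 1)
  if (n_days < 1) {
    abort("n_days must be at least 1", class = "pmscost_validation_error")
  }
  per_day <- field_cost_total / n_days
  c(per_day = per_day, per_week = per_day * week_days)
}
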