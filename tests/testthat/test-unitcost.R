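test_that("crude prevalence is the exact failure fraction", {
  prev <- crude_prevalence(105, 1274)
  expect_equal(prev$p, 105 / 1274)
  expect_equal(round(100 * prev$p, 1), 8.2)
  expect_equal(crude_prevalence(0, 100)$p, 0)
  expect_equal(crude_prevalence(100, 100)$p, 1)
  expect_error(crude_prevalence(101, 100), class = "pmscost_validation_error")
})

test_that("per-sample and per-substandard unit costs divide exactly", {
  expect_equal(round(as.numeric(cost_per_sample(481704, 1274))), 378)
  expect_equal(cost_per_sample(0, 10), 0, ignore_attr = TRUE)
  expect_equal(as.numeric(cost_per_sample(123.4, 1)), 123.4)
  expect_equal(attr(cost_per_sample(100, 10, scope = "excl_lab"), "scope"),
               "excl_lab")
  expect_error(cost_per_sample(100, 0), class = "pmscost_validation_error")

  expect_equal(round(cost_per_substandard(479, 105 / 1274)), 5812)
  expect_equal(cost_per_substandard(479, crude_prevalence(105, 1274)),
               479 * 1274 / 105)
  expect_equal(cost_per_substandard(42, 1), 42)
  expect_equal(round(cost_per_substandard(479, 0.044)), 10886)
  expect_error(cost_per_substandard(479, 0), "undefined",
               class = "pmscost_validation_error")
})

test_that("cost per substandard doubles exactly when prevalence halves", {
  for (p in c(0.5, 0.2, 0.082, 0.01)) {
    expect_equal(cost_per_substandard(479, p / 2),
                 2 * cost_per_substandard(479, p))
    expect_gt(cost_per_substandard(479, p / 2), cost_per_substandard(479, p))
  }
})

test_that("percentile intervals interpolate order statistics", {
  expect_equal(percentile_ci(1:1000, 0.95),
               c(low = 25.975, high = 975.025))
  expect_equal(percentile_ci(rep(3.7, 50)), c(low = 3.7, high = 3.7))
  x <- c(2, 9, 4, 1, 8, 5, 5, 3)
  ci <- percentile_ci(x, 1e-9)
  expect_equal(unname(ci[1]), median(x), tolerance = 1e-9)
  expect_equal(unname(ci[2]), median(x), tolerance = 1e-9)
  expect_error(percentile_ci(1), class = "pmscost_validation_error")
})

test_that("days to target matches closed forms for degenerate counts", {
  log <- make_log(list(urban = rep(5L, 4)))
  cfg <- bootstrap_config(targets = c(urban = 12),
                          per_day_cost = c(urban = 1), iterations = 50,
                          seed = 3)
  days <- bootstrap_days_to_target(log, cfg)
  expect_true(all(days$days == 3)) # ceil(12 / 5)

  cfg1 <- bootstrap_config(targets = c(urban = 1),
                           per_day_cost = c(urban = 1), iterations = 50,
                           seed = 3)
  log_pos <- make_log(list(urban = c(1L, 4L, 2L)))
  expect_true(all(bootstrap_days_to_target(log_pos, cfg1)$days == 1))

  zero <- make_log(list(urban = c(0L, 0L)))
  expect_error(bootstrap_days_to_target(zero, cfg1), "unreachable",
               class = "pmscost_validation_error")
})

test_that("bootstrap mean days agrees with the enumeration oracle", {
  cases <- list(
    list(counts = c(1L, 2L), target = 2),
    list(counts = c(1L, 2L, 3L), target = 6),
    list(counts = c(0L, 2L), target = 4),
    list(counts = c(1L, 1L, 4L), target = 5)
  )
  for (case in cases) {
    log <- make_log(list(urban = case$counts))
    cfg <- bootstrap_config(targets = c(urban = case$target),
                            per_day_cost = c(urban = 1),
                            iterations = 10000, seed = 11)
    days <- bootstrap_days_to_target(log, cfg)$days
    truth <- expected_days_exact(case$counts,
                                 rep(1 / length(case$counts),
                                     length(case$counts)),
                                 case$target)
    se <- sd(days) / sqrt(length(days))
    expect_lt(abs(mean(days) - truth), 3 * se + 1e-12)
  }
})

test_that("bootstrap is bit-identical under a fixed seed and stratum-stable", {
  log <- make_log(list(urban = c(3L, 5L, 2L), rural = c(1L, 2L)))
  cfg <- bootstrap_config(targets = c(urban = 20, rural = 10),
                          per_day_cost = c(urban = 100, rural = 80),
                          iterations = 200, seed = 99)
  d1 <- bootstrap_days_to_target(log, cfg)
  d2 <- bootstrap_days_to_target(log, cfg)
  expect_identical(d1, d2)

  # dropping a stratum leaves the other stratum's draws untouched
  cfg_u <- bootstrap_config(targets = c(urban = 20),
                            per_day_cost = c(urban = 100),
                            iterations = 200, seed = 99)
  d_u <- bootstrap_days_to_target(make_log(list(urban = c(3L, 5L, 2L))), cfg_u)
  expect_identical(d_u$days, d1$days[d1$stratum == "urban"])
})

test_that("days to target is monotone non-increasing in the count support", {
  base_counts <- c(2L, 3L, 1L)
  better_counts <- c(2L, 5L, 1L) # one support point increased
  cfg <- bootstrap_config(targets = c(urban = 30),
                          per_day_cost = c(urban = 1),
                          iterations = 500, seed = 17)
  d_base <- bootstrap_days_to_target(make_log(list(urban = base_counts)), cfg)
  d_best <- bootstrap_days_to_target(make_log(list(urban = better_counts)), cfg)
  # coupled seeds: identical index draws, pointwise larger counts
  expect_true(all(d_best$days <= d_base$days))
})

test_that("zero-variance logs give zero-width intervals", {
  log <- make_log(list(online = rep(4L, 5), urban = rep(10L, 5)))
  cfg <- bootstrap_config(targets = c(online = 40, urban = 100),
                          per_day_cost = c(online = 50, urban = 200),
                          fixed_cost = 1000, iterations = 300, seed = 5)
  est <- bootstrap_unit_costs(log, cfg, 0.1)
  expect_equal(est$ci_low, est$mean)
  expect_equal(est$ci_high, est$mean)
  # days are deterministic: 10 days each stratum
  expect_equal(est$mean[est$quantity == "per_sample"],
               (1000 + 10 * 50 + 10 * 200) / 140)
})

test_that("unit-cost estimates scale and relate as expected", {
  log <- make_log(list(urban = c(8L, 12L, 10L), rural = c(3L, 6L)))
  cfg <- bootstrap_config(targets = c(urban = 60, rural = 30),
                          per_day_cost = c(urban = 100, rural = 70),
                          fixed_cost = 0, iterations = 400, seed = 23)
  est <- bootstrap_unit_costs(log, cfg, 0.2)
  cfg2 <- cfg
  cfg2$per_day_cost <- cfg$per_day_cost * 2
  est2 <- bootstrap_unit_costs(log, cfg2, 0.2)
  expect_equal(est2$mean, est$mean * 2)
  expect_true(all(est$ci_low <= est$ci_high))

  # per-substandard is per-sample scaled by 1 / prevalence, row by row
  ps <- est$mean[est$quantity == "per_sample"]
  expect_equal(est$mean[est$quantity == "per_substandard"], ps / 0.2)
  # per-week is per-day scaled by the working week
  expect_equal(est$mean[est$quantity == "per_fieldwork_week"],
               est$mean[est$quantity == "per_fieldwork_day"] * 5)
})

test_that("per-period fieldwork costs divide and scale by the week", {
  expect_equal(cost_per_fieldwork_period(1866 * 54, 54),
               c(per_day = 1866, per_week = 9330))
  expect_equal(unname(cost_per_fieldwork_period(100, 10)[1]), 10)
  pp <- cost_per_fieldwork_period(500, 4, week_days = 1)
  expect_equal(unname(pp[1]), unname(pp[2]))
  expect_error(cost_per_fieldwork_period(100, 0),
               class = "pmscost_validation_error")
})
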