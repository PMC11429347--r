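cal_30_60_10 <- phase_calendar(list(
  preparation = c("2022-01-01", "2022-01-30"),
  data_collection = c("2022-01-31", "2022-03-31"),
  analysis_reporting = c("2022-04-01", "2022-04-10")
))

test_that("salary allocation is proportional to calendar days and exact", {
  alloc <- allocate_salary_by_calendar_days(1000, cal_30_60_10)
  expect_equal(unname(alloc), c(300, 600, 100))
  expect_equal(sum(alloc), 1000)

  one <- allocate_salary_by_calendar_days(1234.56, cal_30_60_10,
                                          phases = "data_collection")
  expect_equal(unname(one), 1234.56)

  eq_cal <- phase_calendar(list(preparation = c("2022-01-01", "2022-01-31"),
                                data_collection = c("2022-02-01", "2022-03-03")))
  expect_equal(unname(allocate_salary_by_calendar_days(500, eq_cal)),
               c(250, 250))

  # irregular totals still sum exactly (residual goes to the final phase)
  for (total in c(0.1, 7, 99.99, 123456.78)) {
    expect_identical(sum(allocate_salary_by_calendar_days(total, cal_30_60_10)),
                     total)
  }
  expect_error(allocate_salary_by_calendar_days(1, cal_30_60_10, phases = character()),
               class = "pmscost_validation_error")
})

test_that("phase calendars must be ordered, non-overlapping, non-empty", {
  expect_error(phase_calendar(list(preparation = c("2022-02-01", "2022-01-01"))),
               class = "pmscost_validation_error")
  expect_error(phase_calendar(list(
    preparation = c("2022-01-01", "2022-02-15"),
    data_collection = c("2022-02-10", "2022-03-01")
  )), class = "pmscost_validation_error")
  default_days <- phase_calendar()$days
  expect_equal(unname(default_days),
               c(365, 135, 86, 52))
})

test_that("overtime is valued at the full-time hourly rate", {
  # weekly gross of 400 => hourly rate 10 on a 40-hour week
  staff <- staff_member("research staff", "I",
                        base_salary = 400 * 52 / 12, allowance = 0)
  item <- value_overtime(staff, 10, "data_collection")
  expect_equal(item$amount, 100)
  expect_equal(item$cost_basis, "economic")
  expect_equal(item$category, "salaries")
  expect_equal(item$phase, "data_collection")
  expect_equal(value_overtime(staff, 0, "preparation")$amount, 0)

  # FTE is hours worked over hours in a full-time workweek
  half <- staff_member("assistant", "I", 100, hours_per_week = 20,
                       fulltime_week_hours = 40)
  expect_equal(half$fte, 0.5)
})

test_that("overheads are a flat rate on the base categories", {
  led <- make_ledger(c("salaries", "consumables", "travel", "other_direct"),
                     rep("preparation", 4), c(100, 200, 300, 400))
  oh <- apply_overhead(led, rate = 0.10)
  expect_equal(sum(oh$amount), 100)
  expect_true(all(oh$category == "indirect"))

  # the reference component subtotals: 10% of the stated base
  base <- make_ledger(c("salaries", "consumables", "travel", "other_direct"),
                      rep("data_collection", 4),
                      c(32503, 17747, 21660, 82734))
  expect_equal(sum(apply_overhead(base, rate = 0.10)$amount), 15464.40)

  expect_equal(sum(apply_overhead(led, rate = 0)$amount), 0)
})

test_that("overhead allocation follows phase base spend and is homogeneous", {
  led <- make_ledger(c("salaries", "travel", "laboratory", "other_direct"),
                     c("preparation", "data_collection", "analysis_reporting",
                       "data_collection"),
                     c(100, 300, 5000, 100))
  oh <- apply_overhead(led, rate = 0.10)
  # laboratory is outside the base: no overhead lands on analysis_reporting
  expect_setequal(oh$phase, c("preparation", "data_collection"))
  expect_equal(oh$amount[oh$phase == "preparation"], 10)
  expect_equal(oh$amount[oh$phase == "data_collection"], 40)
  expect_equal(sum(oh$amount), 50)

  scaled <- led; scaled$amount <- scaled$amount * 7
  expect_equal(sum(apply_overhead(scaled, rate = 0.10)$amount),
               7 * sum(oh$amount))

  with_ind <- make_ledger("indirect", "preparation", 5)
  expect_error(apply_overhead(with_ind), "mutually exclusive",
               class = "pmscost_validation_error")
  expect_error(apply_overhead(led, base_categories = character()),
               class = "pmscost_validation_error")
  expect_error(apply_overhead(led, base_categories = c("salaries", "indirect")),
               class = "pmscost_validation_error")
})

test_that("the summary conserves totals across both margins", {
  set.seed(7)
  for (i in 1:5) {
    n <- sample(3:25, 1)
    led <- make_ledger(sample(cost_categories(), n, replace = TRUE),
                       sample(study_phases(), n, replace = TRUE),
                       round(runif(n, 0, 5000), 2))
    s <- summarize_costs(led)
    expect_identical(sum(s$matrix), s$grand_total)
    expect_equal(sum(s$category_totals$amount), s$grand_total)
    expect_equal(sum(s$phase_totals$amount), s$grand_total)
    expect_equal(s$grand_total, sum(led$amount))
    expect_equal(sum(s$category_totals$share_pct), 100)
    expect_equal(sum(s$phase_totals$share_pct), 100)

    # scaling every amount scales every cell and leaves shares unchanged
    scaled <- led; scaled$amount <- scaled$amount * 3
    s3 <- summarize_costs(scaled)
    expect_equal(s3$matrix, s$matrix * 3)
    expect_equal(s3$category_totals$share_pct, s$category_totals$share_pct)
  }
})

test_that("the economic summary adds economic items on top of financial", {
  led <- dplyr::bind_rows(
    make_ledger(c("salaries", "laboratory"), c("preparation", "analysis_reporting"),
                c(1000, 5000)),
    {
      ot <- make_ledger("salaries", "data_collection", 250, basis = "economic")
      ot$item_id <- "ot1"; ot
    }
  )
  fin <- summarize_costs(led, "financial")
  eco <- summarize_costs(led, "economic")
  expect_equal(fin$grand_total, 6000)
  expect_equal(eco$grand_total, 6250)
  expect_gte(eco$grand_total_economic, fin$grand_total_financial)
  expect_equal(fin$grand_total_financial, eco$grand_total_financial)
})

test_that("degenerate and invalid summaries are handled", {
  empty <- make_ledger(character(), character(), numeric())
  s <- summarize_costs(empty)
  expect_equal(s$grand_total, 0)
  expect_true(all(s$matrix == 0))
  expect_true(all(s$category_totals$share_pct == 0))

  unalloc <- make_ledger("salaries", "unallocated", 10)
  err <- expect_error(summarize_costs(unalloc),
                      class = "pmscost_validation_error")
  expect_match(conditionMessage(err), "it1")

  gbp <- make_ledger("salaries", "preparation", 10)
  gbp$currency <- "GBP"
  expect_error(summarize_costs(gbp), "USD",
               class = "pmscost_validation_error")
})

test_that("summary files round-trip identically in CSV and JSON", {
  led <- read_ledger(example_ledger_path())
  s <- summarize_costs(led)
  csv_path <- withr::local_tempfile(fileext = ".csv")
  json_path <- withr::local_tempfile(fileext = ".json")
  write_summary(s, csv_path, "csv")
  write_summary(s, json_path, "json")
  from_csv <- read_summary(csv_path, "csv")
  from_json <- read_summary(json_path, "json")
  expect_equal(from_csv$amount_usd, from_json$amount_usd)
  expect_equal(from_csv$amount_usd[from_csv$name == "grand_total"],
               s$grand_total)
  expect_equal(from_csv$amount_usd[from_csv$block == "component"],
               s$category_totals$amount)

  empty <- summarize_costs(make_ledger(character(), character(), numeric()))
  write_summary(empty, csv_path, "csv")
  expect_equal(nrow(read_summary(csv_path)),
               nrow(pmscost:::summary_as_table(empty)))
})
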