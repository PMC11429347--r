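# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own code paths.

# Exact expected number of i.i.d. daily draws needed for the cumulative
# count to reach `target`, by dynamic programming over the remaining
# count: f(r) = 1 + sum_c p_c f(r - c), with f(r <= 0) = 0 and the
# zero-count mass solved out algebraically.
expected_days_exact <- function(support, probs, target) {
  stopifnot(abs(sum(probs) - 1) < 1e-12, any(support > 0))
  p0 <- sum(probs[support == 0])
  f <- numeric(target + 1)
  for (r in seq_len(target)) {
    acc <- 1
    for (i in seq_along(support)) {
      ci <- support[i]
      if (ci > 0) acc <- acc + probs[i] * f[max(r - ci, 0) + 1]
    }
    f[r + 1] <- acc / (1 - p0)
  }
  f[target + 1]
}

# Annualised capital cost found numerically: the annual payment A whose
# discounted n-year stream equals the purchase price.
eac_numeric <- function(price, n_years, rate) {
  if (price == 0) return(0)
  uniroot(function(a) sum(a / (1 + rate)^(seq_len(n_years))) - price,
          c(0, 2 * price), tol = 1e-12)$root
}

# Small fieldwork log with given per-stratum daily counts.
make_log <- function(counts_by_stratum) {
  dplyr::bind_rows(lapply(names(counts_by_stratum), function(s) {
    counts <- counts_by_stratum[[s]]
    tibble::tibble(date = as.Date("2022-02-13") + seq_along(counts) - 1,
                   stratum = s, samples_collected = counts)
  }))
}

# Minimal ledger builder for property tests.
make_ledger <- function(categories, phases, amounts,
                        basis = "financial", sub_category = "") {
  cost_ledger(tibble::tibble(
    item_id = paste0("it", seq_along(amounts)),
    description = "test item",
    category = categories,
    phase = phases,
    sub_category = sub_category,
    amount = amounts,
    currency = "USD",
    cost_basis = basis,
    date = as.Date(NA)
  ))
}
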