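---
title: "Costing medicine quality surveillance: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Costing medicine quality surveillance: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmscost)
```

## The problem

Post-market surveillance (PMS) of medicines — buying samples from retail
outlets and testing them against pharmacopeial specifications — is one of
the main tools regulators have against substandard and falsified
medicines. Deciding whether and how to run such an exercise requires
knowing what it costs: in total, per sample collected, and per
substandard sample detected. `pmscost` implements an activity-based
microcosting pipeline for exactly this kind of exercise: a field campaign
that collects on the order of a thousand samples from urban, rural and
online outlets, sends them to a contracted laboratory, and reports the
results.

The pipeline has four analytical stages, each a package module:

1. **Ledger** — ingest expenditure line items, convert currencies,
   annualise capital.
2. **Costing** — apply the cost-construction rules (salary allocation,
   overtime valuation, overheads) and aggregate into a component-by-phase
   summary with financial and economic totals.
3. **Unit costs** — compute prevalence and unit costs, and propagate
   uncertainty in daily collection counts into unit-cost confidence
   intervals with a stratified bootstrap.
4. **Scenarios** — one-way sensitivity analysis on medicine prices,
   preparation costs and prevalence.

A synthetic-data module generates ledgers, fieldwork logs and test
outcomes with the statistical structure the analysis assumes, so the
whole pipeline is testable without access to any study's raw records.

## Cost model

### Financial versus economic costs

Financial costs are expenditures found in accounting records. Economic
costs additionally value resources consumed without a financial
transaction — here, staff overtime (valued at the same hourly rate as
contracted time) and personally owned equipment (valued at the
annualised cost of a replacement purchase). Every ledger item carries a
`cost_basis` tag; the financial summary uses financial items only, and
the economic summary adds the economic items on top, so the economic
grand total can never be below the financial one.

### Components and phases

Costs are classified on two closed vocabularies: seven components
(salaries, equipment, consumables, travel, laboratory, other direct,
indirect) and four phases (study setup, preparation, data collection,
analysis and reporting). Analysts often describe such exercises in three
stages — design, fieldwork, analysis — but reporting uses four phases;
the four-phase vocabulary is canonical here, with "design" spanning
setup plus preparation. Aggregation is conservative by construction:
component totals, phase totals and the grand total are sums of the same
item set, so the two margins agree exactly before any rounding.
Percentage shares are computed pre-rounding and rounded half-up to whole
percent at reporting time, except shares below 1%, which are shown to
one decimal so small components do not print as zero.

### Salary allocation and overtime

Salaries (base plus allowance, from a civil-service-style grade scale)
are allocated to phases proportionally to the calendar days each phase
spans (`allocate_salary_by_calendar_days()`). Floating-point
proportional splits need not sum exactly to the total, so the final
phase receives the residual — a largest-remainder-style correction that
makes conservation exact. Overtime hours (outside 09:00–17:00) are
valued at weekly gross salary divided by the 40-hour full-time week and
become economic items in the salaries category
(`value_overtime()`).

### Overheads

Indirect costs are a flat rate — 10% by default — on the sum of
salaries, consumables, travel and other direct costs
(`apply_overhead()`). The overhead total is allocated across phases in
proportion to each phase's base-category spend, the choice that keeps
the component-by-phase matrix conservative and the whole operation
homogeneous of degree one in the base amounts. Two modes are supported
and mutually exclusive: `from_rule` generates overheads from the rate,
`from_ledger` ingests indirect rows recorded in the ledger as data. The
second mode exists because real reported indirect totals are routinely
negotiated figures that cannot be regenerated from any stated rate: the
bundled example ledger carries an indirect total of US\$51,200 against a
10%-rule value of US\$15,464.40, and the package deliberately does not
guess at a reconciliation. Replication runs should ingest the recorded
figure; prospective budgeting should use the rule.

### Capital annualisation

Published costing guidance for this kind of study states both
"straight-line" depreciation and a discount rate, which strictly
conflict: straight-line ignores discounting. The package adopts the
equivalent annual cost (EAC), the standard annualisation in
health-economic costing and the only reading that uses the stated rate:

$$A = \frac{P \, r}{1 - (1+r)^{-n}},$$

with purchase price $P$, discount rate $r$ (default 3%) and useful life
$n$ (default 5 years). As $r \to 0$ this tends to $P/n$; the
implementation computes the annuity factor via `expm1()`/`log1p()` so
the limit is numerically clean (error below $10^{-6} P$ already at
$r = 10^{-9}$), and a `straight_line` switch is exposed for analysts who
want the undiscounted convention. With the defaults, a US\$1000 laptop
costs US\$218.35 per year of service.

### Currency

All amounts are converted to USD with period-average rates supplied in
the run configuration. No default rates are hard-coded: annual-average
exchange rates are an analytical input, and baking any year's values
into code invites silent misuse. Rounding to whole dollars happens only
at reporting time (half-up); internally amounts stay at double
precision, which is exact for dollar-and-cent magnitudes in this range.
Given a one-year costing horizon, no discounting of cost streams is
applied anywhere.

## Unit costs and the bootstrap

The headline unit costs are:

- **cost per sample collected** — attributable cost divided by the
  number of samples collected; the numerator scope (`all`, `excl_lab`,
  `excl_indirect`) is recorded with the result;
- **cost per substandard sample detected** — cost per sample divided by
  the substandard prevalence $p$: at prevalence $p$, an expected $1/p$
  samples must be collected and tested per detection, which is why unit
  costs rise steeply as substandard medicines become rarer;
- **cost per fieldwork day / week** — fieldwork cost (excluding
  laboratory costs, which accrue afterwards) divided by fieldwork days,
  scaled by a 5-day week.

The uncertain quantity in such an exercise is how many days of fieldwork
are needed: daily collection counts vary with weather, stock-outs,
outlet responsiveness and other shocks. The bootstrap
(`bootstrap_days_to_target()`, 500 iterations by default) resamples the
observed daily counts with replacement, independently within each outlet
stratum, and records for each iteration the number of days until the
cumulative count reaches the stratum's target. Fieldwork cost for an
iteration is then `fixed_cost + sum(days_s * per_day_cost_s)`, and unit
costs follow by division. Point estimates are means over iterations with
95% percentile confidence intervals.

Numerical conventions, chosen once and documented:

- **Quantiles.** "Percentile method" is ambiguous across software; the
  package uses linear interpolation between order statistics at position
  $h = (n-1)q + 1$ (R's type 7, the most common default).
- **Stratum independence.** Strata are resampled and costed
  independently — field teams operate in parallel — and the calendar
  duration of an iteration is the maximum of the stratum day counts.
- **Reproducibility.** Each (stratum, iteration) pair draws from its own
  RNG substream derived from the run seed and the stratum name. Two
  consequences: adding or removing a stratum never perturbs the draws of
  the others, and comparisons across perturbed inputs under the same
  seed are coupled draw-by-draw, which is what makes the stochastic-
  dominance property (days to target never increases when a daily count
  in the support increases) exactly testable rather than only true in
  expectation.
- **Degenerate inputs.** A stratum whose logged counts are all zero
  makes the target unreachable and errors; a zero-variance log yields
  exactly zero-width intervals; prevalence zero makes the
  per-substandard cost undefined and errors with a clear message.

Iterations default to 500, which puts Monte-Carlo error on the mean well
below the spread the interval reports. The oracle tests raise this to
10,000 where extra power is needed to compare against exact enumeration.

## Sensitivity scenarios

`run_one_way()` runs a list of scenarios against a base case, holding
everything else constant: the same fieldwork log, the same seed (so
differences between rows reflect the perturbation only), and the base
prevalence unless overridden. The three canonical scenarios are medicine
prices times ten (applied only to items tagged
`sub_category = "medicine_purchase"`), preparation costs halved (applied
to every item in the preparation phase), and prevalence set to 20% with
laboratory cost per sample held constant. A `scenario()` may perturb at
most one input — one-way discipline is enforced at construction. Ledger
perturbations enter the bootstrap through the duration-independent fixed
cost, shifted by the scenario's change in ledger total, so the exact
identities hold: the medicine scenario changes total cost by exactly
$(\text{multiplier} - 1)$ times medicine spend, and the
prevalence-scenario per-substandard estimate times the override equals
the base per-sample estimate.

## Time and motion

Workload indicators from time-and-motion records answer the planning
question "how long would this activity take without overtime?". If an
activity ran $w$ weeks at $h$ total hours per week of which $o$ were
overtime, delivering the same hours at regular time takes
$w \, h / (h - o)$ weeks — total hours are conserved, which is the
tested invariant. The published indicator tables this module mirrors
cannot be regenerated from stated per-day overtime assumptions alone, so
overtime hours per week are an explicit input rather than a derived
quantity: testability over speculation. `to_overtime_records()` folds
activity-level overtime into per-phase hours for economic valuation.

## The synthetic-data generator

The generator's defaults pin the shape of the reference exercise: three
outlet strata with collection targets 600 (urban), 406 (rural) and 327
(online), totalling 1333 samples; 1274 samples tested; true substandard
prevalence 105/1274; and a ledger template whose component and phase
margins reproduce the published US\$690,523 breakdown. Daily counts are
drawn from a zero-inflated negative binomial — negative binomial rather
than Poisson because field shocks (weather, stock-outs, road closures)
overdisperse counts, with an optional extra zero-day mass for days lost
entirely. Where the underlying studies publish no value, defaults were
chosen once as field-realistic: daily means of 12/8/6 samples for
urban/rural/online (physical outlets cluster; online purchases trickle),
dispersion $k = 5$ (variance roughly double the mean at these levels),
and a 5% zero-day probability. The true day-to-day count distribution of
any real campaign is unknown; these are stand-ins with the right
qualitative structure, never replication targets.

What passing tests on synthetic data do show: the aggregation arithmetic
is conservative, the bootstrap mean days agree with exact enumeration,
percentile intervals attain close-to-nominal coverage in the regime
where a campaign just reaches its target, and known generator parameters
(prevalence, daily-count mean) are recovered within stated Monte-Carlo
tolerances. What they do not show: anything about the actual count
distribution, cost structure or operational frictions of a particular
real campaign.

## Problem sizes used in the test suite

The suite runs the enumeration-oracle comparisons at 10,000 bootstrap
iterations on count supports of size at most three and targets at most
six (where exhaustive dynamic programming is exact and fast); interval
coverage at 500 synthetic replicates of a 40-day log with 500 bootstrap
iterations each; and parameter-recovery checks at 200–300 replicates.
These sizes put Monte-Carlo error comfortably inside the asserted
tolerances while keeping a full run under a minute of CPU for the heavy
blocks.

## Known limitations

- Published unit-cost confidence intervals from any specific study
  cannot be reproduced without that study's daily collection counts;
  property-based tests substitute for value replication.
- The mean cost per collected sample of the reference exercise
  (US\$479) is not re-derivable from its printed aggregates; functions
  that need it take it as an explicit input.
- The economic/financial gap of the reference exercise's abstract total
  is not itemised in the available material; the package produces an
  economic total from tagged economic items but does not target that
  printed value.
- Market-size adjustment of prevalence is out of scope; an adjusted
  prevalence, where available, is consumed as an input.
- No payroll-tax modelling beyond a flat allowance, and no multi-year
  discounting of cost streams (the costing horizon is one year).
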