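#' Path to the bundled example ledger
#'
#' A small cost ledger shipped with the package whose category and phase
#' subtotals reproduce the published breakdown of a large
#' medicine-quality surveillance exercise in Indonesia (grand total
#' US$690,523; laboratory 70%, other direct 12%, indirect 7%; analysis
#' and reporting 72% by phase). Only the margins of that breakdown are
#' published, so the allocation of each component across phases within
#' the file is a constructed, synthetic split (hence the filename); it is
#' useful for examples and for checking the aggregation arithmetic.
#'
#' @return Path to `surveillance_ledger_synthetic.csv`.
#' @export
#' @examples
#' led <- read_ledger(example_ledger_path())
#' summarize_costs(led)
example_ledger_path <- function() {
  system.file("extdata", "surveillance_ledger_synthetic.csv",
              package = "pmscost", mustWork = TRUE)
}
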