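#' Run the full signal-detection pipeline on a report set
#'
#' Convenience driver chaining the pipeline stages in their fixed order:
#' drug-name standardization, deduplication, event partition, reporter
#' filter and drug eligibility, contingency tables, the four
#' disproportionality statistics with joint classification, and signal
#' ranking.
#'
#' @param rs a `report_set` from [join_records()], or a
#'   `synthetic_universe` (its tables are joined first).
#' @param config a [filter_config()].
#' @param synonym_map optional synonym table for
#'   [standardize_drug_names()].
#' @param priors,chi2_variant,criteria,ic_mode passed to
#'   [signal_table()].
#' @return list with `cases` (filtered `case_set`), `eligible_drugs`,
#'   `tables`, `signals` (full data.frame) and `ranked` (joint-positive
#'   subset).
#' @export
run_signal_pipeline <- function(rs, config, synonym_map = NULL,
                                priors = bcpnn_priors(),
                                chi2_variant = "yates",
                                criteria = signal_criteria(),
                                ic_mode = "crude") {
  if (inherits(rs, "synthetic_universe")) rs <- join_records(rs$tables)
  if (!is.null(synonym_map)) rs <- standardize_drug_names(rs, synonym_map)
  cs <- deduplicate(rs)
  cs <- select_event_cases(cs, config)
  flt <- apply_report_filters(cs, config)
  tables <- build_all_tables(flt$cases, flt$eligible_drugs, config)
  signals <- signal_table(tables, priors = priors,
                          chi2_variant = chi2_variant,
                          criteria = criteria, ic_mode = ic_mode)
  list(cases = flt$cases, eligible_drugs = flt$eligible_drugs,
       tables = tables, signals = signals, ranked = rank_signals(signals))
}
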