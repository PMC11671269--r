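#!/usr/bin/env Rscript
# Step 2: ingest the quarterly files and build the analysis universe.
#
# Reads the "$"-delimited tables written by 01_simulate.R, joins them
# into reports, standardizes drug names, deduplicates to unique cases
# under the FDA rule, partitions by the RVO Preferred Term (10038907),
# restricts to healthcare-professional reporters and determines drug
# eligibility (>= 3 event cases as primary suspect). Writes the joined
# case table (one row per report-drug-reaction) and a provenance
# summary.

suppressPackageStartupMessages(library(rvosignal))

qdir <- file.path("results", "synthetic_quarter")
paths <- list.files(qdir, pattern = "\\.txt$", full.names = TRUE)
stopifnot(length(paths) == 4L)

q <- read_quarter(paths)
rs <- join_records(q)
spec <- desk_spec(seed = 20260101L)
rs <- standardize_drug_names(rs, synth_synonym_map(spec))

cfg <- filter_config(target_pts = "10038907")
cs <- select_event_cases(deduplicate(rs), cfg)
flt <- apply_report_filters(cs, cfg)

cat("reports read:", nrow(rs$demo), " unique cases:", nrow(cs$demo), "\n")
cat("event cases (pre reporter filter):", sum(cs$demo$is_event), "\n")
cat("universe after reporter filter:", nrow(flt$cases$demo),
    " event cases:", sum(flt$cases$demo$is_event), "\n")
cat("eligible drugs (>= 3 event cases):", length(flt$eligible_drugs), "\n")
print(flt$cases)

# one row per (report, drug, reaction) for downstream inspection
joined <- merge(merge(flt$cases$demo, flt$cases$drug, by = "primaryid",
                      suffixes = c("", ".drug")),
                flt$cases$reac, by = "primaryid", suffixes = c("", ".reac"))
utils::write.csv(joined, file.path("results", "joined_cases.csv"),
                 row.names = FALSE)
jsonlite::write_json(
  list(counters = rs$counters, provenance = flt$cases$provenance,
       eligible_drugs = flt$eligible_drugs),
  file.path("results", "ingest_summary.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/joined_cases.csv and results/ingest_summary.json\n")
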