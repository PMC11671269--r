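#!/usr/bin/env Rscript
# Step 1: simulate a desk-scale spontaneous-report universe.
#
# Draws the default desk study conditions — 50,000 unique cases, the 25
# established RVO-risk drugs planted with reporting-rate lifts graded
# from 4 to 80 over 15 null background drugs, baseline event probability
# 0.005, 30% duplicated cases, 20% missing therapy-start dates — and
# writes it as FAERS-dialect quarterly ASCII tables plus the generator's
# ground truth.

suppressPackageStartupMessages(library(rvosignal))

seed <- 20260101L
out_dir <- file.path("results", "synthetic_quarter")

spec <- desk_spec(seed = seed)
u <- synth_generate(spec)

paths <- write_quarter(u$tables, out_dir, quarter = "23Q1")
utils::write.csv(u$truth$cases, file.path("results", "ground_truth_cases.csv"),
                 row.names = FALSE)
utils::write.csv(tables_to_df(ground_truth_tables(u$truth)),
                 file.path("results", "ground_truth_tables.csv"),
                 row.names = FALSE)

cat("simulated", u$truth$n_cases, "unique cases emitted as",
    u$truth$n_reports, "reports (", u$truth$n_duplicates, "duplicates )\n")
cat("target-event cases:", sum(u$truth$cases$is_event), "\n")
cat("missing therapy-start dates:", u$truth$n_missing_start, "\n")
cat("wrote:", paste(basename(paths), collapse = ", "), "->", out_dir, "\n")
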