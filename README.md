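# rvosignal

Pharmacovigilance signal detection for **drug-induced retinal vein
occlusion (RVO)** in spontaneous adverse-event reports with the
structure of the FDA Adverse Event Reporting System (FAERS).

RVO is a vision-threatening retinal vascular event that occasionally
appears as a drug adverse reaction. For clinicians and drug-safety
scientists who want to screen a reporting database for culprit drugs,
`rvosignal` implements the complete chain: quarterly ASCII-file
ingestion, FDA-rule case deduplication, case selection by MedDRA
Preferred Term (PT 10038907), per-drug 2×2 contingency tables, four
disproportionality statistics with joint positivity criteria and risk
tiers, and time-to-onset analysis — plus a synthetic-report generator
with exact ground truth so the whole pipeline is testable without
access to the real database.

## The statistics

For each drug, the universe of unique cases is cross-classified into
the four-grid table (a = drug ∧ event, b = drug ∧ other events,
c = other drugs ∧ event, d = the rest; N = a+b+c+d), and four
established algorithms are computed:

| method | statistic | positive signal |
|---|---|---|
| ROR | ad/bc, 95% CI = exp(log ROR ± 1.96·√(1/a+1/b+1/c+1/d)) | a ≥ 3 and CI lower > 1 |
| PRR | [a/(a+b)]/[c/(c+d)], Wald CI, Yates χ² | a ≥ 3 and CI lower > 1 |
| BCPNN | IC = log₂[aN/((a+b)(a+c))]; prior-based E(IC), V(IC), IC025 = E(IC) − 2√V(IC) | IC025 > 0 |
| MGPS (crude) | EBGM = aN/((a+c)(a+b)); EBGM05 = exp(log EBGM − 1.64·√(1/a+1/b+1/c+1/d)) | EBGM05 > 2 and a > 0 |

A drug is a **joint signal** when all four criteria hold; risk tiers
cut IC025 at 0 / 1.5 / 3 (none/low/medium/high). Onset times (days from
therapy start to event) are summarized per drug and ATC class by
median/quartiles, Kaplan–Meier curves and the log-rank test. See the
methods vignette (`vignettes/disproportionality-methods.Rmd`) for
conventions, priors and design decisions.

## Worked example

Simulate a desk-scale universe (50,000 unique cases, 25 planted
RVO-risk drugs over null background drugs, 30% duplicate reports),
run the pipeline, and rank the signals:

```r
library(rvosignal)

spec <- desk_spec(seed = 20260101)
u    <- synth_generate(spec)
cfg  <- filter_config(target_pts = "10038907")
res  <- run_signal_pipeline(u, cfg, synonym_map = synth_synonym_map(spec))

print(res$cases)
#> <case_set> 33972 unique cases, 448 event cases
#>   provenance:
#>     deduplicate        kept=50000 removed=15000
#>     event_partition    kept=50000 removed=0
#>     reporter_filter    kept=33972 removed=16028
#>     drug_eligibility   kept=37 removed=1

head(res$ranked[, c("drug", "a", "ror", "prr", "ebgm05", "ic_025", "tier")], 5)
#>          drug  a    ror    prr ebgm05 ic_025   tier
#> 1  mirabegron 53 54.721 33.631 22.038  3.788   high
#> 2  raloxifene 45 38.086 26.416 17.563  3.479   high
#> 3   tadalafil 25 18.992 15.505 10.110  2.624 medium
#> 4 brimonidine 17 12.318 10.767  6.726  2.023 medium
#> 5 anastrozole 17 11.459 10.112  6.331  1.970 medium
```

Reading the output: 15,000 duplicate transmissions were removed by the
FDA dedup rule; the analysis universe is the 33,972 professional-
reported cases, 448 of them RVO cases; 37 drugs reached the three-case
threshold. The strongest planted signals (mirabegron, raloxifene) are
recovered at the top of the ranking with high IC025 tiers — matching
their planted lifts of 80 and 67. Time to onset, per drug class:

```r
onsets <- compute_onsets(res$cases, res$ranked$drug, cfg,
                         class_map = rvo_class_map())
logrank_test(onsets, by = "class")
#> $statistic  29.33   $df  4   $p_value  6.69e-06
```

the log-rank test detects the planted class differences in onset time
(ophthalmic-type drugs slowest, musculoskeletal fastest).

The same steps, narrated and writing all result tables under
`results/`, are in the numbered scripts `analysis/01_simulate.R` …
`analysis/05_report.R`.

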