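---
title: "Disproportionality signal detection for drug-induced retinal vein occlusion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Retinal vein occlusion (RVO) is a vision-threatening vascular event that
occasionally appears as a drug adverse reaction. Spontaneous reporting
systems such as FAERS collect millions of adverse-event reports, and
*disproportionality analysis* asks, for each drug, whether RVO is
reported disproportionately often with that drug compared with the rest
of the database. `rvosignal` implements the full chain from raw
quarterly ASCII files to a ranked signal table and time-to-onset
summaries, together with a synthetic-report generator so that every
stage can be validated against known ground truth.

The pipeline has a fixed stage order, and the provenance of every
discarded record is counted, never silently dropped:

1. ingest `"$"`-delimited DEMO/DRUG/REAC/THER tables (`read_quarter()`,
   `join_records()`);
2. standardize verbatim drug names against a synonym table
   (`standardize_drug_names()`);
3. deduplicate reports into unique cases (`deduplicate()`);
4. partition cases by the target MedDRA Preferred Term
   (`select_event_cases()`, default PT 10038907 = retinal vein
   occlusion);
5. restrict the universe to healthcare-professional reporters and
   determine drug eligibility (`apply_report_filters()`);
6. build per-drug 2×2 tables (`build_all_tables()`) and compute the four
   statistics with joint classification (`signal_table()`);
7. summarize time to onset (`compute_onsets()`, `onset_summary()`,
   `km_estimate()`, `logrank_test()`).

## Deduplication

FDA guidance for working with FAERS is to treat reports sharing a
CASEID as transmissions of one case and to keep the most recent one:
sort by CASEID and FDA date, keep the latest FDA date, and break ties
with the numerically highest PRIMARYID. `deduplicate()` implements
exactly this rule. FAERS dates may be partial (year, year–month, or
full), so dates within a case are compared *at the coarsest precision
present in the case*: a year-only date ties with — and never beats — a
full date of the same year, and the PRIMARYID rule then decides. A
report with no parseable FDA date is treated as earliest possible and
survives only when the case has no dated sibling. This makes the
operation idempotent and invariant under permutation of the input,
which the test suite asserts.

## The four-grid table

For each drug the universe of unique cases is cross-classified as

|              | target event | other events |
|--------------|--------------|--------------|
| target drug  | a            | b            |
| other drugs  | c            | d            |

Counting conventions, chosen once:

* the counting unit is the **deduplicated case**, not the raw report;
* a case exposed to several suspect drugs contributes to each drug's
  table, once per drug (so the sum of `a` across drugs may exceed the
  event-case total — standard disproportionality practice);
* exposure means the drug occurs in a kept role (default: primary
  suspect only);
* the denominator universe for `b`, `c`, `d` is the deduplicated,
  reporter-filtered case set. Published FAERS analyses are often
  ambiguous about whether the comparator is the full database or the
  filtered extract; we default to the filtered universe because it
  matches the stated focus on professional-reported, primary-suspect
  cases, and `filter_config(universe = "all")` switches to the
  unrestricted one.

"Healthcare professional" is taken as FAERS occupation codes MD, PH and
OT. Reports name physicians and pharmacists as the professional
sources, but FAERS carries a third professional code (other health
professional), which we include by default; the set is configurable.

## The four statistics

All four are computed from the same table (`signal_table()`), and an
independently written naive implementation of every formula is kept in
the test suite as an oracle; the two agree to 12 significant digits on
randomized tables.

* **ROR** `= ad/bc`, with `SE(log ROR) = sqrt(1/a + 1/b + 1/c + 1/d)`
  and 95% Wald bounds `exp(log ROR ± 1.96 SE)`. The interval is
  log-symmetric: `upper = ROR² / lower`, an identity the package also
  exposes (`wald_upper()`) for reconstructing published tables.
* **PRR** `= [a/(a+b)] / [c/(c+d)]` with
  `SE = sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d))` and Wald bounds as above.
  The accompanying χ² statistic is Yates-corrected by default —
  published tables rarely name the variant, and Yates is the common
  pharmacovigilance convention for sparse 2×2 tables — with plain
  Pearson available via `chi2_variant = "pearson"`.
* **BCPNN information component.** The crude IC is
  `log2[aN / ((a+b)(a+c))]`. The prior-based quantities use the
  standard vague Dirichlet priors (`bcpnn_priors()`: α₁ = β₁ = γ₁₁ = 1,
  α = β = 2, with the joint prior total γ chosen so that the prior IC
  expectation is centred at zero); `E(IC)`, `V(IC)` and
  `IC025 = E(IC) − 2√V(IC)` follow the standard closed forms. The
  headline IC defaults to the crude value because that is what
  published signal tables print (their IC column equals log2 of their
  EBGM column — an identity the acceptance checks verify), while the
  signal flag and risk tier always use the prior-based `IC025`. As the
  cells scale up proportionally, `E(IC) → IC` and `V(IC) → 0`; the
  tests assert this at scale factors 10² and 10⁴.
* **Crude EBGM** `= aN / ((a+c)(a+b))` — the observed-to-expected
  relative reporting ratio — with one-sided lower bound
  `EBGM05 = exp(log EBGM − 1.64 sqrt(1/a+1/b+1/c+1/d))`. The full
  DuMouchel gamma-Poisson mixture fit is intentionally not implemented:
  the crude ratio is what the reference tables print and what this
  pipeline reports. A mixture fit can be slotted in behind
  `ebgm_stats()` without touching the rest of the pipeline.

Algebraically `ROR ≥ PRR ≥ EBGM` whenever `ad ≥ bc` (with equality
exactly at independence), and the reverse ordering below independence;
the suite asserts this on 10,000 random tables.

A note on published IC intervals: across reference tables the printed
`IC − IC025` gap is often constant in `a`, which no variance expression
of the standard BCPNN form can produce. The package computes `IC025`
from the stated variance formula and does not attempt to imitate such
printed bounds.

**Zero cells.** When any of `b`, `c`, `d` is zero the Wald formulas are
kept finite by the Haldane correction (+0.5 to all four cells), applied
per statistic and flagged in the output so corrected rows can be
excluded from analyses that need exact cells. The χ² statistic is
computed on the uncorrected cells.

**Positivity and tiers.** The joint signal criterion is the conjunction
of: ROR with `a ≥ 3` and CI lower bound > 1; PRR likewise; BCPNN with
`IC025 > 0`; and EBGM05 > 2 with `a > 0`. Risk tiers cut `IC025` at 0,
1.5 and 3 (none/low/medium/high). Ranking is by descending `IC025`,
ties broken by ROR then name — deterministic for any input order. No
multiplicity correction is applied across drugs, matching field
practice for hypothesis-generating signal screens.

**Rounding.** Report-style output (`format_signal_table()`) rounds
half-up at 3 decimals, the convention of published signal tables, not
R's banker's rounding.

## Time to onset

Onset is `event date − therapy start` in days, per event case and
suspect drug. Spontaneous reports have no follow-up, so there is no
censoring: every sample is an observed event, and the product-limit
estimator coincides with the empirical survival function (asserted
exactly in the tests). The KM machinery is still used so that medians
and curves follow standard survival conventions. Choices:

* dates at less than day precision are excluded by default and counted;
  `impute_month = TRUE` places year–month dates at day 15 (exclusion is
  the conservative default because mid-month imputation can manufacture
  negative onsets);
* negative differences (event before therapy start) are excluded and
  counted separately;
* quartiles interpolate at position `1 + (n−1)p` (R's type-7 default);
* class-level summaries pool per-case onsets within the class and apply
  the same convention, rather than aggregating per-drug medians —
  published per-class figures with decimal days are not always explicit
  about which of the two they use, and we document ours instead of
  imitating theirs;
* group differences use the k-group log-rank test on a χ² reference
  with k−1 degrees of freedom; a fully degenerate design (identical
  single event time everywhere) is reported as statistic 0, p = 1.

## The synthetic generator

`synthetic_spec()`/`synth_generate()` define the study conditions under
which the pipeline is validated. Per case: one primary-suspect drug
from the exposure margins; target-event occurrence with probability
`min(1, lift × p0)`; 1–3 filler reaction PTs; sex/age/weight/country/
outcome and reporter occupation from fixed mixes chosen to resemble the
demographics of published RVO case series (mean age ≈ 59, ≈ 51% female,
≈ 74% "other serious" outcomes, ≈ 47% physician reporters); therapy
start uniform over 2004–2023; onset drawn from a per-drug distribution
(exponential by default, lognormal and Weibull available), rounded to
whole days and floored at 1 day to match FAERS day precision; a
configurable fraction of cases retransmitted as duplicates sharing the
CASEID with a perturbed PRIMARYID and an earlier FDA date; and a
configurable fraction of missing therapy-start dates. The generator
returns exact ground truth (per-case assignments, per-drug cells after
ideal dedup, planted missing-date counts), and `ground_truth_tables()`
is the oracle against which the pipeline's tables are compared — they
must agree exactly once duplicates are removed.

The bundled **desk conditions** (`desk_spec()`) are 50,000 cases, the
25 established RVO-risk drugs planted at lifts graded 4–80 (tracking
the rank order of their published signal strengths) over 15 null
background drugs, baseline event probability `p0 = 0.005`, 30%
duplication and 20% missing therapy-start dates. These sizes keep a
full pipeline run around a second while leaving expected per-drug event
counts comfortably above one, so calibration studies over hundreds of
replicates are routine. `paper_spec()` scales the same construction to
1.5 million cases and 205 drugs for one-off power studies. Replicate
counts used by the validation suite — 200 null universes for
calibration of the joint criterion, 100 replicates for ROR coverage of
a strongly planted drug (lift 50, exposure 1%), 1,000 and 10,000 random
tables for the oracle and ordering checks — are the package's standard
problem sizes.

What the generator deliberately does **not** emulate: masking and
competition bias (a strong signal suppressing others' expected counts),
stimulated-reporting waves after publicity, real co-prescription
structure, content drift between duplicate transmissions of a case, and
indication-driven channelling. Passing the synthetic suites therefore
demonstrates correctness of the computational chain and calibration
under clean reporting assumptions — not robustness to the biases of
real spontaneous data.

## Known limitations

* Wald intervals are first-order; for very small `a` exact or
  profile-likelihood intervals would be wider.
* The crude EBGM does not shrink; with the full mixture fit small-count
  signals would be pulled towards 1.
* Stratified (age/sex/year) tables and SMQ-based multi-PT event
  definitions beyond a PT list are out of scope.
* Name standardization is exact-match against a synonym table; no fuzzy
  matching.
* The bundled class map covers the 25 established RVO-risk drugs only;
  other drugs require a user-supplied map.
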