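Package: rvosignal
Title: Disproportionality Signal Detection for Drug-Induced Retinal Vein
    Occlusion in Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance pipeline for detecting drug
    safety signals for retinal vein occlusion (RVO) in spontaneous
    reporting data with the structure of the FDA Adverse Event Reporting
    System (FAERS). Reads "$"-delimited quarterly ASCII tables (DEMO,
    DRUG, REAC, THER), deduplicates reports into unique cases under the
    FDA rule (latest FDA date, then highest PRIMARYID per case),
    selects cases by MedDRA Preferred Term, builds per-drug 2x2
    contingency tables, and computes four disproportionality statistics
    (reporting odds ratio, proportional reporting ratio with chi-square,
    Bayesian confidence propagation neural network information
    component, and a crude gamma-Poisson EBGM) with joint positivity
    criteria and information-component risk tiers. Time to onset is
    summarized per drug and drug class by median and quartiles,
    Kaplan-Meier curves, and log-rank tests. A synthetic-report
    generator with known ground truth supports calibration and power
    evaluation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
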