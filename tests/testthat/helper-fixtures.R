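# Small in-code builders for FAERS-dialect fixtures.

mk_demo <- function(primaryid, caseid = primaryid, fda_dt = "20230101",
                    event_dt = "", age = "60", sex = "F", wt = "70",
                    occp_cod = "MD", occr_country = "US", outc_cod = "OT") {
  data.frame(primaryid = as.character(primaryid),
             caseid = as.character(caseid),
             fda_dt = fda_dt, event_dt = event_dt, age = age, sex = sex,
             wt = wt, occp_cod = occp_cod, occr_country = occr_country,
             outc_cod = outc_cod, stringsAsFactors = FALSE)
}

mk_drug <- function(primaryid, drugname, caseid = primaryid,
                    drug_seq = "1", role_cod = "PS") {
  data.frame(primaryid = as.character(primaryid),
             caseid = as.character(caseid),
             drug_seq = as.character(drug_seq), role_cod = role_cod,
             drugname = drugname, stringsAsFactors = FALSE)
}

mk_reac <- function(primaryid, pt, caseid = primaryid) {
  data.frame(primaryid = as.character(primaryid),
             caseid = as.character(caseid),
             pt = as.character(pt), stringsAsFactors = FALSE)
}

mk_ther <- function(primaryid, start_dt, caseid = primaryid,
                    dsg_drug_seq = "1") {
  data.frame(primaryid = as.character(primaryid),
             caseid = as.character(caseid),
             dsg_drug_seq = as.character(dsg_drug_seq),
             start_dt = start_dt, stringsAsFactors = FALSE)
}

mk_rs <- function(demo, drug, reac = NULL, ther = NULL) {
  join_records(list(DEMO = demo, DRUG = drug, REAC = reac, THER = ther))
}

rvo_config <- function(...) filter_config(target_pts = "10038907", ...)

# random strictly-positive 2x2 tables for property tests
rand_tables <- function(n, seed = 1L) {
  set.seed(seed)
  data.frame(a = sample(1:60, n, replace = TRUE),
             b = sample(1:800, n, replace = TRUE),
             c = sample(1:800, n, replace = TRUE),
             d = sample(500:200000, n, replace = TRUE))
}
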