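test_that("dedup keeps the latest FDA date, then the highest primaryid", {
  rs <- mk_rs(
    demo = rbind(mk_demo("11111111", caseid = "1", fda_dt = "20230101"),
                 mk_demo("22222222", caseid = "1", fda_dt = "20230601"),
                 mk_demo("33333331", caseid = "2", fda_dt = "20230301"),
                 mk_demo("33333339", caseid = "2", fda_dt = "20230301")),
    drug = mk_drug("22222222", "DRUG A", caseid = "1")
  )
  cs <- deduplicate(rs)
  expect_equal(cs$demo$primaryid, c("22222222", "33333339"))
  expect_equal(cs$provenance$removed[cs$provenance$stage == "deduplicate"], 2L)
})

test_that("distinct cases all survive dedup", {
  demo <- do.call(rbind, lapply(1:10, function(i)
    mk_demo(as.character(100 + i), caseid = as.character(i))))
  cs <- deduplicate(mk_rs(demo, mk_drug("101", "X", caseid = "1")))
  expect_equal(nrow(cs$demo), 10L)
})

test_that("an undated report survives only without a dated sibling", {
  rs <- mk_rs(
    demo = rbind(mk_demo("11", caseid = "1", fda_dt = ""),
                 mk_demo("10", caseid = "1", fda_dt = "20200101"),
                 mk_demo("20", caseid = "2", fda_dt = "")),
    drug = mk_drug("10", "X", caseid = "1")
  )
  cs <- deduplicate(rs)
  expect_equal(cs$demo$primaryid, c("10", "20"))
})

test_that("a year-only date ties with a full date in the same year", {
  # the tie falls through to the primaryid rule rather than treating
  # the full date as later
  rs <- mk_rs(
    demo = rbind(mk_demo("99", caseid = "1", fda_dt = "2023"),
                 mk_demo("10", caseid = "1", fda_dt = "20230615")),
    drug = mk_drug("99", "X", caseid = "1")
  )
  cs <- deduplicate(rs)
  expect_equal(cs$demo$primaryid, "99")
})

test_that("dedup is idempotent and order-invariant", {
  spec <- desk_spec(seed = 3)
  spec$n_cases <- 800L
  u <- synth_generate(spec, seed = 3)
  rs <- join_records(u$tables)
  cs1 <- deduplicate(rs)
  cs2 <- deduplicate(cs1)
  expect_equal(cs1$demo, cs2$demo)
  set.seed(42)
  perm <- sample(nrow(rs$demo))
  rs_perm <- rs
  rs_perm$demo <- rs$demo[perm, , drop = FALSE]
  rownames(rs_perm$demo) <- NULL
  cs3 <- deduplicate(rs_perm)
  expect_equal(cs1$demo, cs3$demo)
})

test_that("dedup recovers the generator's planted unique-case count", {
  spec <- desk_spec(seed = 5)
  spec$n_cases <- 2000L
  u <- synth_generate(spec, seed = 5)
  expect_gt(u$truth$n_reports, u$truth$n_cases) # duplicates were planted
  cs <- deduplicate(join_records(u$tables))
  expect_equal(nrow(cs$demo), u$truth$n_cases)
  # and the FDA rule picked the original (latest) transmission of each case
  expect_setequal(cs$demo$primaryid, u$truth$cases$primaryid)
})

test_that("cases are partitioned by target PT membership", {
  rs <- mk_rs(
    demo = rbind(mk_demo("1"), mk_demo("2")),
    drug = rbind(mk_drug("1", "X"), mk_drug("2", "X")),
    reac = rbind(mk_reac("1", "10038907"), mk_reac("1", "10019211"),
                 mk_reac("2", "10019211"))
  )
  cs <- select_event_cases(deduplicate(rs), rvo_config())
  expect_equal(cs$demo$is_event[cs$demo$primaryid == "1"], TRUE)
  expect_equal(cs$demo$is_event[cs$demo$primaryid == "2"], FALSE)
  expect_error(filter_config(target_pts = character(0)), "PT")
})

test_that("event prevalence on a null universe matches the planted rate", {
  spec <- synthetic_spec(
    n_cases = 10000L,
    drugs = data.frame(name = c("a", "b"), exposure = c(0.5, 0.5),
                       lift = c(1, 1)),
    p0 = 0.01, duplicate_rate = 0, missing_date_rate = 0, seed = 9
  )
  u <- synth_generate(spec)
  cs <- select_event_cases(deduplicate(join_records(u$tables)), rvo_config())
  n_event <- sum(cs$demo$is_event)
  expect_lt(abs(n_event - 100), 3 * sqrt(10000 * 0.01 * 0.99))
  expect_equal(n_event, sum(u$truth$cases$is_event))
})

test_that("drug eligibility is an inclusive three-case threshold", {
  demo <- do.call(rbind, lapply(1:6, function(i) mk_demo(as.character(i))))
  drug <- rbind(mk_drug("1", "X"), mk_drug("2", "X"), mk_drug("3", "X"),
                mk_drug("4", "Y"), mk_drug("5", "Y"),
                mk_drug("6", "Z", role_cod = "C"))
  reac <- do.call(rbind, lapply(1:6, function(i)
    mk_reac(as.character(i), "10038907")))
  cs <- select_event_cases(deduplicate(mk_rs(demo, drug, reac)), rvo_config())
  flt <- apply_report_filters(cs, rvo_config())
  expect_equal(flt$eligible_drugs, "X")  # Y has 2 cases, Z not in a kept role
})

test_that("non-professional reporters are removed from the universe", {
  demo <- rbind(mk_demo("1", occp_cod = "MD"), mk_demo("2", occp_cod = "CN"),
                mk_demo("3", occp_cod = "PH"), mk_demo("4", occp_cod = "LW"),
                mk_demo("5", occp_cod = "OT"))
  drug <- do.call(rbind, lapply(1:5, function(i) mk_drug(as.character(i), "X")))
  cs <- select_event_cases(deduplicate(mk_rs(demo, drug)), rvo_config())
  flt <- apply_report_filters(cs, rvo_config())
  expect_setequal(flt$cases$demo$primaryid, c("1", "3", "5"))
  st <- flt$cases$provenance
  expect_equal(st$removed[st$stage == "reporter_filter"], 2L)
  # with universe = "all" everything stays
  flt2 <- apply_report_filters(cs, rvo_config(universe = "all"))
  expect_equal(nrow(flt2$cases$demo), 5L)
})

test_that("verbatim names standardize case-insensitively, unmapped pass through", {
  map <- data.frame(verbatim = c("MYRBETRIQ", "VIAGRA", "sildenafil citrate"),
                    canonical = c("mirabegron", "sildenafil", "sildenafil"))
  rs <- mk_rs(
    demo = rbind(mk_demo("1"), mk_demo("2"), mk_demo("3"), mk_demo("4")),
    drug = rbind(mk_drug("1", "Myrbetriq "), mk_drug("2", "VIAGRA"),
                 mk_drug("3", "Sildenafil Citrate"), mk_drug("4", "DRUG X"))
  )
  rs <- standardize_drug_names(rs, map)
  expect_equal(rs$drug$drugname,
               c("mirabegron", "sildenafil", "sildenafil", "DRUG X"))
  expect_equal(rs$counters$n_unmapped, 1L)
})
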