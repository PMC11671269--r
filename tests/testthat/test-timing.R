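mk_onset_cs <- function(rows) {
  # rows: list of c(pid, start, event) with optional occp
  demo <- do.call(rbind, lapply(rows, function(r)
    mk_demo(r[[1]], event_dt = r[[3]])))
  drug <- do.call(rbind, lapply(rows, function(r) mk_drug(r[[1]], "drugX")))
  ther <- do.call(rbind, lapply(rows, function(r) mk_ther(r[[1]], r[[2]])))
  reac <- do.call(rbind, lapply(rows, function(r) mk_reac(r[[1]], "10038907")))
  select_event_cases(deduplicate(mk_rs(demo, drug, reac, ther)), rvo_config())
}

test_that("onset is event date minus therapy start in days, with exclusions counted", {
  cs <- mk_onset_cs(list(
    c("1", "20230101", "20230111"),   # 10 days
    c("2", "20230201", "20230131"),   # negative: excluded
    c("3", "", "20230111"),           # missing start: excluded
    c("4", "202301", "20230111")      # month precision: excluded by default
  ))
  on <- compute_onsets(cs, "drugX", rvo_config())
  expect_equal(on$onset_days, 10L)
  cnt <- attr(on, "counters")
  expect_equal(cnt$n_negative, 1L)
  expect_equal(cnt$n_missing, 1L)
  expect_equal(cnt$n_partial, 1L)
  # with month imputation the partial date contributes (15th - 11th < 0
  # would be negative; here start 2023-01-15 > event 2023-01-11, negative)
  on2 <- compute_onsets(cs, "drugX", rvo_config(), impute_month = TRUE)
  expect_equal(attr(on2, "counters")$n_negative, 2L)
})

test_that("quartiles interpolate at position 1 + (n-1)p", {
  s <- data.frame(caseid = as.character(1:4), drug = "x",
                  drug_class = "cls", onset_days = c(2, 4, 6, 8))
  sm <- onset_summary(s, by = "drug")
  expect_equal(sm$median, 5)
  expect_equal(sm$q1, 3.5)
  expect_equal(sm$q3, 6.5)
  s1 <- data.frame(caseid = "1", drug = "x", drug_class = "cls",
                   onset_days = 7)
  expect_equal(unlist(onset_summary(s1, "drug")[, c("median", "q1", "q3")]),
               c(median = 7, q1 = 7, q3 = 7))
  sdup <- data.frame(caseid = as.character(1:4), drug = "x",
                     drug_class = "cls", onset_days = c(1, 1, 1, 8))
  expect_equal(onset_summary(sdup, "drug")$median, 1)
})

test_that("groups are ordered by descending median", {
  s <- data.frame(caseid = as.character(1:6),
                  drug = rep(c("slow", "fast"), each = 3),
                  drug_class = NA_character_,
                  onset_days = c(100, 200, 300, 1, 2, 3))
  sm <- onset_summary(s, by = "drug")
  expect_equal(sm$group, c("slow", "fast"))
})

test_that("the product-limit curve without censoring is the empirical survival", {
  s <- data.frame(caseid = as.character(1:3), drug = "x", drug_class = "cls",
                  onset_days = c(10, 20, 30))
  km <- km_estimate(s, by = "drug")
  expect_equal(km$time, c(10, 20, 30))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(km$at_risk, c(3, 2, 1))
  # identical times: single drop from 1 to 0
  s5 <- data.frame(caseid = as.character(1:4), drug = "x",
                   drug_class = "cls", onset_days = rep(5, 4))
  km5 <- km_estimate(s5, by = "drug")
  expect_equal(km5$survival, 0)
  expect_equal(km5$time, 5)

  # property: KM == empirical survival function on random samples
  set.seed(77)
  x <- sample(1:400, 120, replace = TRUE)
  sr <- data.frame(caseid = as.character(seq_along(x)), drug = "x",
                   drug_class = "c", onset_days = x)
  kmr <- km_estimate(sr, by = "drug")
  emp <- vapply(kmr$time, function(t) mean(x > t), numeric(1))
  expect_equal(kmr$survival, emp, tolerance = 1e-12)
})

test_that("the KM median of exponential onsets recovers the true median", {
  set.seed(123)
  m_true <- 150
  x <- pmax(1, round(rexp(500, rate = log(2) / m_true)))
  s <- data.frame(caseid = as.character(seq_along(x)), drug = "x",
                  drug_class = "c", onset_days = x)
  med <- attr(km_estimate(s, by = "drug"), "medians")
  expect_lt(abs(med[["x"]] - m_true) / m_true, 0.10)
})

test_that("the log-rank test is null on exchangeable groups and rank-invariant", {
  s <- data.frame(caseid = as.character(1:6),
                  drug = rep(c("a", "b"), each = 3),
                  drug_class = NA_character_,
                  onset_days = rep(c(5, 10, 15), 2))
  lr <- logrank_test(s, by = "drug")
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)

  # a common monotone time transformation leaves the statistic unchanged
  set.seed(31)
  s2 <- data.frame(caseid = as.character(1:80),
                   drug = rep(c("a", "b"), each = 40),
                   drug_class = NA_character_,
                   onset_days = c(rexp(40, 1 / 50), rexp(40, 1 / 200)))
  lr_raw <- logrank_test(s2, by = "drug")
  s3 <- s2
  s3$onset_days <- s2$onset_days^2 + 7
  lr_tr <- logrank_test(s3, by = "drug")
  expect_equal(lr_tr$statistic, lr_raw$statistic, tolerance = 1e-10)
})

test_that("onset exclusion counters equal the generator's planted missing dates", {
  spec <- desk_spec(seed = 23)
  spec$n_cases <- 6000L
  u <- synth_generate(spec, seed = 23)
  cfg <- rvo_config()
  res <- run_signal_pipeline(u, cfg, synonym_map = synth_synonym_map(spec))
  drugs <- res$eligible_drugs
  on <- compute_onsets(res$cases, drugs, cfg, class_map = rvo_class_map())
  tc <- u$truth$cases
  kept <- tc$occp %in% c("MD", "PH", "OT") & tc$is_event & tc$drug %in% drugs
  expect_equal(attr(on, "counters")$n_missing, sum(kept & tc$start_missing))
  expect_equal(attr(on, "counters")$n_negative, 0L)
  # observed onsets equal the planted per-case onsets
  idx <- match(on$caseid, tc$caseid)
  expect_equal(on$onset_days, tc$onset_days[idx])
})
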