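# closed-form reference values for the table (a,b,c,d) = (10,90,100,9900),
# frozen from hand evaluation of each formula (chi-square cross-checked
# against chisq.test)
ref_t <- contingency_table(10, 90, 100, 9900)

test_that("ROR, PRR and chi-square match hand-evaluated closed forms", {
  r <- ror_stats(ref_t)
  expect_equal(r$ror, 11, tolerance = 1e-12)
  expect_equal(r$se_log, 0.3481553, tolerance = 1e-6)
  expect_equal(r$ci_low, 5.559515, tolerance = 1e-6)
  expect_equal(r$ci_high, 21.76449, tolerance = 1e-6)
  expect_false(r$corrected)

  p <- prr_stats(ref_t, chi2_variant = "pearson")
  expect_equal(p$prr, 10, tolerance = 1e-12)
  expect_equal(p$chi2, 74.44717, tolerance = 1e-6)
  py <- prr_stats(ref_t) # yates default
  expect_equal(py$chi2, 66.32694, tolerance = 1e-6)

  # independent route: the Pearson statistic of the same 2x2 table
  m <- matrix(c(10, 100, 90, 9900), 2)
  expect_equal(p$chi2, unname(suppressWarnings(
    chisq.test(m, correct = FALSE)$statistic)), tolerance = 1e-10)
  expect_equal(py$chi2, unname(suppressWarnings(
    chisq.test(m, correct = TRUE)$statistic)), tolerance = 1e-10)
})

test_that("EBGM, EBGM05 and the information component match closed forms", {
  e <- ebgm_stats(ref_t)
  expect_equal(e$ebgm, 9.181818, tolerance = 1e-6)
  expect_equal(e$ebgm05, 5.187493, tolerance = 1e-6)
  i <- ic_stats(ref_t)
  expect_equal(i$ic, log2(9.181818181818), tolerance = 1e-9)
  expect_equal(i$e_ic, 2.382489, tolerance = 1e-6)
  expect_equal(i$v_ic, 0.2280399, tolerance = 1e-6)
  expect_equal(i$ic_025, 1.427419, tolerance = 1e-6)
})

test_that("an independence table gives ROR = PRR = EBGM = 1 and IC = 0", {
  t <- contingency_table(1, 1, 1, 1)
  expect_equal(ror_stats(t)$ror, 1)
  # CI symmetric about 1 on the log scale
  expect_equal(ror_stats(t)$ci_low * ror_stats(t)$ci_high, 1,
               tolerance = 1e-12)
  t2 <- contingency_table(5, 50, 20, 200) # ad = bc
  expect_equal(prr_stats(t2)$prr, 1, tolerance = 1e-12)
  expect_equal(ic_stats(t2)$ic, 0, tolerance = 1e-12)
  expect_equal(ebgm_stats(t2)$ebgm, 1, tolerance = 1e-12)
})

test_that("IC equals log2(EBGM) and Wald bounds are log-symmetric on random tables", {
  tabs <- rand_tables(200, seed = 21)
  st <- signal_table(apply(tabs, 1, function(r)
    contingency_table(r[1], r[2], r[3], r[4])))
  expect_equal(st$ic_crude, log2(st$ebgm), tolerance = 1e-12)
  expect_equal(st$ror_ci_low * st$ror_ci_high, st$ror^2, tolerance = 1e-10)
  expect_equal(st$prr_ci_low * st$prr_ci_high, st$prr^2, tolerance = 1e-10)
  expect_equal(wald_upper(st$ror, st$ror_ci_low), st$ror_ci_high,
               tolerance = 1e-10)
  expect_equal(ebgm05_from_se(st$ebgm, se_from_ci(st$ror_ci_low,
                                                  st$ror_ci_high)),
               st$ebgm05, tolerance = 1e-10)
})

test_that("prior-based IC converges to the crude IC as cells scale up", {
  base <- c(10, 90, 100, 9900)
  errs <- vapply(c(1, 1e2, 1e4), function(k) {
    t <- contingency_table(base[1] * k, base[2] * k, base[3] * k, base[4] * k)
    i <- ic_stats(t)
    c(abs(i$e_ic - i$ic), i$v_ic)
  }, numeric(2))
  expect_true(all(diff(errs[1, ]) < 0))  # |E(IC) - IC| shrinks
  expect_true(all(diff(errs[2, ]) < 0))  # V(IC) -> 0
  expect_lt(errs[1, 3], 1e-3)
  expect_lt(errs[2, 3], 1e-4)
})

test_that("zero cells trigger the Haldane correction and stay finite", {
  t <- contingency_table(3, 0, 50, 5000)
  r <- ror_stats(t)
  expect_true(r$corrected)
  expect_true(is.finite(r$ror) && is.finite(r$ci_high))
  st <- signal_table(list(t))
  expect_true(st$corrected)
  expect_true(all(is.finite(c(st$ror, st$prr, st$ic, st$ebgm05))))
})

test_that("joint positivity and IC tiers follow the published thresholds", {
  # strong signal with few reports: all four algorithms positive, high tier
  strong <- list(a = 3, ror_ci_low = 25.750, prr_ci_low = 25, ic_025 = 4.640,
                 ebgm05 = 30.722)
  r <- classify_signal(strong)
  expect_true(r$joint_signal)
  expect_equal(r$tier, "high")
  # weak but positive signal
  expect_equal(classify_signal(list(a = 47, ror_ci_low = 2.789,
                                    prr_ci_low = 2.7, ic_025 = 0.190,
                                    ebgm05 = 2.840))$tier, "low")
  # moderate tier
  expect_equal(classify_signal(list(a = 8, ror_ci_low = 5.254,
                                    prr_ci_low = 5.2, ic_025 = 1.719,
                                    ebgm05 = 5.846))$tier, "medium")
  # boundary: ic_025 exactly 0 is no signal; a = 2 fails the count rule
  r0 <- classify_signal(list(a = 10, ror_ci_low = 2, prr_ci_low = 2,
                             ic_025 = 0, ebgm05 = 3))
  expect_false(r0$flag_bcpnn)
  expect_equal(r0$tier, "none")
  r2 <- classify_signal(list(a = 2, ror_ci_low = 9, prr_ci_low = 9,
                             ic_025 = 2, ebgm05 = 9))
  expect_false(r2$flag_ror)
  expect_false(r2$joint_signal)
})

test_that("signal ranking is by IC lower bound, then ROR, and deterministic", {
  df <- data.frame(drug = c("tadalafil", "mirabegron", "raloxifene"),
                   ic_025 = c(3.488, 4.640, 4.370),
                   ror = c(36, 80, 67), joint_signal = TRUE)
  expect_equal(rank_signals(df)$drug,
               c("mirabegron", "raloxifene", "tadalafil"))
  # tie on ic_025 broken by ror
  df2 <- data.frame(drug = c("a", "b"), ic_025 = c(2, 2), ror = c(3, 9),
                    joint_signal = TRUE)
  expect_equal(rank_signals(df2)$drug, c("b", "a"))
  # permuting input leaves the ranking unchanged
  expect_equal(rank_signals(df[c(3, 1, 2), ])$drug,
               rank_signals(df)$drug)
})

test_that("report rounding is half-up at 3 decimals", {
  expect_equal(round_half_up(2.0005, 3), 2.001)
  expect_equal(round_half_up(2.0004, 3), 2.000)
  expect_equal(round_half_up(-2.0005, 3), -2.001)
})
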