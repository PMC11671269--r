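#' Dirichlet prior counts for the BCPNN information component
#'
#' The standard vague priors of the Bayesian confidence propagation
#' neural network: alpha1 = beta1 = 1 on the drug and event margins,
#' alpha = beta = 2 on their totals, gamma11 = 1 on the joint cell. The
#' joint prior total gamma is table-dependent,
#' `gamma11 * (N+alpha) * (N+beta) / ((a+b+alpha1) * (a+c+beta1))`,
#' which centres the prior expectation of the IC at zero.
#'
#' @param alpha1,beta1,alpha,beta,gamma11 positive prior counts.
#' @return An object of class `bcpnn_priors`.
#' @export
bcpnn_priors <- function(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2,
                         gamma11 = 1) {
  stopifnot(alpha1 > 0, beta1 > 0, alpha > 0, beta > 0, gamma11 > 0)
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha = alpha,
                 beta = beta, gamma11 = gamma11),
            class = "bcpnn_priors")
}

# Haldane continuity correction: +0.5 to all four cells when any of
# b, c, d is zero, applied per statistic and flagged.
.cells <- function(t) {
  corrected <- (t$b == 0 || t$c == 0 || t$d == 0)
  k <- if (corrected) 0.5 else 0
  list(a = t$a + k, b = t$b + k, c = t$c + k, d = t$d + k,
       N = t$N + 4 * k, corrected = corrected)
}

# ---- vectorized cores (shared by the per-table wrappers and signal_table)

.ror_core <- function(a, b, c, d) {
  ror <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ror = ror, ci_low = exp(log(ror) - 1.96 * se),
       ci_high = exp(log(ror) + 1.96 * se), se_log = se)
}

.prr_core <- function(a, b, c, d) {
  prr <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  list(prr = prr, ci_low = exp(log(prr) - 1.96 * se),
       ci_high = exp(log(prr) + 1.96 * se), se_log = se)
}

.chi2_core <- function(a, b, c, d, variant = "yates") {
  N <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  if (variant == "yates") {
    N * pmax(abs(a * d - b * c) - N / 2, 0)^2 / den
  } else {
    N * (a * d - b * c)^2 / den
  }
}

.ic_core <- function(a, b, c, d, priors) {
  N <- a + b + c + d
  ic <- log2(a * N / ((a + b) * (a + c)))
  a1 <- priors$alpha1; b1 <- priors$beta1
  al <- priors$alpha; be <- priors$beta; g11 <- priors$gamma11
  g <- g11 * (N + al) * (N + be) / ((a + b + a1) * (a + c + b1))
  e_ic <- log2((a + g11) * (N + al) * (N + be) /
                 ((N + g) * (a + b + a1) * (a + c + b1)))
  v_ic <- (1 / log(2)^2) * (
    (N - a + g - g11) / ((a + g11) * (1 + N + g)) +
      (N - a - b + al - a1) / ((a + b + a1) * (1 + N + al)) +
      (N - a - c + be - b1) / ((a + c + b1) * (1 + N + be)))
  list(ic = ic, e_ic = e_ic, v_ic = v_ic, ic_025 = e_ic - 2 * sqrt(v_ic))
}

.ebgm_core <- function(a, b, c, d) {
  N <- a + b + c + d
  ebgm <- a * N / ((a + c) * (a + b))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(ebgm = ebgm, ebgm05 = exp(log(ebgm) - 1.64 * se))
}

# ---- per-table operations

#' Reporting odds ratio with 95% Wald interval
#'
#' `ROR = (a d)/(b c)` with standard error of the log
#' `sqrt(1/a + 1/b + 1/c + 1/d)` and log-symmetric 95% bounds
#' `exp(log(ROR) -/+ 1.96 SE)`, so `ci_high = ror^2 / ci_low`.
#' Zero cells among b, c, d trigger the Haldane correction (all cells
#' +0.5) and set `corrected`.
#'
#' @param t a `contingency_table`.
#' @return list with `ror`, `ci_low`, `ci_high`, `se_log`, `corrected`.
#' @export
ror_stats <- function(t) {
  if (t$N <= 0) stop("degenerate table: N = 0", call. = FALSE)
  cl <- .cells(t)
  c(.ror_core(cl$a, cl$b, cl$c, cl$d), list(corrected = cl$corrected))
}

#' Proportional reporting ratio, Wald interval and chi-square
#'
#' `PRR = (a/(a+b)) / (c/(c+d))` with
#' `SE(log PRR) = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))` and Wald bounds as
#' for the ROR. The chi-square statistic of the same 2x2 table is
#' Yates-corrected by default (the usual convention for sparse
#' pharmacovigilance tables), or plain Pearson via
#' `chi2_variant = "pearson"`; it is computed on the uncorrected cells.
#'
#' @param t a `contingency_table`.
#' @param chi2_variant `"yates"` (default) or `"pearson"`.
#' @return list with `prr`, `ci_low`, `ci_high`, `se_log`, `chi2`,
#'   `chi2_p`, `corrected`.
#' @export
prr_stats <- function(t, chi2_variant = c("yates", "pearson")) {
  chi2_variant <- match.arg(chi2_variant)
  if (t$N <= 0) stop("degenerate table: N = 0", call. = FALSE)
  cl <- .cells(t)
  out <- .prr_core(cl$a, cl$b, cl$c, cl$d)
  chi2 <- .chi2_core(t$a, t$b, t$c, t$d, chi2_variant)
  c(out, list(chi2 = chi2, chi2_p = pchisq(chi2, df = 1, lower.tail = FALSE),
              corrected = cl$corrected))
}

#' BCPNN information component
#'
#' The crude information component `IC = log2(a N / ((a+b)(a+c)))`
#' measures how much more often the drug-event pair is reported than
#' expected under independence. The prior-based BCPNN quantities use the
#' Dirichlet priors of [bcpnn_priors()]: `e_ic` is the posterior
#' expectation, `v_ic` its variance, and `ic_025 = e_ic - 2 sqrt(v_ic)`
#' the lower bound used for signal positivity and risk tiers. With
#' `mode = "crude"` (the default) the headline `ic` is the crude value —
#' which equals `log2(ebgm)` for the crude EBGM exactly — while the
#' prior-based quantities are always computed alongside.
#'
#' @param t a `contingency_table`.
#' @param priors a [bcpnn_priors()].
#' @param mode `"crude"` or `"prior"`; with `"prior"` the headline `ic`
#'   is the posterior expectation `e_ic`.
#' @return list with `ic`, `e_ic`, `v_ic`, `ic_025`, `corrected`.
#' @export
ic_stats <- function(t, priors = bcpnn_priors(), mode = c("crude", "prior")) {
  mode <- match.arg(mode)
  if (t$N <= 0) stop("degenerate table: N = 0", call. = FALSE)
  cl <- .cells(t)
  out <- .ic_core(cl$a, cl$b, cl$c, cl$d, priors)
  if (mode == "prior") out$ic <- out$e_ic
  c(out, list(corrected = cl$corrected))
}

#' Crude EBGM and its one-sided lower bound
#'
#' The crude empirical-Bayes geometric mean is the relative reporting
#' ratio `EBGM = a N / ((a+c)(a+b))`, with one-sided 95% lower bound
#' `EBGM05 = exp(log(EBGM) - 1.64 sqrt(1/a + 1/b + 1/c + 1/d))`. The full
#' DuMouchel gamma-Poisson mixture fit (empirical-Bayes hyperparameter
#' estimation) is intentionally not implemented; the crude ratio is the
#' statistic this pipeline reports, and a mixture fit can be slotted in
#' behind the same interface.
#'
#' @param t a `contingency_table`.
#' @return list with `ebgm`, `ebgm05`, `corrected`.
#' @export
ebgm_stats <- function(t) {
  if (t$N <= 0) stop("degenerate table: N = 0", call. = FALSE)
  cl <- .cells(t)
  c(.ebgm_core(cl$a, cl$b, cl$c, cl$d), list(corrected = cl$corrected))
}

#' Signal positivity thresholds and risk-tier breaks
#'
#' Defaults follow the joint criteria used in FAERS disproportionality
#' practice: ROR requires `a >= 3` and 95% CI lower bound > 1; PRR the
#' same; BCPNN requires `IC025 > 0`; MGPS requires `EBGM05 > 2` and
#' `a > 0`. Risk tiers cut the IC lower bound at 0, 1.5 and 3
#' (none / low / medium / high).
#'
#' @param min_reports minimum `a` for ROR/PRR positivity.
#' @param ror_ci_low,prr_ci_low,ic025_min,ebgm05_min thresholds.
#' @param tier_breaks increasing numeric vector of 3 IC025 cut points.
#' @return list of thresholds, class `signal_criteria`.
#' @export
signal_criteria <- function(min_reports = 3L, ror_ci_low = 1,
                            prr_ci_low = 1, ic025_min = 0,
                            ebgm05_min = 2, tier_breaks = c(0, 1.5, 3)) {
  stopifnot(length(tier_breaks) == 3L, !is.unsorted(tier_breaks))
  structure(list(min_reports = min_reports, ror_ci_low = ror_ci_low,
                 prr_ci_low = prr_ci_low, ic025_min = ic025_min,
                 ebgm05_min = ebgm05_min, tier_breaks = tier_breaks),
            class = "signal_criteria")
}

#' Apply the joint positivity criteria and IC risk tier
#'
#' Sets the four per-algorithm flags, the joint signal flag (their
#' conjunction) and the risk tier from `ic_025`: `<= 0` none,
#' `(0, 1.5]` low, `(1.5, 3]` medium, `> 3` high.
#'
#' @param result a one-row list/data.frame with fields `a`, `ror_ci_low`,
#'   `prr_ci_low`, `ic_025`, `ebgm05` (as produced by [signal_table()]).
#' @param criteria a [signal_criteria()].
#' @return `result` augmented with `flag_ror`, `flag_prr`, `flag_bcpnn`,
#'   `flag_mgps`, `joint_signal`, `tier`.
#' @export
classify_signal <- function(result, criteria = signal_criteria()) {
  result$flag_ror <- result$a >= criteria$min_reports &
    result$ror_ci_low > criteria$ror_ci_low
  result$flag_prr <- result$a >= criteria$min_reports &
    result$prr_ci_low > criteria$prr_ci_low
  result$flag_bcpnn <- result$ic_025 > criteria$ic025_min
  result$flag_mgps <- result$ebgm05 > criteria$ebgm05_min & result$a > 0
  result$joint_signal <- result$flag_ror & result$flag_prr &
    result$flag_bcpnn & result$flag_mgps
  br <- criteria$tier_breaks
  result$tier <- cut(result$ic_025, breaks = c(-Inf, br, Inf),
                     labels = c("none", "low", "medium", "high"),
                     right = TRUE)
  result$tier <- as.character(result$tier)
  result
}

#' Compute all four disproportionality statistics for a set of tables
#'
#' One row per contingency table with ROR, PRR (+ chi-square), crude and
#' prior-based BCPNN quantities, crude EBGM/EBGM05, the Haldane flag,
#' per-algorithm positivity flags, joint signal flag and risk tier.
#'
#' @param tables list of `contingency_table` objects (or a single one).
#' @param priors a [bcpnn_priors()].
#' @param chi2_variant `"yates"` or `"pearson"`.
#' @param criteria a [signal_criteria()].
#' @param ic_mode `"crude"` (headline IC is the crude value) or
#'   `"prior"`.
#' @return data.frame of signal results.
#' @export
signal_table <- function(tables, priors = bcpnn_priors(),
                         chi2_variant = c("yates", "pearson"),
                         criteria = signal_criteria(),
                         ic_mode = c("crude", "prior")) {
  chi2_variant <- match.arg(chi2_variant)
  ic_mode <- match.arg(ic_mode)
  if (inherits(tables, "contingency_table")) tables <- list(tables)
  a0 <- vapply(tables, `[[`, numeric(1), "a")
  b0 <- vapply(tables, `[[`, numeric(1), "b")
  c0 <- vapply(tables, `[[`, numeric(1), "c")
  d0 <- vapply(tables, `[[`, numeric(1), "d")
  corrected <- b0 == 0 | c0 == 0 | d0 == 0
  k <- ifelse(corrected, 0.5, 0)
  a <- a0 + k; b <- b0 + k; c_ <- c0 + k; d <- d0 + k
  ror <- .ror_core(a, b, c_, d)
  prr <- .prr_core(a, b, c_, d)
  chi2 <- .chi2_core(a0, b0, c0, d0, chi2_variant)
  ic <- .ic_core(a, b, c_, d, priors)
  eb <- .ebgm_core(a, b, c_, d)
  res <- data.frame(
    drug = vapply(tables, `[[`, character(1), "drug"),
    a = a0, b = b0, c = c0, d = d0, N = a0 + b0 + c0 + d0,
    ror = ror$ror, ror_ci_low = ror$ci_low, ror_ci_high = ror$ci_high,
    se_log = ror$se_log,
    prr = prr$prr, prr_ci_low = prr$ci_low, prr_ci_high = prr$ci_high,
    chi2 = chi2, chi2_p = pchisq(chi2, df = 1, lower.tail = FALSE),
    ic = if (ic_mode == "crude") ic$ic else ic$e_ic,
    ic_crude = ic$ic, e_ic = ic$e_ic, v_ic = ic$v_ic, ic_025 = ic$ic_025,
    ebgm = eb$ebgm, ebgm05 = eb$ebgm05,
    corrected = corrected,
    stringsAsFactors = FALSE
  )
  classify_signal(res, criteria)
}

#' Rank joint-positive signals
#'
#' Keeps joint-signal rows and orders them by descending IC lower bound,
#' ties broken by descending ROR then drug name. Deterministic for any
#' input order.
#'
#' @param results data.frame from [signal_table()].
#' @return the ranked subset.
#' @export
rank_signals <- function(results) {
  res <- results[results$joint_signal, , drop = FALSE]
  res <- res[order(-res$ic_025, -res$ror, res$drug), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# ---- identities among printed statistics -------------------------------

#' Upper Wald bound from the estimate and lower bound
#'
#' Wald intervals on the log scale are log-symmetric, so
#' `upper = estimate^2 / lower`. Useful for reconstructing the upper
#' bound of a published ROR or PRR interval from the printed estimate and
#' lower bound.
#'
#' @param estimate,lower positive numerics.
#' @return the implied upper bound.
#' @export
wald_upper <- function(estimate, lower) {
  stopifnot(all(estimate > 0), all(lower > 0))
  estimate^2 / lower
}

#' Recover the log-scale standard error from a Wald interval
#'
#' `se = log(upper/lower) / (2 z)` for a two-sided interval with
#' multiplier `z` (1.96 for 95%).
#'
#' @param lower,upper interval bounds.
#' @param z normal multiplier.
#' @return standard error of the log estimate.
#' @export
se_from_ci <- function(lower, upper, z = 1.96) {
  log(upper / lower) / (2 * z)
}

#' EBGM05 implied by an EBGM value and a log-scale standard error
#'
#' @param ebgm crude EBGM value.
#' @param se_log standard error of the log (e.g. from [se_from_ci()]).
#' @return `exp(log(ebgm) - 1.64 * se_log)`.
#' @export
ebgm05_from_se <- function(ebgm, se_log) {
  exp(log(ebgm) - 1.64 * se_log)
}

#' Round half away from zero
#'
#' Report tables round to 3 decimals with halves rounded up (the common
#' presentation in published signal tables), unlike R's banker's
#' rounding.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 3L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a signal table in the style of a published result table
#'
#' One row per drug with `ROR (CI)`, `PRR (chi2)`, `EBGM (EBGM05)` and
#' `IC (IC025)` columns, values rounded half-up to 3 decimals.
#'
#' @param results data.frame from [signal_table()].
#' @param classes optional data.frame from [assign_classes()] to add an
#'   ATC class column.
#' @return character data.frame ready for CSV export.
#' @export
format_signal_table <- function(results, classes = NULL) {
  f <- function(x) formatC(round_half_up(x, 3L), format = "f", digits = 3)
  out <- data.frame(
    drug = results$drug,
    number = results$a,
    ror_ci = sprintf("%s (%s-%s)", f(results$ror), f(results$ror_ci_low),
                     f(results$ror_ci_high)),
    prr_chi2 = sprintf("%s (%s)", f(results$prr), f(results$chi2)),
    ebgm_ebgm05 = sprintf("%s (%s)", f(results$ebgm), f(results$ebgm05)),
    ic_ic025 = sprintf("%s (%s)", f(results$ic), f(results$ic_025)),
    tier = results$tier,
    stringsAsFactors = FALSE
  )
  if (!is.null(classes)) {
    out$atc_class <- classes$atc_class[match(out$drug, classes$drug)]
    out <- out[, c("drug", "number", "atc_class", "ror_ci", "prr_chi2",
                   "ebgm_ebgm05", "ic_ic025", "tier")]
  }
  out
}
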