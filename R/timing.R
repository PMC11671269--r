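#' Compute per-case time to onset for selected drugs
#'
#' Onset is the number of days from therapy start (the `start_dt`
#' attached to the suspect drug row) to the event date (`event_dt` on the
#' case). Only event cases exposed to one of `drugs` in a kept role
#' contribute. Cases where either date is absent, or reported at less
#' than day precision, are excluded and counted (month-precision dates
#' can be imputed to mid-month with `impute_month = TRUE`); negative
#' differences are excluded and counted separately.
#'
#' @param cs a `case_set` through [select_event_cases()].
#' @param drugs character vector of (canonical) drug names, typically the
#'   joint-signal drugs.
#' @param config a [filter_config()] (kept roles).
#' @param class_map optional data.frame (`drug`, `atc_class`, ...) used
#'   to label each sample with its drug class.
#' @param impute_month impute month-precision dates to day 15 instead of
#'   excluding them?
#' @return data.frame with columns `caseid`, `drug`, `drug_class`,
#'   `onset_days`, and attribute `counters` (list with `n_missing`,
#'   `n_partial`, `n_negative`).
#' @export
compute_onsets <- function(cs, drugs, config, class_map = NULL,
                           impute_month = FALSE) {
  stopifnot(inherits(cs, "case_set"))
  if (is.null(cs$demo$is_event)) {
    stop("run select_event_cases() first", call. = FALSE)
  }
  dr <- cs$drug[toupper(cs$drug$role_cod) %in% config$roles_kept &
                  cs$drug$drugname %in% drugs, , drop = FALSE]
  dr <- dr[!duplicated(paste(dr$primaryid, dr$drugname, sep = "\r")), ,
           drop = FALSE]
  demo_idx <- match(dr$primaryid, cs$demo$primaryid)
  keep <- !is.na(demo_idx) & cs$demo$is_event[demo_idx]
  dr <- dr[keep, , drop = FALSE]
  demo_idx <- demo_idx[keep]

  start_pd <- suppressWarnings(parse_partial_date(dr$start_dt))
  event_pd <- suppressWarnings(parse_partial_date(cs$demo$event_dt[demo_idx]))
  start <- partial_date_as_date(start_pd, impute_month = impute_month)
  event <- partial_date_as_date(event_pd, impute_month = impute_month)

  missing <- start_pd$precision == "none" | event_pd$precision == "none"
  partial <- !missing & (is.na(start) | is.na(event))
  onset <- as.integer(event - start)
  negative <- !missing & !partial & onset < 0
  ok <- !missing & !partial & !negative

  out <- data.frame(caseid = dr$caseid[ok], drug = dr$drugname[ok],
                    drug_class = NA_character_,
                    onset_days = onset[ok], stringsAsFactors = FALSE)
  if (!is.null(class_map)) {
    out$drug_class <- class_map$atc_class[match(out$drug, class_map$drug)]
    out$drug_class[is.na(out$drug_class)] <- "unclassified"
  }
  rownames(out) <- NULL
  attr(out, "counters") <- list(n_missing = sum(missing),
                                n_partial = sum(partial),
                                n_negative = sum(negative))
  out
}

.onset_groups <- function(samples, by = c("drug", "class")) {
  by <- match.arg(by)
  g <- if (by == "drug") samples$drug else samples$drug_class
  if (by == "class" && all(is.na(g))) {
    stop("samples carry no drug_class labels; pass class_map to compute_onsets()",
         call. = FALSE)
  }
  g
}

#' Median and quartiles of time to onset per group
#'
#' Quantiles use linear interpolation between order statistics at
#' position `1 + (n-1) p` (R's default type-7 convention). Groups are
#' sorted by descending median.
#'
#' @param samples data.frame from [compute_onsets()].
#' @param by `"drug"` or `"class"`.
#' @return data.frame with `group`, `n`, `median`, `q1`, `q3`.
#' @export
onset_summary <- function(samples, by = c("drug", "class")) {
  g <- .onset_groups(samples, by)
  keep <- !is.na(g)
  if (any(!keep)) warning("omitting samples without a group label",
                          call. = FALSE)
  sp <- split(samples$onset_days[keep], g[keep])
  sp <- sp[lengths(sp) > 0L]
  out <- data.frame(
    group = names(sp),
    n = lengths(sp),
    median = vapply(sp, function(x) unname(quantile(x, 0.5, type = 7)),
                    numeric(1)),
    q1 = vapply(sp, function(x) unname(quantile(x, 0.25, type = 7)),
                numeric(1)),
    q3 = vapply(sp, function(x) unname(quantile(x, 0.75, type = 7)),
                numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$median, out$group), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier curves of time to onset per group
#'
#' Spontaneous-report onsets carry no follow-up, so every sample is an
#' observed event and the product-limit estimator reduces to the
#' empirical survival function; the KM machinery is kept so that the
#' median and curve conventions match standard survival output.
#'
#' @param samples data.frame from [compute_onsets()].
#' @param by `"drug"` or `"class"`.
#' @return data.frame with `group`, `time`, `at_risk`, `survival`;
#'   attribute `survfit` holds the underlying [survival::survfit] object
#'   and attribute `medians` the per-group KM medians (first time at
#'   which survival drops to 0.5 or below).
#' @export
km_estimate <- function(samples, by = c("drug", "class")) {
  g <- .onset_groups(samples, by)
  keep <- !is.na(g)
  df <- data.frame(time = samples$onset_days[keep], group = g[keep],
                   stringsAsFactors = FALSE)
  fit <- survival::survfit(survival::Surv(time, rep(1L, nrow(df))) ~ group,
                           data = df)
  if (is.null(fit$strata)) {
    groups <- rep(unique(df$group), length(fit$time))
  } else {
    groups <- rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  out <- data.frame(group = groups, time = fit$time, at_risk = fit$n.risk,
                    survival = fit$surv, stringsAsFactors = FALSE)
  med <- vapply(split(out, out$group), function(s) {
    t_half <- s$time[s$survival <= 0.5]
    if (length(t_half)) min(t_half) else NA_real_
  }, numeric(1))
  attr(out, "survfit") <- fit
  attr(out, "medians") <- med
  out
}

#' Log-rank test of onset-time differences across groups
#'
#' Standard k-group log-rank test; the statistic is referred to a
#' chi-square distribution with k-1 degrees of freedom.
#'
#' @param samples data.frame from [compute_onsets()].
#' @param by `"drug"` or `"class"`.
#' @return list with `statistic`, `df`, `p_value`, `n_groups`.
#' @export
logrank_test <- function(samples, by = c("drug", "class")) {
  g <- .onset_groups(samples, by)
  keep <- !is.na(g)
  df <- data.frame(time = samples$onset_days[keep], group = g[keep],
                   stringsAsFactors = FALSE)
  if (length(unique(df$group)) < 2L) {
    stop("log-rank test needs at least two non-empty groups", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, rep(1L, nrow(df))) ~ group,
                           data = df)
  k <- length(sd$n)
  stat <- sd$chisq
  # degenerate design (e.g. identical single event time in every group):
  # no variance, no evidence of a difference
  if (!is.finite(stat)) stat <- 0
  list(statistic = unname(stat), df = k - 1L,
       p_value = pchisq(unname(stat), df = k - 1L, lower.tail = FALSE),
       n_groups = k)
}
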