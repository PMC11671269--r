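#' Build the 2x2 contingency table for one drug
#'
#' Classical pharmacovigilance "four-grid" table over the analysis
#' universe of unique cases:
#' * `a`: cases with the drug (in a kept role) and the target event
#' * `b`: cases with the drug and only other events
#' * `c`: event cases without the drug
#' * `d`: all remaining cases
#'
#' A case exposed to several suspect drugs contributes to each drug's
#' table, but only once per drug; `a + b + c + d` always equals the
#' universe size, and `a + c` (the event margin) is identical across all
#' drugs' tables.
#'
#' @param cs a `case_set` through [select_event_cases()] (and usually
#'   [apply_report_filters()]).
#' @param drug canonical drug name.
#' @param config a [filter_config()] (supplies the kept roles).
#' @return An object of class `contingency_table`: list with `drug`,
#'   `a`, `b`, `c`, `d`, `N` and logical `empty` (drug absent from the
#'   universe).
#' @export
build_table <- function(cs, drug, config) {
  stopifnot(inherits(cs, "case_set"))
  if (is.null(cs$demo$is_event)) {
    stop("run select_event_cases() first", call. = FALSE)
  }
  dr <- cs$drug[toupper(cs$drug$role_cod) %in% config$roles_kept &
                  cs$drug$drugname == drug, , drop = FALSE]
  exposed <- cs$demo$primaryid %in% dr$primaryid
  ev <- cs$demo$is_event
  a <- sum(exposed & ev); b <- sum(exposed & !ev)
  c_ <- sum(!exposed & ev); d <- sum(!exposed & !ev)
  structure(list(drug = drug, a = a, b = b, c = c_, d = d,
                 N = a + b + c_ + d, empty = (a + b) == 0L),
            class = "contingency_table")
}

#' Build contingency tables for all eligible drugs
#'
#' Single-pass equivalent of calling [build_table()] per drug; tables are
#' returned sorted by descending `a`, ties broken by drug name.
#'
#' @param cs a `case_set` through [select_event_cases()].
#' @param eligible_drugs character vector of drug names (typically from
#'   [apply_report_filters()]).
#' @param config a [filter_config()].
#' @return A list of `contingency_table` objects.
#' @export
build_all_tables <- function(cs, eligible_drugs, config) {
  stopifnot(inherits(cs, "case_set"))
  if (is.null(cs$demo$is_event)) {
    stop("run select_event_cases() first", call. = FALSE)
  }
  n_univ <- nrow(cs$demo)
  n_event <- sum(cs$demo$is_event)
  dr <- cs$drug[toupper(cs$drug$role_cod) %in% config$roles_kept &
                  cs$drug$drugname %in% eligible_drugs, , drop = FALSE]
  key <- paste(dr$primaryid, dr$drugname, sep = "\r")
  dr <- dr[!duplicated(key), , drop = FALSE]
  ev <- cs$demo$is_event[match(dr$primaryid, cs$demo$primaryid)]
  a_tab <- table(factor(dr$drugname[ev], levels = eligible_drugs))
  ab_tab <- table(factor(dr$drugname, levels = eligible_drugs))
  tabs <- lapply(eligible_drugs, function(g) {
    a <- as.integer(a_tab[[g]]); ab <- as.integer(ab_tab[[g]])
    b <- ab - a; c_ <- n_event - a; d <- n_univ - ab - c_
    structure(list(drug = g, a = a, b = b, c = c_, d = d,
                   N = n_univ, empty = ab == 0L),
              class = "contingency_table")
  })
  ord <- order(-vapply(tabs, `[[`, integer(1), "a"),
               vapply(tabs, `[[`, character(1), "drug"))
  tabs[ord]
}

#' Construct a contingency table from raw counts
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param drug optional drug label.
#' @return A `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, drug = "drug") {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0, a + b + c + d > 0)
  structure(list(drug = drug, a = a, b = b, c = c, d = d,
                 N = a + b + c + d, empty = (a + b) == 0),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s: a=%d b=%d c=%d d=%d (N=%d)%s\n",
              x$drug, x$a, x$b, x$c, x$d, x$N,
              if (isTRUE(x$empty)) " [drug absent]" else ""))
  invisible(x)
}

#' Export contingency tables as a data.frame / CSV
#' @param tables list of `contingency_table` objects.
#' @param path optional CSV path; when given, the table is also written.
#' @return data.frame with columns drug, a, b, c, d.
#' @export
tables_to_df <- function(tables, path = NULL) {
  df <- data.frame(
    drug = vapply(tables, `[[`, character(1), "drug"),
    a = vapply(tables, function(t) as.integer(t$a), integer(1)),
    b = vapply(tables, function(t) as.integer(t$b), integer(1)),
    c = vapply(tables, function(t) as.integer(t$c), integer(1)),
    d = vapply(tables, function(t) as.integer(t$d), integer(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
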