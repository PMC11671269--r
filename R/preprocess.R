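#' Analysis filter configuration
#'
#' Holds the case-selection rules: which MedDRA Preferred Terms define
#' the event, which drug roles count as exposure, which reporter
#' occupations are retained, and the minimum number of event cases a
#' drug needs to enter the analysis.
#'
#' The reporter default treats FAERS occupation codes MD (physician),
#' PH (pharmacist) and OT (other health professional) as "healthcare
#' professional". The drug-role default is primary suspect only (`PS`).
#'
#' @param target_pts character vector of MedDRA PT codes defining the
#'   event (e.g. `"10038907"`, retinal vein occlusion).
#' @param roles_kept drug role codes counted as exposure.
#' @param reporters_kept occupation codes retained in the analysis
#'   universe.
#' @param min_reports_per_drug minimum number of event cases per drug
#'   (inclusive) for signal analysis; must be >= 1.
#' @param universe `"professional"` restricts the denominator universe to
#'   the reporter-filtered cases (the default); `"all"` keeps every
#'   deduplicated case in the denominators.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(target_pts,
                          roles_kept = "PS",
                          reporters_kept = c("MD", "PH", "OT"),
                          min_reports_per_drug = 3L,
                          universe = c("professional", "all")) {
  if (length(target_pts) == 0L) {
    stop("target_pts must contain at least one MedDRA PT code", call. = FALSE)
  }
  min_reports_per_drug <- as.integer(min_reports_per_drug)
  if (is.na(min_reports_per_drug) || min_reports_per_drug < 1L) {
    stop("min_reports_per_drug must be >= 1", call. = FALSE)
  }
  structure(list(target_pts = as.character(target_pts),
                 roles_kept = toupper(roles_kept),
                 reporters_kept = toupper(reporters_kept),
                 min_reports_per_drug = min_reports_per_drug,
                 universe = match.arg(universe)),
            class = "filter_config")
}

#' Read a filter configuration from a plain-text (YAML) file
#'
#' Recognized keys: `target_pts`, `roles`, `reporters`, `min_reports`,
#' `universe`; missing keys fall back to the [filter_config()] defaults.
#'
#' @param path path to a YAML file.
#' @return A `filter_config`.
#' @export
read_filter_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- list(target_pts = as.character(cfg$target_pts))
  if (!is.null(cfg$roles)) args$roles_kept <- as.character(cfg$roles)
  if (!is.null(cfg$reporters)) args$reporters_kept <- as.character(cfg$reporters)
  if (!is.null(cfg$min_reports)) args$min_reports_per_drug <- cfg$min_reports
  if (!is.null(cfg$universe)) args$universe <- cfg$universe
  do.call(filter_config, args)
}

.add_stage <- function(provenance, stage, kept, removed) {
  rbind(provenance,
        data.frame(stage = stage, kept = kept, removed = removed,
                   stringsAsFactors = FALSE))
}

#' Deduplicate reports into unique cases
#'
#' Applies the FDA deduplication rule: for each `caseid` keep the report
#' with the latest FDA receipt date; among reports tied on date, keep the
#' numerically highest `primaryid`. Dates are compared at the coarsest
#' precision present within the case, so a year-only date ties with (and
#' never beats) a full date in the same year; the primaryid rule then
#' decides. Reports with no parseable FDA date are treated as earliest
#' possible and survive only when no dated sibling exists. Output is
#' sorted by `caseid`, making the result order-independent.
#'
#' @param rs a `report_set` from [join_records()].
#' @return An object of class `case_set`: like a `report_set` but with
#'   one `demo` row per `caseid`, plus a `provenance` data.frame counting
#'   kept/removed records at each pipeline stage.
#' @export
deduplicate <- function(rs) {
  stopifnot(inherits(rs, c("report_set", "case_set")))
  demo <- rs$demo
  pd <- suppressWarnings(parse_partial_date(demo$fda_dt))
  dt <- data.table(
    caseid = demo$caseid,
    primaryid = demo$primaryid,
    pid_num = suppressWarnings(as.numeric(demo$primaryid)),
    precision_rank = date_precision_rank(pd),
    row = seq_len(nrow(demo))
  )
  dt[is.na(pid_num), pid_num := -Inf]
  # coarsest precision among dated reports of the same case
  dt[, group_level := {
    p <- precision_rank[precision_rank > 0L]
    if (length(p)) min(p) else 0L
  }, by = caseid]
  dt[, date_key := partial_date_key(pd[dt$row, , drop = FALSE], pmax(dt$group_level, 1L))]
  setorder(dt, caseid, -date_key, -pid_num)
  keep_rows <- dt$row[!duplicated(dt$caseid)]
  keep_rows <- keep_rows[order(demo$caseid[keep_rows])]

  demo2 <- demo[keep_rows, , drop = FALSE]
  keep_ids <- demo2$primaryid
  drug2 <- rs$drug[rs$drug$primaryid %in% keep_ids, , drop = FALSE]
  reac2 <- rs$reac[rs$reac$primaryid %in% keep_ids, , drop = FALSE]
  rownames(demo2) <- rownames(drug2) <- rownames(reac2) <- NULL

  provenance <- if (!is.null(rs$provenance)) rs$provenance else
    data.frame(stage = character(0), kept = integer(0), removed = integer(0),
               stringsAsFactors = FALSE)
  provenance <- .add_stage(provenance, "deduplicate",
                           nrow(demo2), nrow(demo) - nrow(demo2))
  structure(list(demo = demo2, drug = drug2, reac = reac2,
                 counters = rs$counters, provenance = provenance),
            class = "case_set")
}

#' Partition a case set into event and non-event cases
#'
#' Flags each unique case as an event case when at least one of its
#' reaction Preferred Terms matches the configured target PT list. Both
#' partitions are retained: non-event cases form the comparator arm of
#' the contingency tables.
#'
#' @param cs a `case_set` from [deduplicate()].
#' @param config a [filter_config()].
#' @return The `case_set` with a logical `is_event` column on `demo`.
#' @export
select_event_cases <- function(cs, config) {
  stopifnot(inherits(cs, "case_set"), inherits(config, "filter_config"))
  hit_ids <- unique(cs$reac$primaryid[cs$reac$pt %in% config$target_pts])
  cs$demo$is_event <- cs$demo$primaryid %in% hit_ids
  cs$provenance <- .add_stage(cs$provenance, "event_partition",
                              nrow(cs$demo), 0L)
  attr(cs, "n_event") <- sum(cs$demo$is_event)
  cs
}

#' Apply reporter filter and drug-eligibility rule
#'
#' Restricts the analysis universe to the configured reporter occupations
#' (unless `config$universe == "all"`), then determines which drugs are
#' eligible for signal analysis: a drug qualifies when it appears in a
#' kept role in at least `min_reports_per_drug` event cases.
#'
#' @param cs a `case_set` that has been through [select_event_cases()].
#' @param config a [filter_config()].
#' @return A list with `cases` (the filtered `case_set`) and
#'   `eligible_drugs` (character vector, ordered by descending event-case
#'   count then name).
#' @export
apply_report_filters <- function(cs, config) {
  stopifnot(inherits(cs, "case_set"))
  if (is.null(cs$demo$is_event)) {
    stop("run select_event_cases() before apply_report_filters()",
         call. = FALSE)
  }
  if (config$universe == "professional") {
    keep <- toupper(cs$demo$occp_cod) %in% config$reporters_kept
    removed <- sum(!keep)
    cs$demo <- cs$demo[keep, , drop = FALSE]
    keep_ids <- cs$demo$primaryid
    cs$drug <- cs$drug[cs$drug$primaryid %in% keep_ids, , drop = FALSE]
    cs$reac <- cs$reac[cs$reac$primaryid %in% keep_ids, , drop = FALSE]
    rownames(cs$demo) <- rownames(cs$drug) <- rownames(cs$reac) <- NULL
    cs$provenance <- .add_stage(cs$provenance, "reporter_filter",
                                nrow(cs$demo), removed)
  } else {
    cs$provenance <- .add_stage(cs$provenance, "reporter_filter",
                                nrow(cs$demo), 0L)
  }

  event_ids <- cs$demo$primaryid[cs$demo$is_event]
  dr <- cs$drug[toupper(cs$drug$role_cod) %in% config$roles_kept &
                  cs$drug$primaryid %in% event_ids, , drop = FALSE]
  # one case counts once per drug, however many rows repeat the pair
  pairs <- unique(paste(dr$primaryid, dr$drugname, sep = "\r"))
  drugs <- sub("^[^\r]*\r", "", pairs)
  counts <- c(table(drugs))
  eligible <- counts[counts >= config$min_reports_per_drug]
  if (length(eligible)) {
    eligible <- eligible[order(-as.integer(eligible), names(eligible))]
  }
  cs$provenance <- .add_stage(cs$provenance, "drug_eligibility",
                              length(eligible), length(counts) - length(eligible))
  list(cases = cs,
       eligible_drugs = if (length(eligible)) names(eligible) else character(0))
}

#' Standardize verbatim drug names to canonical generics
#'
#' Maps verbatim drug names (brand names, salts, spelling variants) to
#' canonical generic names using a two-column synonym table. Matching is
#' case-insensitive on trimmed names; unmapped names pass through
#' verbatim and are counted.
#'
#' @param cs a `report_set` or `case_set`.
#' @param synonym_map data.frame with columns `verbatim` and `canonical`
#'   (see [read_synonym_map()]).
#' @return The input object with `drug$drugname` standardized and an
#'   `n_unmapped` entry added to its counters.
#' @export
standardize_drug_names <- function(cs, synonym_map) {
  stopifnot(all(c("verbatim", "canonical") %in% names(synonym_map)))
  key <- tolower(trimws(cs$drug$drugname))
  idx <- match(key, tolower(trimws(synonym_map$verbatim)))
  hit <- !is.na(idx)
  cs$drug$drugname[hit] <- synonym_map$canonical[idx[hit]]
  cs$counters$n_unmapped <- sum(!hit & nzchar(key))
  cs
}

#' Read a two-column synonym map (verbatim, canonical) from CSV
#' @param path CSV path with header `verbatim,canonical`.
#' @return data.frame.
#' @export
read_synonym_map <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("verbatim", "canonical") %in% names(map)))
  map
}

#' @export
print.case_set <- function(x, ...) {
  cat("<case_set>", nrow(x$demo), "unique cases")
  if (!is.null(x$demo$is_event)) cat(",", sum(x$demo$is_event), "event cases")
  cat("\n")
  if (!is.null(x$provenance) && nrow(x$provenance)) {
    cat("  provenance:\n")
    for (i in seq_len(nrow(x$provenance))) {
      cat(sprintf("    %-18s kept=%d removed=%d\n", x$provenance$stage[i],
                  x$provenance$kept[i], x$provenance$removed[i]))
    }
  }
  invisible(x)
}
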