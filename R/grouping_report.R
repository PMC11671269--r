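#' Read a drug class map (ATC class + target class) from CSV
#'
#' @param path CSV with header `drug,atc_class,target_class`.
#' @return data.frame.
#' @export
read_class_map <- function(path) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("drug", "atc_class", "target_class") %in% names(map)))
  map
}

#' Bundled class map for established RVO-risk drugs
#'
#' ATC-level therapeutic classes and pharmacological target classes for
#' the 25 drugs with published RVO disproportionality signals. Users
#' analysing other drugs supply their own map via [read_class_map()].
#'
#' @return data.frame with `drug`, `atc_class`, `target_class`.
#' @export
rvo_class_map <- function() {
  read_class_map(system.file("extdata", "rvo_class_map.csv",
                             package = "rvosignal", mustWork = TRUE))
}

#' Bundled brand/verbatim to generic synonym map
#' @return data.frame with `verbatim`, `canonical`.
#' @export
rvo_synonym_map <- function() {
  read_synonym_map(system.file("extdata", "rvo_synonym_map.csv",
                               package = "rvosignal", mustWork = TRUE))
}

#' Published reference signal statistics for RVO-risk drugs
#'
#' Signal statistics for 25 drugs associated with retinal vein occlusion
#' as printed in a published FAERS disproportionality study (reporting
#' odds ratio with 95% CI, PRR with chi-square, crude EBGM with EBGM05,
#' and information component with its lower bound). These are data, not
#' package output: they serve as inputs for checking the analytic
#' identities that hold among the printed columns (Wald log-symmetry,
#' `IC = log2(EBGM)`, EBGM05 reconstruction).
#'
#' @return data.frame, one row per drug.
#' @export
rvo_published_signals <- function() {
  utils::read.csv(system.file("extdata", "rvo_published_signals.csv",
                              package = "rvosignal", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Annotate drugs with ATC and target classes
#'
#' @param drugs character vector of canonical drug names.
#' @param map data.frame from [read_class_map()] / [rvo_class_map()].
#' @return data.frame with `drug`, `atc_class`, `target_class`;
#'   unresolved drugs are annotated `"unclassified"` and listed in the
#'   `unresolved` attribute rather than dropped.
#' @export
assign_classes <- function(drugs, map = rvo_class_map()) {
  idx <- match(tolower(drugs), tolower(map$drug))
  out <- data.frame(
    drug = drugs,
    atc_class = ifelse(is.na(idx), "unclassified", map$atc_class[idx]),
    target_class = ifelse(is.na(idx), "unclassified", map$target_class[idx]),
    stringsAsFactors = FALSE
  )
  attr(out, "unresolved") <- drugs[is.na(idx)]
  out
}

.pct_block <- function(counts, denom) {
  data.frame(level = names(counts), n = as.integer(counts),
             pct = 100 * as.integer(counts) / denom,
             stringsAsFactors = FALSE)
}

#' Descriptive summary of a case set
#'
#' Continuous variables (age in years, weight in kg) are summarized as
#' mean, SD, median and quartiles over non-missing values. Categorical
#' blocks are counts with percentages: sex and country percentages use
#' the case count as denominator; outcome percentages use the total
#' number of outcome entries (cases with a recorded outcome), the
#' convention under which published outcome shares reconcile. Yearly
#' report counts are split by sex using the FDA receipt year.
#'
#' @param cs a `case_set`.
#' @return list of class `descriptive_summary`.
#' @export
summarize_cases <- function(cs) {
  demo <- cs$demo
  n <- nrow(demo)
  num_block <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(list(mean = NA, sd = NA, median = NA,
                                q1 = NA, q3 = NA, n = 0L))
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7)
    list(mean = mean(x), sd = sd(x), median = unname(q[2]),
         q1 = unname(q[1]), q3 = unname(q[3]), n = length(x))
  }
  sex <- toupper(demo$sex)
  sex[!sex %in% c("F", "M")] <- "UNK"
  sex_counts <- table(factor(sex, levels = c("F", "M", "UNK")))

  outc <- toupper(demo$outc_cod)
  outc <- outc[nzchar(outc) & !is.na(outc)]
  outc_counts <- sort(table(outc), decreasing = TRUE)

  country <- demo$occr_country
  country[is.na(country) | !nzchar(country)] <- "UNK"
  country_counts <- sort(table(country), decreasing = TRUE)

  occp <- toupper(demo$occp_cod)
  occp[is.na(occp) | !nzchar(occp)] <- "UNK"
  occp_counts <- sort(table(occp), decreasing = TRUE)

  fda_pd <- suppressWarnings(parse_partial_date(demo$fda_dt))
  yearly <- table(year = fda_pd$year, sex = sex)

  structure(list(
    n_cases = n,
    age = num_block(demo$age),
    weight = num_block(demo$wt),
    sex = .pct_block(sex_counts, n),
    outcome = .pct_block(outc_counts, sum(outc_counts)),
    country = .pct_block(country_counts, n),
    reporter = .pct_block(occp_counts, n),
    yearly = as.data.frame(yearly, stringsAsFactors = FALSE)
  ), class = "descriptive_summary")
}

#' @export
print.descriptive_summary <- function(x, ...) {
  cat("<descriptive_summary>", x$n_cases, "cases\n")
  cat(sprintf("  age: %.1f +/- %.1f (median %.0f [%.0f, %.0f], n=%d)\n",
              x$age$mean, x$age$sd, x$age$median, x$age$q1, x$age$q3,
              x$age$n))
  lead <- x$outcome[which.max(x$outcome$n), , drop = FALSE]
  if (nrow(lead)) {
    cat(sprintf("  leading outcome: %s %d (%.1f%%)\n",
                lead$level, lead$n, lead$pct))
  }
  invisible(x)
}

#' Export all pipeline result tables
#'
#' Writes the signal table (full numeric and formatted report-style
#' versions), forest-plot data (estimate/low/high per drug), onset
#' summary, KM curves, descriptive summary (JSON) and a run manifest.
#' Outputs are byte-identical for identical inputs and manifest: nothing
#' time- or locale-dependent is written.
#'
#' @param signals data.frame from [signal_table()] (all drugs).
#' @param onsets data.frame from [onset_summary()], or NULL.
#' @param curves data.frame from [km_estimate()], or NULL.
#' @param summary a `descriptive_summary`, or NULL.
#' @param out_dir output directory.
#' @param classes optional [assign_classes()] result for the formatted
#'   signal table.
#' @param manifest list of run metadata (config, seed, stage counts).
#' @return Invisibly, the character vector of files written.
#' @export
export_results <- function(signals, onsets = NULL, curves = NULL,
                           summary = NULL, out_dir, classes = NULL,
                           manifest = list()) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  files <- character(0)
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  w(signals, "signal_table.csv")
  w(format_signal_table(signals, classes = classes), "signal_report.csv")
  forest <- data.frame(drug = signals$drug, estimate = signals$ror,
                       low = signals$ror_ci_low, high = signals$ror_ci_high,
                       stringsAsFactors = FALSE)
  w(forest, "forest_ror.csv")
  if (!is.null(onsets)) w(onsets, "onset_summary.csv")
  if (!is.null(curves)) w(curves, "km_curves.csv")
  if (!is.null(summary)) {
    p <- file.path(out_dir, "case_summary.json")
    jsonlite::write_json(unclass(summary), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <- c(files, p)
  }
  p <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, p)
  invisible(files)
}
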