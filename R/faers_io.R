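#' @section FAERS quarterly dialect:
#' The public quarterly ASCII files are "$"-delimited with one header line
#' and no quoting. This package reads a trimmed dialect of the four tables
#' it needs (lower-case headers; the outcome code is carried on DEMO):
#'
#' * `DEMO`: `primaryid, caseid, fda_dt, event_dt, age, sex, wt, occp_cod,
#'    occr_country, outc_cod`
#' * `DRUG`: `primaryid, caseid, drug_seq, role_cod, drugname`
#' * `THER`: `primaryid, caseid, dsg_drug_seq, start_dt`
#' * `REAC`: `primaryid, caseid, pt`
#'
#' Extra columns are kept; only `primaryid` and `caseid` are mandatory.
#' @name faers-dialect
NULL

.faers_tables <- c("DEMO", "DRUG", "REAC", "THER")

.guess_table_name <- function(path) {
  base <- toupper(basename(path))
  hit <- .faers_tables[vapply(.faers_tables, function(t) startsWith(base, t),
                              logical(1))]
  if (length(hit) != 1L) {
    stop("cannot infer table type (DEMO/DRUG/REAC/THER) from file name: ",
         basename(path), call. = FALSE)
  }
  hit
}

.read_faers_file <- function(path, delim = "$") {
  con <- file(path, open = "r", encoding = "latin1")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) == 0L) {
    warning("empty file: ", basename(path), call. = FALSE)
    return(list(table = data.frame(), malformed = 0L))
  }
  header <- tolower(strsplit(lines[[1L]], delim, fixed = TRUE)[[1L]])
  header <- trimws(header)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    warning("no data rows in file: ", basename(path), call. = FALSE)
    tab <- as.data.frame(setNames(rep(list(character(0)), length(header)),
                                  header), stringsAsFactors = FALSE)
    return(list(table = tab, malformed = 0L))
  }
  parts <- strsplit(body, delim, fixed = TRUE)
  # a trailing empty field is dropped by strsplit; pad back to header length
  nf <- lengths(parts)
  pad <- nf == length(header) - 1L & endsWith(body, delim)
  parts[pad] <- lapply(parts[pad], function(p) c(p, ""))
  nf[pad] <- nf[pad] + 1L
  ok <- nf == length(header)
  malformed <- sum(!ok)
  mat <- matrix(unlist(parts[ok], use.names = FALSE),
                ncol = length(header), byrow = TRUE)
  tab <- as.data.frame(mat, stringsAsFactors = FALSE)
  names(tab) <- header
  list(table = tab, malformed = malformed)
}

#' Read one quarter of FAERS-style ASCII tables
#'
#' Reads the DEMO/DRUG/REAC/THER files of one quarter. Table types are
#' inferred from the file-name prefix (`DEMO23Q1.txt` etc., case
#' insensitive). Lines whose field count does not match the header are
#' excluded and counted as malformed, never silently dropped. Files are
#' decoded as Latin-1 (the legacy encoding of the public files).
#'
#' @param paths character vector of file paths (any subset/order of the
#'   four tables).
#' @param delim field delimiter, `"$"` in the public dialect.
#' @return An object of class `faers_quarter`: a list with `tables`
#'   (named list of data.frames), `malformed` (named integer counts) and
#'   `files`.
#' @export
read_quarter <- function(paths, delim = "$") {
  stopifnot(length(paths) >= 1L)
  tables <- list()
  malformed <- integer(0)
  files <- character(0)
  for (p in paths) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
    nm <- .guess_table_name(p)
    res <- .read_faers_file(p, delim = delim)
    if (nrow(res$table) > 0L || ncol(res$table) > 0L) {
      missing_cols <- setdiff(c("primaryid", "caseid"), names(res$table))
      if (length(missing_cols) > 0L) {
        stop(sprintf("file %s (%s) lacks mandatory column(s): %s",
                     basename(p), nm, paste(missing_cols, collapse = ", ")),
             call. = FALSE)
      }
    }
    tables[[nm]] <- res$table
    malformed[nm] <- res$malformed
    files[nm] <- p
  }
  structure(list(tables = tables, malformed = malformed, files = files),
            class = "faers_quarter")
}

#' Write FAERS-style quarterly ASCII tables
#'
#' Inverse of [read_quarter()]: writes each table as a "$"-delimited file
#' `<TABLE><quarter>.txt` with one header line. `NA` values are written
#' as empty fields.
#'
#' @param tables named list of data.frames (names among DEMO, DRUG, REAC,
#'   THER), or a `faers_quarter`.
#' @param dir output directory (created if needed).
#' @param quarter quarter tag used in file names, e.g. `"23Q1"`.
#' @param delim field delimiter.
#' @return Invisibly, the named vector of written file paths.
#' @export
write_quarter <- function(tables, dir, quarter = "23Q1", delim = "$") {
  if (inherits(tables, "faers_quarter")) tables <- tables$tables
  stopifnot(is.list(tables), all(names(tables) %in% .faers_tables))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    p <- file.path(dir, paste0(nm, quarter, ".txt"))
    cells <- vapply(tab, function(col) {
      col <- as.character(col)
      col[is.na(col)] <- ""
      col
    }, character(nrow(tab)))
    if (nrow(tab) == 1L) cells <- matrix(cells, nrow = 1L)
    lines <- c(paste(names(tab), collapse = delim),
               if (nrow(tab) > 0L) apply(cells, 1L, paste, collapse = delim))
    con <- file(p, open = "w", encoding = "latin1")
    writeLines(lines, con = con)
    close(con)
    paths[nm] <- p
  }
  invisible(paths)
}

#' Join raw quarterly tables into a report set
#'
#' Produces one record per DEMO row (one spontaneous report), attaching
#' DRUG, REAC and THER rows by `primaryid`. Therapy start dates from THER
#' are attached to the drug whose sequence number matches
#' (`dsg_drug_seq == drug_seq`); THER rows with no matching sequence fall
#' back to the report's first primary-suspect drug. Duplicate DEMO
#' `primaryid`s keep the first row (the rest are counted), and DRUG/REAC/
#' THER rows whose `primaryid` is absent from DEMO are excluded and
#' counted as orphans.
#'
#' @param quarter a `faers_quarter` from [read_quarter()], or a named list
#'   of data.frames.
#' @return An object of class `report_set`: list with data.frames `demo`,
#'   `drug`, `reac` and a `counters` list accounting for every discarded
#'   row.
#' @export
join_records <- function(quarter) {
  tables <- if (inherits(quarter, "faers_quarter")) quarter$tables else quarter
  if (is.null(tables$DEMO)) stop("DEMO table is required", call. = FALSE)
  demo <- tables$DEMO
  counters <- list(
    malformed = if (inherits(quarter, "faers_quarter")) sum(quarter$malformed) else 0L,
    dup_demo_primaryid = 0L, orphan_drug = 0L, orphan_reac = 0L,
    orphan_ther = 0L, ther_unmatched = 0L
  )

  dup <- duplicated(demo$primaryid)
  counters$dup_demo_primaryid <- sum(dup)
  demo <- demo[!dup, , drop = FALSE]

  for (col in c("fda_dt", "event_dt", "sex", "occp_cod", "occr_country",
                "outc_cod")) {
    if (is.null(demo[[col]])) demo[[col]] <- ""
  }
  demo$age <- if (is.null(demo$age)) NA_real_ else
    suppressWarnings(as.numeric(demo$age))
  demo$wt <- if (is.null(demo$wt)) NA_real_ else
    suppressWarnings(as.numeric(demo$wt))

  keep_ids <- demo$primaryid

  drug <- tables$DRUG
  if (is.null(drug) || nrow(drug) == 0L) {
    drug <- data.frame(primaryid = character(0), caseid = character(0),
                       drug_seq = character(0), role_cod = character(0),
                       drugname = character(0), stringsAsFactors = FALSE)
  }
  known <- drug$primaryid %in% keep_ids
  counters$orphan_drug <- sum(!known)
  drug <- drug[known, , drop = FALSE]
  if (is.null(drug$drug_seq)) drug$drug_seq <- "1"
  if (is.null(drug$role_cod)) drug$role_cod <- ""
  if (is.null(drug$drugname)) drug$drugname <- ""
  drug$start_dt <- ""

  ther <- tables$THER
  if (!is.null(ther) && nrow(ther) > 0L) {
    known <- ther$primaryid %in% keep_ids
    counters$orphan_ther <- sum(!known)
    ther <- ther[known, , drop = FALSE]
    if (is.null(ther$dsg_drug_seq)) ther$dsg_drug_seq <- "1"
    if (is.null(ther$start_dt)) ther$start_dt <- ""
    seq_match <- match(paste(ther$primaryid, ther$dsg_drug_seq, sep = "\r"),
                       paste(drug$primaryid, drug$drug_seq, sep = "\r"))
    hit <- !is.na(seq_match)
    drug$start_dt[seq_match[hit]] <- ther$start_dt[hit]
    # fall back to the report's first primary-suspect drug
    if (any(!hit)) {
      ps_idx <- which(toupper(drug$role_cod) == "PS")
      ps_first <- ps_idx[!duplicated(drug$primaryid[ps_idx])]
      fb <- match(ther$primaryid[!hit], drug$primaryid[ps_first])
      target <- ps_first[fb[!is.na(fb)]]
      src <- which(!hit)[!is.na(fb)]
      blank <- !nzchar(drug$start_dt[target])
      drug$start_dt[target[blank]] <- ther$start_dt[src[blank]]
      counters$ther_unmatched <- sum(is.na(fb))
    }
  }

  reac <- tables$REAC
  if (is.null(reac) || nrow(reac) == 0L) {
    reac <- data.frame(primaryid = character(0), caseid = character(0),
                       pt = character(0), stringsAsFactors = FALSE)
  }
  known <- reac$primaryid %in% keep_ids
  counters$orphan_reac <- sum(!known)
  reac <- reac[known, , drop = FALSE]
  if (is.null(reac$pt)) reac$pt <- ""

  rownames(demo) <- rownames(drug) <- rownames(reac) <- NULL
  structure(list(demo = demo,
                 drug = drug[, c("primaryid", "caseid", "drug_seq",
                                 "role_cod", "drugname", "start_dt")],
                 reac = reac[, c("primaryid", "caseid", "pt")],
                 counters = counters),
            class = "report_set")
}

#' @export
print.report_set <- function(x, ...) {
  cat("<report_set>", nrow(x$demo), "reports,",
      nrow(x$drug), "drug rows,", nrow(x$reac), "reaction rows\n")
  dropped <- unlist(x$counters)
  dropped <- dropped[dropped > 0]
  if (length(dropped)) {
    cat("  discarded rows:",
        paste(names(dropped), dropped, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
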