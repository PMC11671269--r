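#' Parse FAERS-style partial dates
#'
#' FAERS date fields come in three precisions: `YYYY` (year only),
#' `YYYYMM` (year and month) and `YYYYMMDD` (full day). Empty strings mean
#' the date was not reported. Anything else (wrong length, non-digits,
#' impossible month or day) is treated as absent and counted.
#'
#' @param x character vector of raw date strings.
#' @return A data.frame with columns `raw`, `year`, `month`, `day`
#'   (integer, `NA` where unknown) and `precision` (one of `"day"`,
#'   `"month"`, `"year"`, `"none"`), with attribute `n_invalid` giving the
#'   number of non-empty strings that failed to parse.
#' @examples
#' parse_partial_date(c("20230415", "202304", "2023", "", "20231345"))
#' @export
parse_partial_date <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  raw <- trimws(x)
  n <- length(raw)
  year <- month <- day <- rep(NA_integer_, n)
  precision <- rep("none", n)

  digits_only <- grepl("^[0-9]+$", raw)
  nc <- nchar(raw)

  y_ok <- digits_only & nc == 4L
  ym_ok <- digits_only & nc == 6L
  ymd_ok <- digits_only & nc == 8L

  year[y_ok] <- as.integer(raw[y_ok])
  precision[y_ok] <- "year"

  if (any(ym_ok)) {
    yy <- as.integer(substr(raw[ym_ok], 1L, 4L))
    mm <- as.integer(substr(raw[ym_ok], 5L, 6L))
    good <- mm >= 1L & mm <= 12L
    idx <- which(ym_ok)
    year[idx[good]] <- yy[good]
    month[idx[good]] <- mm[good]
    precision[idx[good]] <- "month"
  }

  if (any(ymd_ok)) {
    idx <- which(ymd_ok)
    d <- as.Date(raw[ymd_ok], format = "%Y%m%d")
    good <- !is.na(d)
    year[idx[good]] <- as.integer(format(d[good], "%Y"))
    month[idx[good]] <- as.integer(format(d[good], "%m"))
    day[idx[good]] <- as.integer(format(d[good], "%d"))
    precision[idx[good]] <- "day"
  }

  n_invalid <- sum(nc > 0L & precision == "none")
  if (n_invalid > 0L) {
    warning(sprintf("%d date string(s) could not be parsed and were treated as absent",
                    n_invalid), call. = FALSE)
  }
  out <- data.frame(raw = raw, year = year, month = month, day = day,
                    precision = precision, stringsAsFactors = FALSE)
  attr(out, "n_invalid") <- n_invalid
  out
}

#' Numeric precision rank of a parsed partial date
#'
#' 3 = day, 2 = month, 1 = year, 0 = absent.
#' @param pd data.frame from [parse_partial_date()].
#' @return integer vector.
#' @export
date_precision_rank <- function(pd) {
  match(pd$precision, c("none", "year", "month", "day")) - 1L
}

#' Comparable sort key for partial dates at a chosen precision
#'
#' Truncates each date to `level` (1 = year, 2 = month, 3 = day) and packs
#' it into a single integer (`year*10000 + month*100 + day`, with truncated
#' parts zero). Absent dates get key -1, i.e. earlier than any real date.
#' Comparing a group of dates at the coarsest precision present in the
#' group implements the rule that a year-only date never counts as later
#' (or earlier) than a full date in the same year: they tie.
#'
#' @param pd data.frame from [parse_partial_date()].
#' @param level integer (scalar or vector) precision level to compare at.
#' @return numeric key vector.
#' @export
partial_date_key <- function(pd, level = 3L) {
  level <- as.integer(level)
  y <- ifelse(is.na(pd$year), 0L, pd$year)
  m <- ifelse(is.na(pd$month) | level < 2L, 0L, pd$month)
  d <- ifelse(is.na(pd$day) | level < 3L, 0L, pd$day)
  key <- y * 10000 + m * 100 + d
  key[pd$precision == "none"] <- -1
  key
}

#' Convert parsed partial dates to Date
#'
#' Day-precision entries convert exactly. Month-precision entries are
#' imputed to mid-month (day 15) when `impute_month = TRUE`, otherwise
#' dropped to `NA`. Year-only and absent entries are always `NA`.
#'
#' @param pd data.frame from [parse_partial_date()].
#' @param impute_month impute month-precision dates to day 15?
#' @return Date vector.
#' @export
partial_date_as_date <- function(pd, impute_month = FALSE) {
  out <- rep(as.Date(NA), nrow(pd))
  full <- pd$precision == "day"
  out[full] <- as.Date(sprintf("%04d-%02d-%02d",
                               pd$year[full], pd$month[full], pd$day[full]))
  if (impute_month) {
    mo <- pd$precision == "month"
    out[mo] <- as.Date(sprintf("%04d-%02d-15", pd$year[mo], pd$month[mo]))
  }
  out
}
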