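#' Specification of a synthetic spontaneous-report universe
#'
#' Defines the study conditions for a simulated FAERS-style universe:
#' per-case one primary-suspect drug drawn from exposure margins, a
#' target-event occurrence with probability `min(1, lift * p0)` for the
#' case's drug, 1-3 filler reaction PTs, demographics and reporter
#' occupation, therapy-start and event dates, case duplication (the same
#' case retransmitted under a new PRIMARYID and earlier FDA date), and
#' missing therapy-start dates. A lift of 1 means no association
#' (the null) for that drug.
#'
#' @param n_cases number of unique cases.
#' @param drugs data.frame with columns `name`, `exposure` (relative
#'   exposure margin, normalized internally) and `lift` (reporting-rate
#'   multiplier for the target event, >= 0; 1 = null).
#' @param p0 baseline probability that a case's report concerns the
#'   target event.
#' @param duplicate_rate fraction of cases emitted as two reports
#'   sharing a CASEID.
#' @param reporter_mix named occupation probabilities (FAERS codes).
#' @param missing_date_rate fraction of cases whose therapy-start date
#'   is absent.
#' @param second_suspect_rate fraction of cases with a second
#'   primary-suspect drug (off by default; used to exercise multi-drug
#'   contingency counting).
#' @param onset data.frame with columns `drug`, `family`
#'   (`"exponential"`, `"lognormal"` or `"weibull"`), `median` (days) and
#'   `shape` (sdlog for lognormal, shape for weibull; ignored for
#'   exponential). Drugs without a row get the exponential default with
#'   median 180 days.
#' @param date_window character or Date vector of length 2: therapy
#'   starts are uniform in this window.
#' @param target_pt MedDRA PT code planted as the target event reaction.
#' @param seed integer seed making the universe fully reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cases, drugs, p0,
                           duplicate_rate = 0.3,
                           reporter_mix = c(MD = 0.47, CN = 0.22,
                                            PH = 0.12, OT = 0.09,
                                            LW = 0.02, UNK = 0.08),
                           missing_date_rate = 0.2,
                           second_suspect_rate = 0,
                           onset = NULL,
                           date_window = c("2004-01-01", "2023-12-31"),
                           target_pt = "10038907",
                           seed = NULL) {
  stopifnot(is.data.frame(drugs),
            all(c("name", "exposure", "lift") %in% names(drugs)),
            n_cases >= 1, p0 > 0, p0 <= 1,
            duplicate_rate >= 0, duplicate_rate < 1,
            missing_date_rate >= 0, missing_date_rate <= 1,
            second_suspect_rate >= 0, second_suspect_rate <= 1,
            all(drugs$lift >= 0), all(drugs$exposure > 0),
            abs(sum(reporter_mix) - 1) < 1e-8)
  drugs$exposure <- drugs$exposure / sum(drugs$exposure)
  expected_a <- n_cases * drugs$exposure * pmin(1, drugs$lift * p0)
  bad <- drugs$lift > 1 & expected_a < 1
  if (any(bad)) {
    stop("infeasible spec: expected event-case count < 1 for planted drug(s): ",
         paste(drugs$name[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(n_cases = as.integer(n_cases), drugs = drugs, p0 = p0,
                 duplicate_rate = duplicate_rate,
                 reporter_mix = reporter_mix,
                 missing_date_rate = missing_date_rate,
                 second_suspect_rate = second_suspect_rate,
                 onset = onset, date_window = as.Date(date_window),
                 target_pt = as.character(target_pt), seed = seed),
            class = "synthetic_spec")
}

#' Read a synthetic spec from a plain-text (YAML) file
#' @param path YAML file with the fields of [synthetic_spec()]; `drugs`
#'   and `onset` as lists of records.
#' @return A `synthetic_spec`.
#' @export
read_synthetic_spec <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$drugs <- do.call(rbind, lapply(cfg$drugs, as.data.frame))
  if (!is.null(cfg$onset)) {
    cfg$onset <- do.call(rbind, lapply(cfg$onset, as.data.frame))
  }
  if (!is.null(cfg$reporter_mix)) cfg$reporter_mix <- unlist(cfg$reporter_mix)
  do.call(synthetic_spec, cfg)
}

.default_onset_medians <- c(
  "Urogenital System and Sex Hormone Drugs" = 210,
  "Sensory Organ Drugs" = 532,
  "Nervous System Drugs" = 266,
  "Musculoskeletal System Drugs" = 180,
  "Antitumor and Immunomodulating Drugs" = 201,
  "Antiparasitic Drugs" = 363
)

.planted_lifts <- c(
  mirabegron = 80, raloxifene = 67, tadalafil = 36, fingolimod = 30,
  bimatoprost = 27, sildenafil = 26, brimonidine = 25, vardenafil = 22,
  verteporfin = 20, celecoxib = 20, sorafenib = 19, anastrozole = 16,
  drospirenone = 11, hydroxychloroquine = 10, upadacitinib = 10,
  encorafenib = 9, ponatinib = 9, "peginterferon beta-1a" = 8,
  aripiprazole = 8, estradiol = 7, letrozole = 6, vemurafenib = 6,
  dabrafenib = 5, tacrolimus = 4, rofecoxib = 4
)

.background_drugs <- c(
  "metformin", "lisinopril", "atorvastatin", "omeprazole", "amlodipine",
  "levothyroxine", "ibuprofen", "paracetamol", "sertraline", "warfarin",
  "gabapentin", "amoxicillin", "prednisone", "insulin glargine",
  "salbutamol"
)

#' Desk-scale synthetic study conditions
#'
#' A 50,000-case universe with the 25 established RVO-risk drugs planted
#' at reporting-rate lifts graded from 4 to 80 (roughly tracking their
#' published signal strength) plus 15 null background drugs, baseline
#' event probability 0.005, 30% case duplication and 20% missing
#' therapy-start dates. Per-drug onset distributions are exponential
#' with the published per-class median induction times. With
#' `null = TRUE` every lift is set to 1, giving a no-association universe
#' for calibration runs.
#'
#' @param seed integer seed.
#' @param null set all lifts to 1?
#' @return A `synthetic_spec`.
#' @export
desk_spec <- function(seed = 1L, null = FALSE) {
  planted <- names(.planted_lifts)
  cm <- rvo_class_map()
  med <- .default_onset_medians[cm$atc_class[match(planted, cm$drug)]]
  med[is.na(med)] <- 180
  drugs <- data.frame(
    name = c(planted, .background_drugs),
    exposure = c(rep(0.004, length(planted)),
                 rep(0.9 / length(.background_drugs), length(.background_drugs))),
    lift = if (null) 1 else c(unname(.planted_lifts),
                              rep(1, length(.background_drugs))),
    stringsAsFactors = FALSE
  )
  onset <- data.frame(
    drug = drugs$name,
    family = "exponential",
    median = c(unname(med), rep(180, length(.background_drugs))),
    shape = NA_real_,
    stringsAsFactors = FALSE
  )
  synthetic_spec(n_cases = 50000L, drugs = drugs, p0 = 0.005,
                 onset = onset, seed = seed)
}

#' Full-scale synthetic study conditions
#'
#' The same construction as [desk_spec()] scaled towards the size of the
#' real extract that motivates the pipeline: 1.5 million cases, the 25
#' planted drugs plus 180 null background drugs, and a baseline event
#' probability of 0.0015 so that the expected number of target-event
#' cases is in the low thousands. Intended for one-off power studies,
#' not for routine test runs.
#'
#' @param seed integer seed.
#' @return A `synthetic_spec`.
#' @export
paper_spec <- function(seed = 1L) {
  planted <- names(.planted_lifts)
  cm <- rvo_class_map()
  med <- .default_onset_medians[cm$atc_class[match(planted, cm$drug)]]
  med[is.na(med)] <- 180
  bg <- sprintf("background_%03d", seq_len(180))
  drugs <- data.frame(
    name = c(planted, bg),
    exposure = c(rep(0.002, length(planted)), rep(0.95 / 180, 180)),
    lift = c(unname(.planted_lifts), rep(1, 180)),
    stringsAsFactors = FALSE
  )
  onset <- data.frame(drug = drugs$name, family = "exponential",
                      median = c(unname(med), rep(180, 180)),
                      shape = NA_real_, stringsAsFactors = FALSE)
  synthetic_spec(n_cases = 1500000L, drugs = drugs, p0 = 0.0015,
                 onset = onset, seed = seed)
}

.sample_onsets <- function(drug_names, onset) {
  n <- length(drug_names)
  fam <- rep("exponential", n)
  med <- rep(180, n)
  shp <- rep(NA_real_, n)
  if (!is.null(onset)) {
    idx <- match(drug_names, onset$drug)
    hit <- !is.na(idx)
    fam[hit] <- onset$family[idx[hit]]
    med[hit] <- onset$median[idx[hit]]
    shp[hit] <- if (is.null(onset$shape)) NA_real_ else onset$shape[idx[hit]]
  }
  out <- numeric(n)
  e <- fam == "exponential"
  out[e] <- rexp(sum(e), rate = log(2) / med[e])
  l <- fam == "lognormal"
  if (any(l)) {
    s <- ifelse(is.na(shp[l]), 1, shp[l])
    out[l] <- rlnorm(sum(l), meanlog = log(med[l]), sdlog = s)
  }
  w <- fam == "weibull"
  if (any(w)) {
    k <- ifelse(is.na(shp[w]), 1.5, shp[w])
    out[w] <- rweibull(sum(w), shape = k,
                       scale = med[w] / log(2)^(1 / k))
  }
  pmax(1L, as.integer(round(out)))
}

#' Generate a synthetic spontaneous-report universe
#'
#' Draws a universe from a [synthetic_spec()] and returns both the
#' FAERS-dialect quarterly tables (consumable by [join_records()] or
#' [write_quarter()]) and the exact ground truth: the per-case drug,
#' event and occupation assignments after ideal deduplication, the
#' planted missing-date count and the duplicate count. Fully
#' reproducible from the seed.
#'
#' @param spec a [synthetic_spec()].
#' @param seed overrides `spec$seed`.
#' @return An object of class `synthetic_universe`: list with `tables`
#'   (named list DEMO/DRUG/REAC/THER of data.frames) and `truth` (list
#'   with `cases` data.frame, counts, and the spec).
#' @export
synth_generate <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(seed)) stop("a seed is required (spec$seed or seed=)",
                          call. = FALSE)
  set.seed(as.integer(seed))
  n <- spec$n_cases
  K <- nrow(spec$drugs)

  caseid <- as.character(10000000 + seq_len(n))
  primaryid <- paste0(caseid, "2")

  didx <- sample.int(K, n, replace = TRUE, prob = spec$drugs$exposure)
  drug <- spec$drugs$name[didx]
  p_event <- pmin(1, spec$drugs$lift[didx] * spec$p0)
  is_event <- runif(n) < p_event

  drug2 <- rep(NA_character_, n)
  if (spec$second_suspect_rate > 0) {
    has2 <- runif(n) < spec$second_suspect_rate
    d2 <- sample.int(K, sum(has2), replace = TRUE, prob = spec$drugs$exposure)
    drug2[has2] <- spec$drugs$name[d2]
    same <- !is.na(drug2) & drug2 == drug
    drug2[same] <- NA_character_
  }

  occp <- sample(names(spec$reporter_mix), n, replace = TRUE,
                 prob = spec$reporter_mix)
  sex <- sample(c("F", "M", ""), n, replace = TRUE,
                prob = c(0.506, 0.395, 0.099))
  age <- round(pmin(100, pmax(18, rnorm(n, 58.8, 16.9))))
  wt <- round(pmin(160, pmax(35, rnorm(n, 70.5, 21.2))))
  country <- sample(c("US", "JP", "FR", "GB", "DE", "CA", "CN", "IT", "ES",
                      "OTHER"), n, replace = TRUE,
                    prob = c(0.344, 0.145, 0.107, 0.074, 0.056, 0.032,
                             0.019, 0.014, 0.01, 0.199))
  outc <- sample(c("OT", "DS", "HO", "DE", "LT"), n, replace = TRUE,
                 prob = c(0.739, 0.129, 0.113, 0.011, 0.007))

  window_days <- as.integer(diff(spec$date_window))
  start <- spec$date_window[1] + sample.int(window_days + 1L, n,
                                            replace = TRUE) - 1L
  onset_days <- .sample_onsets(drug, spec$onset)
  event_date <- start + onset_days
  fda_date <- event_date + sample(31:90, n, replace = TRUE)
  start_missing <- runif(n) < spec$missing_date_rate

  fmt <- function(d) format(d, "%Y%m%d")

  demo <- data.frame(
    primaryid = primaryid, caseid = caseid, fda_dt = fmt(fda_date),
    event_dt = fmt(event_date), age = as.character(age), sex = sex,
    wt = as.character(wt), occp_cod = occp, occr_country = country,
    outc_cod = outc, stringsAsFactors = FALSE
  )
  drug_tab <- data.frame(
    primaryid = primaryid, caseid = caseid, drug_seq = "1",
    role_cod = "PS", drugname = toupper(drug), stringsAsFactors = FALSE
  )
  ther <- data.frame(
    primaryid = primaryid, caseid = caseid, dsg_drug_seq = "1",
    start_dt = ifelse(start_missing, "", fmt(start)),
    stringsAsFactors = FALSE
  )
  has2 <- !is.na(drug2)
  if (any(has2)) {
    drug_tab <- rbind(drug_tab, data.frame(
      primaryid = primaryid[has2], caseid = caseid[has2], drug_seq = "2",
      role_cod = "PS", drugname = toupper(drug2[has2]),
      stringsAsFactors = FALSE))
    ther <- rbind(ther, data.frame(
      primaryid = primaryid[has2], caseid = caseid[has2],
      dsg_drug_seq = "2",
      start_dt = ifelse(start_missing[has2], "", fmt(start[has2])),
      stringsAsFactors = FALSE))
  }

  n_fill <- sample(1:3, n, replace = TRUE)
  filler_pool <- sprintf("100%05d", 1:60)
  fill_pid <- rep(primaryid, n_fill)
  fill_cid <- rep(caseid, n_fill)
  fill_pt <- sample(filler_pool, sum(n_fill), replace = TRUE)
  reac <- data.frame(primaryid = fill_pid, caseid = fill_cid, pt = fill_pt,
                     stringsAsFactors = FALSE)
  if (any(is_event)) {
    reac <- rbind(reac, data.frame(primaryid = primaryid[is_event],
                                   caseid = caseid[is_event],
                                   pt = spec$target_pt,
                                   stringsAsFactors = FALSE))
  }

  n_dup <- floor(spec$duplicate_rate * n)
  if (n_dup > 0) {
    dup_idx <- sample.int(n, n_dup)
    dup_pid <- paste0(caseid[dup_idx], "1")
    dup_fda <- fmt(event_date[dup_idx] + sample(1:30, n_dup, replace = TRUE))
    dmap <- function(df) {
      rows <- df[df$primaryid %in% primaryid[dup_idx], , drop = FALSE]
      rows$primaryid <- dup_pid[match(rows$primaryid, primaryid[dup_idx])]
      rows
    }
    demo_dup <- demo[dup_idx, , drop = FALSE]
    demo_dup$primaryid <- dup_pid
    demo_dup$fda_dt <- dup_fda
    drug_dup <- dmap(drug_tab)
    ther_dup <- dmap(ther)
    reac_dup <- dmap(reac)
    demo <- rbind(demo, demo_dup)
    drug_tab <- rbind(drug_tab, drug_dup)
    ther <- rbind(ther, ther_dup)
    reac <- rbind(reac, reac_dup)
  }

  rownames(demo) <- rownames(drug_tab) <- rownames(ther) <-
    rownames(reac) <- NULL
  truth_cases <- data.frame(
    caseid = caseid, primaryid = primaryid, drug = drug, drug2 = drug2,
    is_event = is_event, occp = occp, therapy_start = start,
    onset_days = onset_days, start_missing = start_missing,
    stringsAsFactors = FALSE
  )
  structure(list(
    tables = list(DEMO = demo, DRUG = drug_tab, REAC = reac, THER = ther),
    truth = list(cases = truth_cases, n_cases = n, n_reports = nrow(demo),
                 n_duplicates = n_dup,
                 n_missing_start = sum(start_missing), spec = spec)
  ), class = "synthetic_universe")
}

#' Verbatim-to-canonical synonym map for a synthetic spec
#'
#' The generator writes drug names the way FAERS reports them — verbatim
#' upper case. This helper returns the synonym table mapping those
#' verbatim forms back to the spec's canonical names, for use with
#' [standardize_drug_names()].
#'
#' @param spec a [synthetic_spec()].
#' @return data.frame with `verbatim`, `canonical`.
#' @export
synth_synonym_map <- function(spec) {
  data.frame(verbatim = toupper(spec$drugs$name),
             canonical = spec$drugs$name, stringsAsFactors = FALSE)
}

#' Exact contingency tables from generator ground truth
#'
#' Computes the per-drug a/b/c/d cells directly from the generator's
#' case-level truth, for a given reporter restriction — the oracle the
#' pipeline's [build_all_tables()] must reproduce.
#'
#' @param truth the `truth` element of a `synthetic_universe`.
#' @param drugs drug names (default: all drugs in the spec).
#' @param reporters_kept occupation codes defining the universe; `NULL`
#'   keeps all cases.
#' @return list of `contingency_table` objects, sorted by descending `a`
#'   then name.
#' @export
ground_truth_tables <- function(truth, drugs = NULL,
                                reporters_kept = c("MD", "PH", "OT")) {
  cases <- truth$cases
  if (!is.null(reporters_kept)) {
    cases <- cases[toupper(cases$occp) %in% toupper(reporters_kept), ,
                   drop = FALSE]
  }
  if (is.null(drugs)) drugs <- truth$spec$drugs$name
  n_univ <- nrow(cases)
  n_event <- sum(cases$is_event)
  tabs <- lapply(drugs, function(g) {
    exposed <- cases$drug == g | (!is.na(cases$drug2) & cases$drug2 == g)
    a <- sum(exposed & cases$is_event)
    b <- sum(exposed & !cases$is_event)
    structure(list(drug = g, a = a, b = b, c = n_event - a,
                   d = n_univ - a - b - (n_event - a), N = n_univ,
                   empty = (a + b) == 0L),
              class = "contingency_table")
  })
  ord <- order(-vapply(tabs, `[[`, numeric(1), "a"),
               vapply(tabs, `[[`, character(1), "drug"))
  tabs[ord]
}
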