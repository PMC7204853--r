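# Case-crossover cohort construction: index admissions from ICD-coded
# hospital records, case/control window assignment, per-window exposure and
# covariate summaries, and the matched-pair analysis table.
#
# All date arithmetic is on calendar dates (no time of day). "d days prior"
# means index_date - d; both window boundaries are inclusive.

# ICD-10 categories indicating intentional self-harm / undetermined intent:
# X60-X84, Y10-Y34, and sequelae Y87.
.attempt_categories <- function() {
  c(sprintf("X%02d", 60:84), sprintf("Y%02d", 10:34), "Y87")
}

#' Does an ICD-10 code indicate a suicide attempt?
#'
#' Matching is on the 3-character category after stripping dots and suffixes,
#' so 4-character subcodes inherit their category's status. Qualifying
#' categories are X60-X69, X70-X79, X80-X84, Y10-Y19, Y20-Y29, Y30-Y34 and
#' Y87 (intentional self-harm, undetermined intent, and their sequelae).
#'
#' @param code Character vector of ICD-10 codes (e.g. `"X61"`, `"Y87.0"`).
#'
#' @return Logical vector.
#' @export
#' @examples
#' is_suicide_attempt_code(c("X61", "X85", "Y87.0", "F32.1"))
is_suicide_attempt_code <- function(code) {
  stopifnot(is.character(code), all(nzchar(code)))
  norm <- toupper(gsub("[. ]", "", code))
  if (!all(grepl("^[A-Z][0-9]{2}", norm))) {
    bad <- code[!grepl("^[A-Z][0-9]{2}", norm)]
    stop("malformed ICD-10 code(s): ", paste(bad, collapse = ", "))
  }
  substr(norm, 1L, 3L) %in% .attempt_categories()
}

#' Does an admission qualify as a hospitalised suicide attempt?
#'
#' Requires at least one qualifying ICD code and a stay of at least 24 hours,
#' operationalised as admission and discharge on different dates.
#'
#' @param icd_codes Character vector: semicolon-separated code strings, one
#'   element per admission.
#' @param admission_date,discharge_date `Date` vectors.
#'
#' @return Logical vector.
#' @export
is_qualifying_admission <- function(icd_codes, admission_date, discharge_date) {
  admission_date <- as.Date(admission_date)
  discharge_date <- as.Date(discharge_date)
  stopifnot(length(icd_codes) == length(admission_date),
            length(admission_date) == length(discharge_date),
            all(admission_date <= discharge_date))
  code_ok <- vapply(strsplit(as.character(icd_codes), ";", fixed = TRUE),
                    function(cs) {
                      cs <- trimws(cs)
                      cs <- cs[nzchar(cs)]
                      length(cs) > 0L && any(is_suicide_attempt_code(cs))
                    }, logical(1))
  code_ok & (admission_date != discharge_date)
}

#' Select the index admission for one patient
#'
#' Returns the qualifying admission with the earliest admission date (the
#' first hospitalised attempt); ties are broken by longest stay, then input
#' order.
#'
#' @param admissions Data frame with `admission_date`, `discharge_date`,
#'   `icd_codes` for a single patient.
#' @param study_start,study_end Optional `Date` bounds; only admissions whose
#'   admission date falls inside are considered. Default unbounded.
#'
#' @return The selected row of `admissions`, or `NULL` when no admission
#'   qualifies.
#' @export
select_index_admission <- function(admissions, study_start = NULL,
                                   study_end = NULL) {
  if (nrow(admissions) == 0L) return(NULL)
  ok <- is_qualifying_admission(admissions$icd_codes,
                                admissions$admission_date,
                                admissions$discharge_date)
  adm <- as.Date(admissions$admission_date)
  if (!is.null(study_start)) ok <- ok & adm >= as.Date(study_start)
  if (!is.null(study_end)) ok <- ok & adm <= as.Date(study_end)
  if (!any(ok)) return(NULL)
  cand <- which(ok)
  stay <- as.integer(as.Date(admissions$discharge_date) - adm)
  # order(): earliest admission, then longest stay, then original position
  pick <- cand[order(adm[cand], -stay[cand], cand)][1L]
  admissions[pick, , drop = FALSE]
}

#' Assign an event date to the case or control window
#'
#' With `d = index_date - event_date` in whole days, the case window is
#' `d` in 1-30 and the control window `d` in 61-90 (boundaries inclusive);
#' anything else, including the index date itself, is `"neither"`.
#'
#' @param event_date,index_date `Date` vectors (recycled).
#' @param case_window,control_window Integer pairs `c(lo, hi)` of days prior.
#'
#' @return Character vector: `"case"`, `"control"` or `"neither"`.
#' @export
#' @examples
#' assign_window(as.Date("2010-06-01"), as.Date("2010-06-15"))  # "case"
assign_window <- function(event_date, index_date,
                          case_window = c(1L, 30L),
                          control_window = c(61L, 90L)) {
  stopifnot(length(case_window) == 2L, length(control_window) == 2L,
            case_window[1L] <= case_window[2L],
            control_window[1L] <= control_window[2L])
  if (max(case_window[1L], control_window[1L]) <=
      min(case_window[2L], control_window[2L])) {
    stop("case and control windows must not overlap")
  }
  d <- as.integer(as.Date(index_date) - as.Date(event_date))
  out <- rep("neither", length(d))
  out[d >= case_window[1L] & d <= case_window[2L]] <- "case"
  out[d >= control_window[1L] & d <= control_window[2L]] <- "control"
  out
}

# Distinct occupied days (nights) of any stay interval falling inside the
# window [win_start, win_end]. A stay [s, e) occupies nights s .. e-1.
.bed_days <- function(stay_start, stay_end, win_start, win_end) {
  if (length(stay_start) == 0L) return(0L)
  days <- unlist(Map(function(s, e) {
    if (e <= s) return(integer(0))
    lo <- max(as.integer(s), as.integer(win_start))
    hi <- min(as.integer(e) - 1L, as.integer(win_end))
    if (lo > hi) integer(0) else lo:hi
  }, as.Date(stay_start), as.Date(stay_end)))
  length(unique(days))
}

#' Summarise one patient's exposure and covariates in one window
#'
#' Aggregates documents, extracted quotations, appointments and inpatient
#' stays over the requested window relative to the index date.
#'
#' @param period `"case"` or `"control"`.
#' @param index_date `Date` scalar.
#' @param docs Data frame of this patient's documents (`doc_id`, `timestamp`,
#'   `text`; optional precomputed `n_tokens` and `n_quotes` columns, used when
#'   present so corpora without composed text can be summarised).
#' @param spans Data frame of extracted spans with `doc_id` (ignored when
#'   `docs` carries `n_quotes`).
#' @param appointments Data frame with `date`, `status` (`attended`/`dna`).
#' @param stays Data frame with `start_date`, `end_date`.
#' @param case_window,control_window Window definitions as in
#'   [assign_window()].
#'
#' @return One-row data frame: `period`, `n_documents`, `n_quotes`,
#'   `n_tokens`, `quotes_per_token`, `any_quote`, `face_to_face`, `dna`,
#'   `bed_days`.
#' @export
summarise_period <- function(period, index_date, docs, spans, appointments,
                             stays, case_window = c(1L, 30L),
                             control_window = c(61L, 90L)) {
  period <- match.arg(period, c("case", "control"))
  win <- if (period == "case") case_window else control_window
  win_start <- as.Date(index_date) - win[2L]
  win_end <- as.Date(index_date) - win[1L]

  in_win <- assign_window(docs$timestamp, index_date, case_window,
                          control_window) == period
  wd <- docs[in_win, , drop = FALSE]
  n_documents <- nrow(wd)
  if (n_documents == 0L) {
    n_quotes <- 0L; n_tokens <- 0L
  } else {
    n_quotes <- if ("n_quotes" %in% names(wd)) sum(wd$n_quotes) else {
      sum(spans$doc_id %in% wd$doc_id)
    }
    n_tokens <- if ("n_tokens" %in% names(wd)) sum(wd$n_tokens) else {
      sum(count_tokens(wd$text))
    }
  }
  qpt <- if (n_tokens == 0L && n_quotes == 0L) 0 else n_quotes / n_tokens

  app_win <- appointments[assign_window(appointments$date, index_date,
                                        case_window, control_window) == period,
                          , drop = FALSE]
  f2f <- sum(app_win$status == "attended")
  dna <- sum(app_win$status == "dna")
  bd <- .bed_days(stays$start_date, stays$end_date, win_start, win_end)

  data.frame(period = period, n_documents = n_documents,
             n_quotes = as.integer(n_quotes), n_tokens = as.integer(n_tokens),
             quotes_per_token = qpt, any_quote = as.integer(n_quotes >= 1L),
             face_to_face = as.integer(f2f), dna = as.integer(dna),
             bed_days = as.integer(bd), stringsAsFactors = FALSE)
}

#' Build the matched-pair analysis table
#'
#' For every patient with a qualifying index admission, summarises the case
#' (1-30 days prior) and control (61-90 days prior) windows and keeps the
#' patients with at least one mental-healthcare document in both windows.
#'
#' @param docs Document corpus data frame (see [read_documents()]); may carry
#'   precomputed `n_tokens`/`n_quotes` columns.
#' @param admissions Admissions data frame (see [read_admissions()]).
#' @param appointments,stays Event tables (see [read_appointments()]).
#' @param spans Extracted spans; when `NULL` and `docs` lacks an `n_quotes`
#'   column, [extract_corpus()] is run with `cfg`.
#' @param cfg An [extraction_config()].
#' @param case_window,control_window Window definitions as in
#'   [assign_window()].
#' @param study_start,study_end Optional study-period bounds on the index
#'   admission date.
#'
#' @return Data frame with one row per included patient: `patient_id`,
#'   `index_date`, and `case_*` / `control_*` copies of every
#'   [summarise_period()] column. An `audit` attribute records exclusion
#'   counts.
#' @export
build_matched_pairs <- function(docs, admissions, appointments, stays,
                                spans = NULL, cfg = extraction_config(),
                                case_window = c(1L, 30L),
                                control_window = c(61L, 90L),
                                study_start = NULL, study_end = NULL) {
  if (is.null(spans) && !("n_quotes" %in% names(docs))) {
    spans <- extract_corpus(docs, cfg)
  }
  patients <- unique(admissions$patient_id)
  audit <- list(n_patients = length(patients), no_index_admission = 0L,
                no_case_documents = 0L, no_control_documents = 0L,
                included = 0L)
  rows <- vector("list", length(patients))
  for (k in seq_along(patients)) {
    pid <- patients[k]
    idx <- select_index_admission(
      admissions[admissions$patient_id == pid, , drop = FALSE],
      study_start, study_end)
    if (is.null(idx)) {
      audit$no_index_admission <- audit$no_index_admission + 1L
      next
    }
    index_date <- as.Date(idx$admission_date)
    pd <- docs[docs$patient_id == pid, , drop = FALSE]
    pa <- appointments[appointments$patient_id == pid, , drop = FALSE]
    ps <- stays[stays$patient_id == pid, , drop = FALSE]
    cs <- summarise_period("case", index_date, pd, spans, pa, ps,
                           case_window, control_window)
    ct <- summarise_period("control", index_date, pd, spans, pa, ps,
                           case_window, control_window)
    if (cs$n_documents < 1L) {
      audit$no_case_documents <- audit$no_case_documents + 1L
      next
    }
    if (ct$n_documents < 1L) {
      audit$no_control_documents <- audit$no_control_documents + 1L
      next
    }
    audit$included <- audit$included + 1L
    drop_period <- function(x, prefix) {
      x$period <- NULL
      names(x) <- paste0(prefix, names(x))
      x
    }
    rows[[k]] <- cbind(data.frame(patient_id = pid,
                                  index_date = format(index_date),
                                  stringsAsFactors = FALSE),
                       drop_period(cs, "case_"), drop_period(ct, "control_"))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else {
    # empty table with the full column set
    tmpl <- summarise_period("case", Sys.Date(),
                             data.frame(doc_id = character(),
                                        timestamp = as.Date(character()),
                                        text = character()),
                             data.frame(doc_id = character()),
                             data.frame(date = as.Date(character()),
                                        status = character()),
                             data.frame(start_date = as.Date(character()),
                                        end_date = as.Date(character())))
    tmpl$period <- NULL
    cols <- c("patient_id", "index_date",
              paste0("case_", names(tmpl)), paste0("control_", names(tmpl)))
    stats::setNames(
      as.data.frame(lapply(cols, function(x) character(0)),
                    stringsAsFactors = FALSE), cols)[0, ]
  }
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}
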