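# Seed-reproducible synthetic EHR corpora: per-patient document streams in
# two 30-day windows with controllable quotation prevalence, Poisson
# appointment/DNA counts, inpatient stays, and gold-annotated quote spans.
#
# Documents are assembled from clinical-style clause templates. Salting
# inserts material the extractor must reject: contractions, possessives,
# email/URL-only quotes (excluded from gold), and unclosed or runaway quotes.

.sim_vocab <- function() {
  c("patient", "reports", "low", "mood", "today", "sleep", "poor", "appetite",
    "reduced", "attended", "clinic", "review", "medication", "unchanged",
    "denies", "ideation", "plan", "follow", "up", "week", "family", "visited",
    "ward", "round", "settled", "night", "engaged", "group", "session",
    "discussed", "discharge", "planning", "risk", "assessment", "completed",
    "mental", "state", "stable", "community", "team", "informed")
}

#' Simulation configuration for the synthetic EHR generator
#'
#' Defaults emulate the structure of a mental-healthcare record stream around
#' a hospitalised suicide attempt: roughly 15 documents per 30-day window,
#' per-document quote probabilities calibrated so that about 58% (control)
#' and 61% (case) of patients have at least one quotation in a window, and
#' Poisson appointment/DNA rates of 2.47/2.92 and 0.38/0.47.
#'
#' @param n_patients Number of patients.
#' @param seed Integer seed fixing all randomness end-to-end.
#' @param docs_per_window_mean Poisson mean for documents per 30-day window.
#' @param p_quote_doc_control,p_quote_doc_case Per-document probability that
#'   a document contains quoted speech, by window; these set the true
#'   pair-level exposure odds ratio (see [calibrate_case_probability()]).
#' @param quotes_per_quoting_doc_mean Mean quotations in a quoting document
#'   (1 plus a Poisson count).
#' @param tokens_per_doc_mean Poisson mean for word tokens per document (used
#'   directly when `text = FALSE`; with composed text, token counts follow
#'   from the templates).
#' @param face_to_face_rate_control,face_to_face_rate_case Poisson means for
#'   attended appointments per window.
#' @param dna_rate_control,dna_rate_case Poisson means for non-attended
#'   appointments per window.
#' @param stay_probability Probability of an inpatient stay starting in a
#'   window.
#' @param stay_length_mean Mean stay length in days (geometric).
#' @param filler_docs_mean Poisson mean for documents in the gap region
#'   (31-60 days prior), which belongs to neither window.
#' @param curly_fraction Fraction of quotations set in curly rather than
#'   straight delimiters.
#' @param single_fraction Fraction of quotations set in single rather than
#'   double delimiters.
#' @param p_salt_contraction,p_salt_possessive Per-document probabilities of
#'   inserting an apostrophe contraction ("can't") / a possessive
#'   ("patients'") into unquoted filler text.
#' @param p_salt_email,p_salt_url Per-document probabilities of inserting a
#'   quote whose content is only an email address / URL (excluded from gold).
#' @param fraction_malformed Per-document probability of appending a
#'   deliberately unclosed quote (sometimes followed by more than
#'   `max_quote_chars` characters, exercising the runaway guard); excluded
#'   from gold.
#' @param require_inclusion Resample document counts so every patient has at
#'   least one document in both windows (an inclusion-ready cohort).
#' @param text Compose document text with gold span offsets (`TRUE`), or keep
#'   per-document gold quote/token counts only (`FALSE`; much faster, used
#'   for large simulation studies of the count pipeline).
#' @param origin_date Earliest calendar anchor; arbitrary, since all window
#'   logic is translation invariant.
#'
#' @return Object of class `simulation_config` (a named list).
#' @export
simulation_config <- function(n_patients = 200L, seed = 1L,
                              docs_per_window_mean = 15,
                              p_quote_doc_control = 0.0583,
                              p_quote_doc_case = 0.0629,
                              quotes_per_quoting_doc_mean = 1.5,
                              tokens_per_doc_mean = 120,
                              face_to_face_rate_control = 2.47,
                              face_to_face_rate_case = 2.92,
                              dna_rate_control = 0.38,
                              dna_rate_case = 0.47,
                              stay_probability = 0.15,
                              stay_length_mean = 15,
                              filler_docs_mean = 2,
                              curly_fraction = 0.4,
                              single_fraction = 0.25,
                              p_salt_contraction = 0.3,
                              p_salt_possessive = 0.15,
                              p_salt_email = 0.05,
                              p_salt_url = 0.05,
                              fraction_malformed = 0.05,
                              require_inclusion = TRUE,
                              text = TRUE,
                              origin_date = as.Date("2010-01-01")) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              docs_per_window_mean = docs_per_window_mean,
              p_quote_doc_control = p_quote_doc_control,
              p_quote_doc_case = p_quote_doc_case,
              quotes_per_quoting_doc_mean = quotes_per_quoting_doc_mean,
              tokens_per_doc_mean = tokens_per_doc_mean,
              face_to_face_rate_control = face_to_face_rate_control,
              face_to_face_rate_case = face_to_face_rate_case,
              dna_rate_control = dna_rate_control,
              dna_rate_case = dna_rate_case,
              stay_probability = stay_probability,
              stay_length_mean = stay_length_mean,
              filler_docs_mean = filler_docs_mean,
              curly_fraction = curly_fraction,
              single_fraction = single_fraction,
              p_salt_contraction = p_salt_contraction,
              p_salt_possessive = p_salt_possessive,
              p_salt_email = p_salt_email,
              p_salt_url = p_salt_url,
              fraction_malformed = fraction_malformed,
              require_inclusion = isTRUE(require_inclusion),
              text = isTRUE(text),
              origin_date = as.Date(origin_date))
  probs <- c(cfg$p_quote_doc_control, cfg$p_quote_doc_case,
             cfg$stay_probability, cfg$curly_fraction, cfg$single_fraction,
             cfg$p_salt_contraction, cfg$p_salt_possessive, cfg$p_salt_email,
             cfg$p_salt_url, cfg$fraction_malformed)
  stopifnot(cfg$n_patients >= 1L, all(probs >= 0 & probs <= 1),
            cfg$docs_per_window_mean >= 0, cfg$filler_docs_mean >= 0,
            cfg$quotes_per_quoting_doc_mean >= 1)
  if (cfg$require_inclusion && cfg$docs_per_window_mean <= 0) {
    stop("infeasible config: inclusion-ready cohort requested but the ",
         "document rate is zero")
  }
  structure(cfg, class = "simulation_config")
}

#' Marginal probability of any quotation in a window
#'
#' For document count N ~ Poisson(lambda) (optionally truncated at N >= 1)
#' and independent per-document quote probability p, returns
#' P(at least one quoting document).
#'
#' @param p Per-document quote probability.
#' @param lambda Poisson mean document count per window.
#' @param truncated Condition on N >= 1 (inclusion-ready cohorts).
#'
#' @return Probability in `[0, 1]`.
#' @export
window_quote_probability <- function(p, lambda, truncated = TRUE) {
  # E[(1-p)^N] = exp(-lambda * p); remove the N = 0 mass when truncated
  if (truncated) {
    1 - (exp(-lambda * p) - exp(-lambda)) / (1 - exp(-lambda))
  } else {
    1 - exp(-lambda * p)
  }
}

#' Calibrate the case-window quote probability to a target pair-level OR
#'
#' Solves for the per-document case-window probability such that the
#' pair-level discordant odds ratio — the odds ratio of the marginal
#' any-quotation probabilities across independent windows — equals
#' `target_or`.
#'
#' @param target_or Desired pair-level exposure odds ratio.
#' @param p_control Per-document control-window quote probability.
#' @param lambda Poisson mean document count per window.
#' @param truncated As in [window_quote_probability()].
#'
#' @return Per-document case-window probability.
#' @export
#' @examples
#' calibrate_case_probability(1.5, 0.0583, 15)
calibrate_case_probability <- function(target_or, p_control, lambda,
                                       truncated = TRUE) {
  p0 <- window_quote_probability(p_control, lambda, truncated)
  f <- function(p) {
    stats::qlogis(window_quote_probability(p, lambda, truncated)) -
      stats::qlogis(p0) - log(target_or)
  }
  stats::uniroot(f, c(1e-9, 1 - 1e-9), tol = 1e-12)$root
}

.compose_clause <- function(n_words) {
  paste(sample(.sim_vocab(), n_words, replace = TRUE), collapse = " ")
}

.quote_delims <- function(cfg) {
  single <- stats::runif(1) < cfg$single_fraction
  curly <- stats::runif(1) < cfg$curly_fraction
  if (single && curly) c("‘", "’", "curly_single")
  else if (single) c("'", "'", "squote")
  else if (curly) c("“", "”", "curly_double")
  else c("\"", "\"", "dquote")
}

#' Generate one gold-annotated synthetic document
#'
#' Assembles clinical-style clauses with exactly `n_quotes` well-formed
#' quotations at recorded offsets, optionally salted with contractions,
#' possessives, email/URL-only quotes and unclosed/runaway quotes — all of
#' which are excluded from gold and designed to be correctly rejected by
#' [extract_quoted_spans()]. Uses the current RNG state.
#'
#' @param n_quotes Number of gold quotations to insert.
#' @param cfg A [simulation_config()] controlling the salting probabilities
#'   and delimiter mix.
#'
#' @return List with `text` (character scalar) and `gold` (data frame of
#'   0-based half-open `start`/`end` offsets, delimiters included).
#' @export
#' @examples
#' set.seed(7)
#' doc <- generate_annotated_document(2, simulation_config())
#' extract_quoted_spans(doc$text)[, c("start", "end")] == doc$gold
generate_annotated_document <- function(n_quotes, cfg = simulation_config()) {
  stopifnot(n_quotes >= 0)
  parts <- character(0)
  gold_start <- integer(0)
  gold_end <- integer(0)
  pos <- 0L
  push <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    pos <<- pos + nchar(s, type = "chars")
  }
  filler <- function() {
    s <- .compose_clause(sample(4:9, 1L))
    if (stats::runif(1) < cfg$p_salt_contraction) {
      s <- paste(s, sample(c("can't", "won't", "didn't", "she'll", "they've"),
                           1L))
    }
    if (stats::runif(1) < cfg$p_salt_possessive) {
      s <- paste(s, sample(c("the patients' needs", "his parents' house",
                             "nurses' station"), 1L))
    }
    push(paste0(s, ". "))
    if (stats::runif(1) < cfg$p_salt_email) {
      push("\"team.admin@example.org\" ")
    }
    if (stats::runif(1) < cfg$p_salt_url) {
      push("\"www.example.org/leaflet\" ")
    }
  }
  quote_content <- function(delim_class) {
    s <- .compose_clause(sample(3:8, 1L))
    # contractions are safe inside any class: the suffix rule protects them
    if (stats::runif(1) < cfg$p_salt_contraction) {
      s <- paste(s, sample(c("can't", "don't", "won't"), 1L))
    }
    # a subquotation of a different class, absorbed by the outer span
    if (delim_class %in% c("dquote", "curly_double") &&
        stats::runif(1) < 0.25) {
      s <- paste0(s, " ‘", .compose_clause(2L), "’")
    }
    s
  }
  filler()
  if (n_quotes > 0) {
    for (q in seq_len(n_quotes)) {
      d <- .quote_delims(cfg)
      content <- quote_content(d[3L])
      start <- pos
      push(paste0(d[1L], content, d[2L]))
      gold_start <- c(gold_start, start)
      gold_end <- c(gold_end, pos)
      push(" ")
      filler()
    }
  }
  if (stats::runif(1) < cfg$fraction_malformed) {
    # unclosed opener; half the time with enough tail to trip the length cap
    tail_words <- if (stats::runif(1) < 0.5) 60L else 320L
    push(paste0("\"", paste(sample(.sim_vocab(), tail_words, replace = TRUE),
                            collapse = " ")))
  }
  list(text = paste0(parts, collapse = ""),
       gold = data.frame(start = gold_start, end = gold_end))
}

# Poisson draws, optionally resampled to be >= 1.
.rpois_trunc <- function(n, lambda, truncated) {
  x <- stats::rpois(n, lambda)
  if (truncated) {
    while (any(x == 0L)) x[x == 0L] <- stats::rpois(sum(x == 0L), lambda)
  }
  x
}

#' Simulate a synthetic case-crossover cohort
#'
#' For each patient: an index admission with a qualifying ICD-10 code (plus
#' occasional non-qualifying noise admissions), Poisson document counts in the
#' case (1-30 days prior), control (61-90 days prior) and gap (31-60 days)
#' regions, per-document quote presence at the window-specific probability,
#' Poisson attended/DNA appointment counts, and occasional inpatient stays.
#' Fully reproducible under `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @param seed Overrides `cfg$seed` when given.
#'
#' @return Object of class `synthetic_corpus`: a list with data frames
#'   `documents` (with `n_quotes`/`n_tokens` count columns when
#'   `cfg$text = FALSE`), `gold` (span offsets; empty when no text is
#'   composed), `admissions`, `appointments`, `stays`, `index_dates`, plus
#'   `true_parameters` (the generating values and the implied pair-level
#'   odds ratio) and `config`.
#' @export
#' @examples
#' corpus <- simulate_cohort(simulation_config(n_patients = 5, seed = 42))
#' names(corpus)
simulate_cohort <- function(cfg = simulation_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(seed)
  n <- cfg$n_patients
  pid <- sprintf("p%05d", seq_len(n))
  index_date <- cfg$origin_date + 90L + sample.int(3000L, n, replace = TRUE)

  # admissions: the qualifying index admission, plus noise that must never be
  # selected (non-qualifying code, or a later qualifying attempt)
  qual_codes <- c("X61", "X63.0", "X70", "X78", "X84", "Y14", "Y25", "Y30",
                  "Y34", "Y87.0")
  admissions <- data.frame(
    patient_id = pid, admission_date = index_date,
    discharge_date = index_date + sample.int(14L, n, replace = TRUE),
    icd_codes = sample(qual_codes, n, replace = TRUE),
    stringsAsFactors = FALSE)
  noise_early <- stats::runif(n) < 0.2
  if (any(noise_early)) {
    k <- sum(noise_early)
    early_date <- index_date[noise_early] - 100L -
      sample.int(200L, k, replace = TRUE)
    same_day <- stats::runif(k) < 0.5  # same-day attempts never qualify
    admissions <- rbind(admissions, data.frame(
      patient_id = pid[noise_early], admission_date = early_date,
      discharge_date = early_date + ifelse(same_day, 0L,
                                           sample.int(5L, k, replace = TRUE)),
      icd_codes = ifelse(same_day, "X61", "F32.1"),
      stringsAsFactors = FALSE))
  }
  noise_late <- stats::runif(n) < 0.1
  if (any(noise_late)) {
    k <- sum(noise_late)
    late_date <- index_date[noise_late] + 180L +
      sample.int(200L, k, replace = TRUE)
    admissions <- rbind(admissions, data.frame(
      patient_id = pid[noise_late], admission_date = late_date,
      discharge_date = late_date + sample.int(7L, k, replace = TRUE),
      icd_codes = sample(qual_codes, k, replace = TRUE),
      stringsAsFactors = FALSE))
  }

  # documents: counts per region, then one row per document
  n_case <- .rpois_trunc(n, cfg$docs_per_window_mean, cfg$require_inclusion)
  n_ctrl <- .rpois_trunc(n, cfg$docs_per_window_mean, cfg$require_inclusion)
  n_gap <- stats::rpois(n, cfg$filler_docs_mean)
  counts <- c(n_case, n_ctrl, n_gap)
  region <- rep(rep(c("case", "control", "gap"), each = n), counts)
  dpid <- rep(rep(pid, 3L), counts)
  didx <- rep(rep(index_date, 3L), counts)
  nd <- length(dpid)
  days_prior <- integer(nd)
  days_prior[region == "case"] <- sample(1:30, sum(region == "case"), TRUE)
  days_prior[region == "control"] <- sample(61:90, sum(region == "control"), TRUE)
  days_prior[region == "gap"] <- sample(31:60, sum(region == "gap"), TRUE)
  p_quote <- ifelse(region == "case", cfg$p_quote_doc_case,
                    cfg$p_quote_doc_control)
  quoting <- stats::rbinom(nd, 1L, p_quote)
  n_quotes <- quoting * (1L + stats::rpois(nd, cfg$quotes_per_quoting_doc_mean - 1))
  documents <- data.frame(
    doc_id = sprintf("d%07d", seq_len(nd)), patient_id = dpid,
    timestamp = didx - days_prior,
    doc_type = sample(c("correspondence", "case_note"), nd, TRUE),
    text = "", window = region, stringsAsFactors = FALSE)

  if (cfg$text) {
    gold <- vector("list", nd)
    for (k in seq_len(nd)) {
      doc <- generate_annotated_document(n_quotes[k], cfg)
      documents$text[k] <- doc$text
      if (nrow(doc$gold) > 0L) {
        gold[[k]] <- cbind(doc_id = documents$doc_id[k], doc$gold,
                           stringsAsFactors = FALSE)
      }
    }
    gold <- gold[!vapply(gold, is.null, logical(1))]
    gold <- if (length(gold)) do.call(rbind, gold) else {
      data.frame(doc_id = character(), start = integer(), end = integer(),
                 stringsAsFactors = FALSE)
    }
  } else {
    documents$n_quotes <- n_quotes
    documents$n_tokens <- pmax(1L, stats::rpois(nd, cfg$tokens_per_doc_mean))
    gold <- data.frame(doc_id = character(), start = integer(),
                       end = integer(), stringsAsFactors = FALSE)
  }

  # appointments and stays, per patient and window
  mk_appts <- function(window, status, rate) {
    cnt <- stats::rpois(n, rate)
    if (sum(cnt) == 0L) {
      return(data.frame(patient_id = character(), date = as.Date(character()),
                        status = character(), stringsAsFactors = FALSE))
    }
    offs <- if (window == "case") 1:30 else 61:90
    data.frame(patient_id = rep(pid, cnt),
               date = rep(index_date, cnt) - sample(offs, sum(cnt), TRUE),
               status = status, stringsAsFactors = FALSE)
  }
  appointments <- rbind(
    mk_appts("case", "attended", cfg$face_to_face_rate_case),
    mk_appts("control", "attended", cfg$face_to_face_rate_control),
    mk_appts("case", "dna", cfg$dna_rate_case),
    mk_appts("control", "dna", cfg$dna_rate_control))

  mk_stays <- function(window) {
    has <- stats::runif(n) < cfg$stay_probability
    k <- sum(has)
    if (k == 0L) {
      return(data.frame(patient_id = character(),
                        start_date = as.Date(character()),
                        end_date = as.Date(character()),
                        stringsAsFactors = FALSE))
    }
    offs <- if (window == "case") 1:30 else 61:90
    start <- index_date[has] - sample(offs, k, TRUE)
    len <- 1L + stats::rgeom(k, 1 / cfg$stay_length_mean)
    data.frame(patient_id = pid[has], start_date = start,
               end_date = start + len, stringsAsFactors = FALSE)
  }
  stays <- rbind(mk_stays("case"), mk_stays("control"))

  p0 <- window_quote_probability(cfg$p_quote_doc_control,
                                 cfg$docs_per_window_mean,
                                 cfg$require_inclusion)
  p1 <- window_quote_probability(cfg$p_quote_doc_case,
                                 cfg$docs_per_window_mean,
                                 cfg$require_inclusion)
  true_parameters <- list(
    p_quote_doc_control = cfg$p_quote_doc_control,
    p_quote_doc_case = cfg$p_quote_doc_case,
    marginal_p_control = p0, marginal_p_case = p1,
    true_log_or = stats::qlogis(p1) - stats::qlogis(p0),
    true_or = exp(stats::qlogis(p1) - stats::qlogis(p0)),
    seed = seed)

  structure(list(documents = documents, gold = gold, admissions = admissions,
                 appointments = appointments, stays = stays,
                 index_dates = data.frame(patient_id = pid,
                                          index_date = index_date,
                                          stringsAsFactors = FALSE),
                 true_parameters = true_parameters, config = cfg),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("Synthetic EHR corpus: %d patients, %d documents, %d gold spans\n",
              nrow(x$index_dates), nrow(x$documents), nrow(x$gold)))
  cat(sprintf("  true pair-level exposure OR %.3f (seed %d)\n",
              x$true_parameters$true_or, x$true_parameters$seed))
  invisible(x)
}

#' Matched-pair table straight from a synthetic corpus
#'
#' A vectorised summariser for simulation studies: aggregates per-document
#' quote/token counts by patient and window and joins the appointment and
#' bed-day covariates. With `use_gold = FALSE` the quote counts come from
#' running [extract_corpus()] on the composed text, exercising the full
#' pipeline; with `use_gold = TRUE` the generator's own counts are used.
#'
#' @param corpus A [simulate_cohort()] result.
#' @param use_gold Use the generator's gold quote counts instead of running
#'   the extractor.
#' @param cfg An [extraction_config()] for the extraction path.
#' @param method `"cohort"` routes through [build_matched_pairs()] (index
#'   admissions selected from the ICD-coded table); `"fast"` aggregates the
#'   same quantities with vectorised group sums, anchored on the corpus's
#'   recorded index dates. Both produce identical tables on corpora where the
#'   index admission is recoverable (always true for generated corpora).
#'
#' @return A matched-pair table with the same columns as
#'   [build_matched_pairs()].
#' @export
corpus_pair_table <- function(corpus, use_gold = TRUE,
                              cfg = extraction_config(),
                              method = c("cohort", "fast")) {
  method <- match.arg(method)
  docs <- corpus$documents
  if (use_gold) {
    if (!("n_quotes" %in% names(docs))) {
      cnt <- table(corpus$gold$doc_id)
      docs$n_quotes <- as.integer(cnt[docs$doc_id])
      docs$n_quotes[is.na(docs$n_quotes)] <- 0L
    }
    if (!("n_tokens" %in% names(docs))) docs$n_tokens <- count_tokens(docs$text)
  } else {
    docs$n_quotes <- NULL
    docs$n_tokens <- NULL
  }
  if (method == "cohort") {
    return(build_matched_pairs(docs, corpus$admissions, corpus$appointments,
                               corpus$stays, cfg = cfg))
  }
  if (!all(c("n_quotes", "n_tokens") %in% names(docs))) {
    spans <- extract_corpus(docs, cfg)
    cnt <- table(spans$doc_id)
    docs$n_quotes <- as.integer(cnt[docs$doc_id])
    docs$n_quotes[is.na(docs$n_quotes)] <- 0L
    docs$n_tokens <- count_tokens(docs$text)
  }
  .fast_pair_table(docs, corpus$index_dates, corpus$appointments,
                   corpus$stays)
}

# Vectorised pair-table construction for simulation studies: group sums by
# patient x window instead of per-patient subsetting.
.fast_pair_table <- function(docs, index_dates, appointments, stays) {
  pid_all <- sort(index_dates$patient_id)
  idx <- as.Date(index_dates$index_date)[match(pid_all, index_dates$patient_id)]
  names(idx) <- pid_all

  doc_idx <- idx[docs$patient_id]
  w <- assign_window(docs$timestamp, doc_idx)
  keep <- w != "neither"
  agg <- rowsum(cbind(n = 1L, q = docs$n_quotes[keep], t = docs$n_tokens[keep]),
                paste(docs$patient_id[keep], w[keep], sep = "\r"))
  get_agg <- function(pids, win, col) {
    v <- agg[match(paste(pids, win, sep = "\r"), rownames(agg)), col]
    v[is.na(v)] <- 0L
    as.integer(v)
  }

  included <- pid_all[get_agg(pid_all, "case", "n") >= 1L &
                        get_agg(pid_all, "control", "n") >= 1L]

  aw <- assign_window(appointments$date, idx[appointments$patient_id])
  akeep <- aw != "neither"
  aagg <- rowsum(
    cbind(f2f = as.integer(appointments$status[akeep] == "attended"),
          dna = as.integer(appointments$status[akeep] == "dna")),
    paste(appointments$patient_id[akeep], aw[akeep], sep = "\r"))
  get_app <- function(pids, win, col) {
    v <- aagg[match(paste(pids, win, sep = "\r"), rownames(aagg)), col]
    v[is.na(v)] <- 0L
    as.integer(v)
  }

  bed <- matrix(0L, nrow = length(included), ncol = 2L,
                dimnames = list(included, c("case", "control")))
  stay_pts <- intersect(unique(stays$patient_id), included)
  for (p in stay_pts) {
    s <- stays[stays$patient_id == p, , drop = FALSE]
    bed[p, "case"] <- .bed_days(s$start_date, s$end_date,
                                idx[p] - 30L, idx[p] - 1L)
    bed[p, "control"] <- .bed_days(s$start_date, s$end_date,
                                   idx[p] - 90L, idx[p] - 61L)
  }

  side <- function(win) {
    nq <- get_agg(included, win, "q")
    nt <- get_agg(included, win, "t")
    out <- data.frame(
      n_documents = get_agg(included, win, "n"), n_quotes = nq,
      n_tokens = nt,
      quotes_per_token = ifelse(nt == 0L & nq == 0L, 0, nq / nt),
      any_quote = as.integer(nq >= 1L),
      face_to_face = get_app(included, win, "f2f"),
      dna = get_app(included, win, "dna"),
      bed_days = as.integer(bed[, win]))
    names(out) <- paste0(win, "_", names(out))
    out
  }
  out <- cbind(data.frame(patient_id = included,
                          index_date = format(idx[included]),
                          stringsAsFactors = FALSE),
               side("case"), side("control"))
  rownames(out) <- NULL
  out
}

#' Write a synthetic corpus to disk
#'
#' Emits `documents.jsonl`, `gold.jsonl`, `admissions.csv`,
#' `appointments.csv`, `stays.csv` and `true_parameters.json` in the formats
#' the pipeline reads.
#'
#' @param corpus A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#'
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_documents(corpus$documents, file.path(dir, "documents.jsonl"))
  write_gold(corpus$gold, file.path(dir, "gold.jsonl"))
  utils::write.csv(corpus$admissions, file.path(dir, "admissions.csv"),
                   row.names = FALSE)
  utils::write.csv(corpus$appointments, file.path(dir, "appointments.csv"),
                   row.names = FALSE)
  utils::write.csv(corpus$stays, file.path(dir, "stays.csv"),
                   row.names = FALSE)
  jsonlite::write_json(corpus$true_parameters,
                       file.path(dir, "true_parameters.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
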