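# Readers and writers for the pipeline's plain-text interchange formats:
# documents and span annotations as JSONL, event tables and the matched-pair
# table as CSV, pipeline configuration as YAML.

.read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
             error = function(e) {
               stop(sprintf("malformed JSONL at %s line %d: %s",
                            path, i, conditionMessage(e)), call. = FALSE)
             })
  })
}

.write_jsonl <- function(records, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (rec in records) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null"),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' Read a document corpus
#'
#' Accepts JSONL (one object per line with keys `doc_id`, `patient_id`,
#' `timestamp`, `doc_type`, `text`) or CSV with identical columns; the format
#' is inferred from the file extension unless given.
#'
#' @param path File path.
#' @param format `"jsonl"`, `"csv"` or `"auto"`.
#'
#' @return Data frame with columns `doc_id`, `patient_id`, `timestamp`
#'   (`Date`), `doc_type`, `text`.
#' @export
read_documents <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  } else {
    recs <- .read_jsonl(path)
    df <- do.call(rbind, lapply(recs, function(r) {
      data.frame(doc_id = as.character(r$doc_id),
                 patient_id = as.character(r$patient_id),
                 timestamp = as.character(r$timestamp),
                 doc_type = as.character(r$doc_type %||% "other"),
                 text = as.character(r$text %||% ""),
                 stringsAsFactors = FALSE)
    }))
  }
  need <- c("doc_id", "patient_id", "timestamp", "doc_type", "text")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("documents file lacks columns: ",
                            paste(missing, collapse = ", "))
  df$timestamp <- as.Date(df$timestamp)
  if (anyNA(df$timestamp)) stop("documents file contains unparseable timestamps")
  if (anyDuplicated(df$doc_id)) stop("doc_id values must be unique within a corpus")
  df$text[is.na(df$text)] <- ""
  df[need]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write documents as JSONL
#' @param docs Data frame as returned by [read_documents()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_documents <- function(docs, path) {
  .write_jsonl(lapply(seq_len(nrow(docs)), function(k) {
    list(doc_id = docs$doc_id[k], patient_id = docs$patient_id[k],
         timestamp = format(as.Date(docs$timestamp[k])),
         doc_type = docs$doc_type[k], text = docs$text[k])
  }), path)
}

#' Read / write extracted spans as JSONL
#'
#' One object per span with keys `doc_id`, `start`, `end`, `content_start`,
#' `content_end`, `content`, `delimiter_class` (0-based half-open offsets).
#'
#' @param spans Data frame of spans from [extract_corpus()].
#' @param path File path.
#' @return `write_spans()` returns `path` invisibly; `read_spans()` returns a
#'   span data frame.
#' @export
write_spans <- function(spans, path) {
  .write_jsonl(lapply(seq_len(nrow(spans)), function(k) {
    as.list(spans[k, c("doc_id", "start", "end", "content_start",
                       "content_end", "content", "delimiter_class")])
  }), path)
}

#' @rdname write_spans
#' @export
read_spans <- function(path) {
  recs <- .read_jsonl(path)
  if (length(recs) == 0L) {
    return(data.frame(doc_id = character(), start = integer(), end = integer(),
                      content_start = integer(), content_end = integer(),
                      content = character(), delimiter_class = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(recs, function(r) {
    data.frame(doc_id = as.character(r$doc_id), start = as.integer(r$start),
               end = as.integer(r$end),
               content_start = as.integer(r$content_start),
               content_end = as.integer(r$content_end),
               content = as.character(r$content %||% ""),
               delimiter_class = as.character(r$delimiter_class %||% NA),
               stringsAsFactors = FALSE)
  }))
}

#' Read / write gold span annotations
#'
#' Gold files are JSONL with one object per document:
#' `{"doc_id": ..., "spans": [[start, end], ...]}` (0-based half-open).
#'
#' @param path File path.
#' @param gold Data frame with `doc_id`, `start`, `end`.
#' @return `read_gold()` returns a data frame with `doc_id`, `start`, `end`;
#'   `write_gold()` returns `path` invisibly.
#' @export
read_gold <- function(path) {
  recs <- .read_jsonl(path)
  rows <- lapply(recs, function(r) {
    sp <- r$spans
    if (is.null(sp) || length(sp) == 0L) return(NULL)
    sp <- matrix(as.integer(unlist(sp)), ncol = 2L, byrow = !is.matrix(sp))
    if (is.matrix(r$spans)) sp <- matrix(as.integer(r$spans), ncol = 2L)
    data.frame(doc_id = as.character(r$doc_id), start = sp[, 1L], end = sp[, 2L],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(doc_id = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' @rdname read_gold
#' @export
write_gold <- function(gold, path) {
  ids <- unique(gold$doc_id)
  .write_jsonl(lapply(ids, function(id) {
    g <- gold[gold$doc_id == id, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    list(doc_id = id, spans = unname(Map(c, g$start, g$end)))
  }), path)
}

#' Read the event tables consumed by the cohort builder
#'
#' Admissions CSV has columns `patient_id`, `admission_date`,
#' `discharge_date`, `icd_codes` (semicolon-separated); appointments CSV has
#' `patient_id`, `date`, `status` (`attended`/`dna`); stays CSV has
#' `patient_id`, `start_date`, `end_date`.
#'
#' @param path File path.
#' @return A data frame with date columns parsed as `Date`.
#' @export
read_admissions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$admission_date <- as.Date(df$admission_date)
  df$discharge_date <- as.Date(df$discharge_date)
  stopifnot(all(df$admission_date <= df$discharge_date))
  df
}

#' @rdname read_admissions
#' @export
read_appointments <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  bad <- setdiff(unique(df$status), c("attended", "dna"))
  if (length(bad)) stop("unknown appointment status: ", paste(bad, collapse = ", "))
  df
}

#' @rdname read_admissions
#' @export
read_stays <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$start_date <- as.Date(df$start_date)
  df$end_date <- as.Date(df$end_date)
  stopifnot(all(df$start_date <= df$end_date))
  df
}

#' Read / write the matched-pair table
#'
#' One row per included patient with `case_*` and `control_*` summary columns
#' (see [build_matched_pairs()]).
#'
#' @param pairs Pair table data frame.
#' @param path File path.
#' @return `read_pairs()` returns the pair table; `write_pairs()` returns
#'   `path` invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
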