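# Rule-based detection of quoted speech in clinical free text.
#
# The scanner walks a document character by character. Quote characters come
# from a fixed inventory of paired delimiter classes; single-quote characters
# that look like apostrophes (contractions, possessives, intra-word marks) are
# never treated as delimiters, inner quotations are absorbed into the
# enclosing span, and candidate quotes longer than a configurable cap are
# discarded as improperly closed.

#' Extraction configuration
#'
#' Bundles the tunable parameters of the quoted-speech scanner.
#'
#' @param max_quote_chars Maximum length (in characters) of the quoted
#'   content. Candidates exceeding this are discarded as runaway quotes, not
#'   truncated. Default 1500.
#' @param contraction_suffixes Lowercase letter sequences that, when they
#'   immediately follow a single quote (with a letter on the quote's left and
#'   a non-letter boundary after the suffix), mark it as an apostrophe rather
#'   than a quote delimiter.
#' @param word_token_pattern Perl regular expression defining a word token for
#'   [count_tokens()]; the default matches maximal runs of letters/digits.
#' @param email_pattern,url_pattern Perl regular expressions; an extracted
#'   span whose whitespace-trimmed content matches one of these entirely is
#'   removed.
#'
#' @return An object of class `extraction_config` (a named list).
#' @export
#' @examples
#' cfg <- extraction_config()
#' cfg$max_quote_chars
extraction_config <- function(max_quote_chars = 1500L,
                              contraction_suffixes = c("c", "d", "e", "m",
                                                       "n", "s", "t", "ve",
                                                       "re", "ll", "all"),
                              word_token_pattern = "[\\p{L}\\p{N}]+",
                              email_pattern = "^[^@\\s]+@[^@\\s.]+(\\.[^@\\s.]+)+$",
                              url_pattern = "^(?i)([a-z][a-z0-9+.-]*://\\S+|www\\.\\S+)$") {
  max_quote_chars <- as.integer(max_quote_chars)
  stopifnot(length(max_quote_chars) == 1L, max_quote_chars > 0L,
            length(contraction_suffixes) >= 1L)
  suffixes <- unique(tolower(contraction_suffixes))
  structure(list(max_quote_chars = max_quote_chars,
                 contraction_suffixes = suffixes[order(-nchar(suffixes))],
                 word_token_pattern = word_token_pattern,
                 email_pattern = email_pattern,
                 url_pattern = url_pattern),
            class = "extraction_config")
}

# Quote-character inventory: four paired delimiter classes. Straight marks
# pair with themselves; curly marks pair only within their own style, since
# cross-style pairing inflates false positives.
.quote_inventory <- function() {
  data.frame(
    char  = c("\"", "“", "”", "'", "‘", "’"),
    class = c("dquote", "curly_double", "curly_double",
              "squote", "curly_single", "curly_single"),
    role  = c("both", "open", "close", "both", "open", "close"),
    single = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

.is_letter <- function(ch) {
  nzchar(ch) && grepl("^\\p{L}$", ch, perl = TRUE)
}

# TRUE when the characters after position `index` begin with a contraction
# suffix followed by a non-letter boundary (or end of text).
.contraction_follows <- function(chars, index, cfg) {
  n <- length(chars)
  for (suf in cfg$contraction_suffixes) {
    k <- nchar(suf)
    if (index + k > n) next
    nxt <- tolower(paste0(chars[(index + 1L):(index + k)], collapse = ""))
    if (nxt != suf) next
    after <- if (index + k + 1L > n) "" else chars[index + k + 1L]
    if (!.is_letter(after)) return(TRUE)
  }
  FALSE
}

.classify_at <- function(chars, index, pending, cfg) {
  inv <- .quote_inventory()
  ch <- chars[index]
  row <- inv[inv$char == ch, ]
  if (nrow(row) == 0L) stop("character at `index` is not in the quote inventory")
  left <- if (index > 1L) chars[index - 1L] else ""
  right <- if (index < length(chars)) chars[index + 1L] else ""
  if (row$single) {
    # apostrophe checks take precedence over any pairing decision
    if (.is_letter(left) &&
        (.contraction_follows(chars, index, cfg) || .is_letter(right))) {
      return("APOSTROPHE")
    }
    if (ch == "‘") return("OPEN")
    if (ch == "’") {
      return(if (identical(pending, "curly_single")) "CLOSE" else "APOSTROPHE")
    }
    # straight single quote: closes a pending same-class opener, otherwise it
    # opens only when not glued to the preceding word
    if (identical(pending, "squote")) return("CLOSE")
    if (.is_letter(left)) return("APOSTROPHE")
    return("OPEN")
  }
  if (ch == "“") return("OPEN")
  if (ch == "”") {
    return(if (identical(pending, "curly_double")) "CLOSE" else "IGNORE")
  }
  if (identical(pending, "dquote")) "CLOSE" else "OPEN"
}

#' Classify one quote character
#'
#' Decides whether the quote-inventory character at `index` acts as an opening
#' delimiter, a closing delimiter, an apostrophe, or is ignored, given the
#' scanner's pairing state. Single quotes immediately followed by a
#' contraction suffix and a non-letter boundary (with a letter on their left),
#' or sitting between two letters, are apostrophes; close-style marks are
#' accepted as closers only when a same-class opener is pending.
#'
#' @param text Character scalar.
#' @param index 1-based character position within `text`; the character there
#'   must belong to the quote inventory.
#' @param pending Delimiter class of an unclosed opener
#'   (`"dquote"`, `"curly_double"`, `"squote"`, `"curly_single"`) or
#'   `NA_character_` when no opener is pending.
#' @param cfg An [extraction_config()].
#'
#' @return One of `"OPEN"`, `"CLOSE"`, `"APOSTROPHE"`, `"IGNORE"`.
#' @export
#' @examples
#' classify_quote_character("can't", 4)            # "APOSTROPHE"
#' classify_quote_character("“abc”", 1)  # "OPEN"
classify_quote_character <- function(text, index, pending = NA_character_,
                                     cfg = extraction_config()) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, NULL)[[1L]]
  index <- as.integer(index)
  if (is.na(index) || index < 1L || index > length(chars)) {
    stop("`index` is out of range for `text`")
  }
  .classify_at(chars, index, pending, cfg)
}

#' Extract quoted-speech spans from text
#'
#' Scans `text` left to right. When a delimiter opens, everything up to the
#' matching same-class closer is one quotation; quote characters of other
#' classes inside it (subquotations) are absorbed, never reported separately.
#' Candidates whose content exceeds `cfg$max_quote_chars`, or that never
#' close, are discarded and scanning resumes just after the stray opener.
#' Spans whose trimmed content is entirely an email address or URL are
#' removed.
#'
#' @param text Character scalar (may be empty).
#' @param cfg An [extraction_config()].
#'
#' @return A data frame with one row per span and columns `start`, `end`,
#'   `content_start`, `content_end` (0-based, half-open character offsets;
#'   `start`/`end` include the delimiters, `content_*` exclude them),
#'   `content`, and `delimiter_class`. Rows are sorted by `start` and spans
#'   never overlap.
#' @export
#' @examples
#' extract_quoted_spans('He said "I can\'t go on" today')
extract_quoted_spans <- function(text, cfg = extraction_config()) {
  stopifnot(is.character(text), length(text) == 1L, inherits(cfg, "extraction_config"))
  empty <- data.frame(start = integer(), end = integer(),
                      content_start = integer(), content_end = integer(),
                      content = character(), delimiter_class = character(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  chars <- strsplit(text, NULL)[[1L]]
  n <- length(chars)
  inv <- .quote_inventory()
  in_inventory <- chars %in% inv$char
  if (!any(in_inventory)) return(empty)

  limit <- cfg$max_quote_chars
  out <- vector("list", 16L); n_out <- 0L
  i <- 1L
  while (i <= n) {
    if (!in_inventory[i]) { i <- i + 1L; next }
    if (.classify_at(chars, i, NA_character_, cfg) != "OPEN") { i <- i + 1L; next }
    cls <- inv$class[inv$char == chars[i]]
    closer_chars <- inv$char[inv$class == cls & inv$role != "open"]
    opener_chars <- setdiff(inv$char[inv$class == cls & inv$role == "open"],
                            closer_chars)
    j <- i + 1L
    depth <- 1L  # same-class nesting, trackable only for curly classes
    closed <- FALSE
    while (j <= n) {
      if ((j - i - 1L) > limit) break  # runaway: content already too long
      if (in_inventory[j]) {
        if (length(opener_chars) && chars[j] %in% opener_chars &&
            .classify_at(chars, j, cls, cfg) == "OPEN") {
          depth <- depth + 1L
        } else if (chars[j] %in% closer_chars &&
                   .classify_at(chars, j, cls, cfg) == "CLOSE") {
          depth <- depth - 1L
          if (depth == 0L) { closed <- TRUE; break }
        }
      }
      j <- j + 1L
    }
    if (!closed) { i <- i + 1L; next }  # stray opener, rescan inside
    content <- if (j - i > 1L) paste0(chars[(i + 1L):(j - 1L)], collapse = "") else ""
    trimmed <- trimws(content)
    keep <- !(nzchar(trimmed) &&
                (grepl(cfg$email_pattern, trimmed, perl = TRUE) ||
                   grepl(cfg$url_pattern, trimmed, perl = TRUE)))
    if (keep) {
      n_out <- n_out + 1L
      if (n_out > length(out)) out <- c(out, vector("list", length(out)))
      out[[n_out]] <- list(start = i - 1L, end = j,
                           content_start = i, content_end = j - 1L,
                           content = content, delimiter_class = cls)
    }
    i <- j + 1L
  }
  if (n_out == 0L) return(empty)
  out <- out[seq_len(n_out)]
  data.frame(start = vapply(out, `[[`, integer(1), "start"),
             end = vapply(out, `[[`, integer(1), "end"),
             content_start = vapply(out, `[[`, integer(1), "content_start"),
             content_end = vapply(out, `[[`, integer(1), "content_end"),
             content = vapply(out, `[[`, character(1), "content"),
             delimiter_class = vapply(out, `[[`, character(1), "delimiter_class"),
             stringsAsFactors = FALSE)
}

#' Extract spans for every document in a corpus
#'
#' @param docs Data frame with at least `doc_id` and `text` columns (see
#'   [read_documents()]).
#' @param cfg An [extraction_config()].
#'
#' @return A data frame of spans as in [extract_quoted_spans()] with a leading
#'   `doc_id` column; documents without quotations contribute no rows.
#' @export
extract_corpus <- function(docs, cfg = extraction_config()) {
  stopifnot(is.data.frame(docs), all(c("doc_id", "text") %in% names(docs)))
  res <- lapply(seq_len(nrow(docs)), function(k) {
    sp <- extract_quoted_spans(docs$text[k], cfg)
    if (nrow(sp) == 0L) return(NULL)
    cbind(doc_id = docs$doc_id[k], sp, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    return(data.frame(doc_id = character(), start = integer(), end = integer(),
                      content_start = integer(), content_end = integer(),
                      content = character(), delimiter_class = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Count word tokens
#'
#' Counts maximal runs of letters/digits (punctuation is never a token).
#'
#' @param text Character vector.
#' @param pattern Perl regex defining a token; default from
#'   [extraction_config()].
#'
#' @return Integer vector of token counts; empty or `NA` text counts 0.
#' @export
#' @examples
#' count_tokens("patient reports low mood")  # 4
count_tokens <- function(text, pattern = extraction_config()$word_token_pattern) {
  vapply(text, function(x) {
    if (is.na(x) || !nzchar(x)) return(0L)
    m <- gregexpr(pattern, x, perl = TRUE)[[1L]]
    if (m[1L] == -1L) 0L else length(m)
  }, integer(1), USE.NAMES = FALSE)
}

#' Quotations per token
#'
#' Normalises a quotation count for document length.
#'
#' @param n_quotes,n_tokens Non-negative counts (vectorised).
#'
#' @return `n_quotes / n_tokens`, with 0 when both are 0.
#' @export
#' @examples
#' quotes_per_token(4, 200)  # 0.02
quotes_per_token <- function(n_quotes, n_tokens) {
  stopifnot(all(n_quotes >= 0), all(n_tokens >= 0))
  if (any(n_tokens == 0 & n_quotes > 0)) {
    stop("undefined rate: quotations present but zero tokens")
  }
  ifelse(n_tokens == 0, 0, n_quotes / n_tokens)
}
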