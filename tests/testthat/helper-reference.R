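# Independent reference implementations used as oracles. These walk inputs
# by brute force and are written against the stated rules, not against the
# package internals.

# --- reference quoted-span automaton -------------------------------------
# Explicit state machine over codepoints. Classes: 1 = straight double,
# 2 = curly double, 3 = straight single, 4 = curly single.

ref_suffix_follows <- function(text, i) {
  rest <- substr(text, i + 1L, nchar(text))
  grepl("^(all|ve|re|ll|[cdemnst])($|[^a-zA-Z])", rest, ignore.case = TRUE)
}

ref_letter <- function(text, i) {
  if (i < 1L || i > nchar(text)) return(FALSE)
  grepl("^[a-zA-Z]$", substr(text, i, i))
}

# is the single-quote char at i an apostrophe?
ref_apostrophe <- function(text, i) {
  ref_letter(text, i - 1L) &&
    (ref_suffix_follows(text, i) || ref_letter(text, i + 1L))
}

ref_extract <- function(text, max_chars = 1500L) {
  cp <- utf8ToInt(text)
  n <- length(cp)
  opens <- c(`34` = 1L, `8220` = 2L, `39` = 3L, `8216` = 4L)
  closes <- c(`34` = 1L, `8221` = 2L, `39` = 3L, `8217` = 4L)
  out <- list()
  i <- 1L
  while (i <= n) {
    key <- as.character(cp[i])
    cls <- unname(opens[key])
    is_open <- FALSE
    if (!is.na(cls)) {
      if (cls %in% c(1L, 2L)) {
        is_open <- TRUE
      } else if (!ref_apostrophe(text, i)) {
        # straight single opens only when not glued to a word
        is_open <- cls == 4L || !ref_letter(text, i - 1L)
      }
    }
    if (!is_open) { i <- i + 1L; next }
    j <- i + 1L
    depth <- 1L
    closed_at <- NA_integer_
    while (j <= n && (j - i - 1L) <= max_chars) {
      kj <- as.character(cp[j])
      if (cls %in% c(2L, 4L) && identical(unname(opens[kj]), cls)) {
        if (cls == 2L || !ref_apostrophe(text, j)) depth <- depth + 1L
      } else if (identical(unname(closes[kj]), cls)) {
        ok <- switch(cls,
                     TRUE,                                  # straight double
                     TRUE,                                  # curly double
                     !ref_apostrophe(text, j),              # straight single
                     !ref_apostrophe(text, j))              # curly single
        if (ok) {
          depth <- depth - 1L
          if (depth == 0L) { closed_at <- j; break }
        }
      }
      j <- j + 1L
    }
    if (is.na(closed_at)) { i <- i + 1L; next }
    content <- substr(text, i + 1L, closed_at - 1L)
    trimmed <- trimws(content)
    email <- grepl("^[^@\\s]+@[^@\\s.]+(\\.[^@\\s.]+)+$", trimmed, perl = TRUE)
    url <- grepl("^([a-z][a-z0-9+.-]*://\\S+|www\\.\\S+)$", trimmed,
                 perl = TRUE, ignore.case = TRUE)
    if (!(nzchar(trimmed) && (email || url))) {
      out[[length(out) + 1L]] <- c(start = i - 1L, end = closed_at)
    }
    i <- closed_at + 1L
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

# random fuzz text over a small alphabet with quote characters over-weighted
fuzz_text <- function(len) {
  alphabet <- c(letters[1:8], " ", " ", ".", ",",
                "\"", "“", "”", "'", "‘", "’")
  weights <- c(rep(3, 8), 6, 6, 1, 1, rep(2, 6))
  paste0(sample(alphabet, len, replace = TRUE, prob = weights), collapse = "")
}

# --- reference conditional log-likelihood --------------------------------
# direct transcription of the 1:1 pair likelihood, used for grid searches
ref_clr_loglik <- function(beta, d) {
  eta <- as.vector(d %*% beta)
  sum(-log1p(exp(-eta)))
}

# 0-based substring helper: content of text[(start+1):end] in R indexing
substr0 <- function(text, start, end) substring(text, start + 1L, end)

# quick corpus for pipeline tests
small_corpus <- function(n = 25, seed = 99, ...) {
  simulate_cohort(simulation_config(n_patients = n, seed = seed,
                                    docs_per_window_mean = 4,
                                    filler_docs_mean = 1, ...))
}
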