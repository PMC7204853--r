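test_that("single quotes in contractions and possessives are apostrophes", {
  expect_identical(classify_quote_character("can't", 4), "APOSTROPHE")
  expect_identical(classify_quote_character("they've gone", 5), "APOSTROPHE")
  expect_identical(classify_quote_character("o'clock", 2), "APOSTROPHE")
  # trailing possessive with no pending opener
  expect_identical(classify_quote_character("the patients' needs", 13),
                   "APOSTROPHE")
  # the same character closes when an opener is pending
  expect_identical(classify_quote_character("the patients' needs", 13,
                                            pending = "squote"), "CLOSE")
  expect_identical(classify_quote_character("“abc”", 1), "OPEN")
  expect_identical(classify_quote_character("“abc”", 5,
                                            pending = "curly_double"), "CLOSE")
  # stray curly closer with nothing pending is ignored
  expect_identical(classify_quote_character("abc” def", 4), "IGNORE")
  expect_error(classify_quote_character("a'b", 9), "out of range")
  expect_error(classify_quote_character("abc", 2), "inventory")
})

test_that("extraction handles contractions, nesting, emails and runaways", {
  expect_identical(nrow(extract_quoted_spans("no inventory characters")), 0L)
  expect_identical(nrow(extract_quoted_spans("")), 0L)

  s <- extract_quoted_spans("He said \"I can't go on\" today")
  expect_identical(s$content, "I can't go on")
  expect_identical(s$delimiter_class, "dquote")

  # subquotations (same or different class) are absorbed into the outer span
  s <- extract_quoted_spans("“She said “he told me ‘leave now’ then” loudly”")
  expect_identical(nrow(s), 1L)
  expect_identical(s$content, "She said “he told me ‘leave now’ then” loudly")

  # email- and URL-only quotes are removed
  expect_identical(nrow(extract_quoted_spans('"john.doe@example.org"')), 0L)
  expect_identical(nrow(extract_quoted_spans('"www.nhs.uk/self-help"')), 0L)
  expect_identical(nrow(extract_quoted_spans('" https://x.org/a "')), 0L)
  # but quotes merely containing one are kept
  expect_identical(nrow(extract_quoted_spans('"email me at a@b.org today"')), 1L)

  # unclosed quote followed by a long tail is never extracted
  runaway <- paste0('"', strrep("x", 2000))
  expect_identical(nrow(extract_quoted_spans(runaway)), 0L)
  # a closer beyond the cap does not rescue the span
  too_long <- paste0('"', strrep("x", 1501), '"')
  expect_identical(nrow(extract_quoted_spans(too_long)), 0L)
  at_cap <- paste0('"', strrep("x", 1500), '"')
  expect_identical(nrow(extract_quoted_spans(at_cap)), 1L)
  # scanning resumes after a stray opener, recovering later quotes
  s <- extract_quoted_spans(paste0('" ', strrep("y ", 900), '“found”'))
  expect_identical(s$content, "found")
})

test_that("span offsets are 0-based, half-open and consistent with content", {
  text <- "start “one” mid \"two\" 'three' end"
  s <- extract_quoted_spans(text)
  expect_identical(nrow(s), 3L)
  expect_identical(substr0(text, s$content_start, s$content_end),
                   c("one", "two", "three"))
  expect_identical(substr0(text, s$start, s$end),
                   c("“one”", "\"two\"", "'three'"))
})

test_that("token counting matches the word-token pattern", {
  expect_identical(count_tokens(""), 0L)
  expect_identical(count_tokens("patient reports low mood"), 4L)
  expect_identical(count_tokens("He said \"stop\" twice."), 4L)
  expect_identical(count_tokens("dose 20mg, b.d."), 4L)
  expect_identical(count_tokens(c("a b", "", "c")), c(2L, 0L, 1L))
})

test_that("quotes-per-token handles degenerate denominators", {
  expect_identical(quotes_per_token(0, 100), 0)
  expect_identical(quotes_per_token(4, 200), 0.02)
  expect_identical(quotes_per_token(0, 0), 0)
  expect_error(quotes_per_token(1, 0), "undefined rate")
})

test_that("extracted spans satisfy ordering, bounds and length invariants", {
  set.seed(401)
  cfg <- extraction_config(max_quote_chars = 40L)
  for (k in 1:150) {
    text <- fuzz_text(sample(10:200, 1))
    s <- extract_quoted_spans(text, cfg)
    if (nrow(s) == 0) next
    expect_true(all(s$start >= 0 & s$end <= nchar(text)))
    expect_true(all(s$start < s$end))
    expect_false(is.unsorted(s$start))
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
    expect_true(all(nchar(s$content) <= 40L))
    expect_identical(substr0(text, s$content_start, s$content_end), s$content)
  }
})

test_that("texts stripped of quote characters yield no spans", {
  set.seed(402)
  for (k in 1:25) {
    text <- fuzz_text(120)
    stripped <- gsub("[\"'‘’“”]", "", text)
    expect_identical(nrow(extract_quoted_spans(stripped)), 0L)
  }
})

test_that("extraction is deterministic and idempotent", {
  set.seed(403)
  text <- fuzz_text(300)
  a <- extract_quoted_spans(text)
  b <- extract_quoted_spans(text)
  expect_identical(a, b)
})

test_that("scanner agrees with the brute-force reference automaton", {
  set.seed(404)
  cfg <- extraction_config(max_quote_chars = 30L)
  for (k in 1:400) {
    text <- fuzz_text(sample(5:200, 1))
    got <- extract_quoted_spans(text, cfg)[, c("start", "end")]
    want <- ref_extract(text, max_chars = 30L)
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want, label = sprintf("text <<%s>>", text))
  }
})
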