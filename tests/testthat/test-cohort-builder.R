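d <- function(x) as.Date(x)

test_that("ICD-10 self-harm categories match the stated ranges exactly", {
  # independent oracle: enumerate every X/Y category and apply the printed
  # ranges X60-X84, Y10-Y34, Y87 directly
  cats <- c(sprintf("X%02d", 0:99), sprintf("Y%02d", 0:99))
  num <- as.integer(substr(cats, 2, 3))
  letter <- substr(cats, 1, 1)
  want <- (letter == "X" & num >= 60 & num <= 84) |
    (letter == "Y" & num >= 10 & num <= 34) |
    (letter == "Y" & num == 87)
  expect_identical(is_suicide_attempt_code(cats), want)

  expect_true(is_suicide_attempt_code("X61"))
  expect_false(is_suicide_attempt_code("X85"))
  expect_true(is_suicide_attempt_code("Y87.0"))
  expect_false(is_suicide_attempt_code("Y35"))
  expect_true(is_suicide_attempt_code("x700"))  # subcodes inherit, any case
  expect_error(is_suicide_attempt_code("12X"), "malformed")
})

test_that("qualifying admissions need a code and different dates", {
  expect_true(is_qualifying_admission("X61", d("2010-01-01"), d("2010-01-02")))
  expect_false(is_qualifying_admission("X61", d("2010-01-01"), d("2010-01-01")))
  expect_false(is_qualifying_admission("F32.1", d("2010-01-01"), d("2010-01-05")))
  expect_true(is_qualifying_admission("F32.1;Y20", d("2010-01-01"), d("2010-01-05")))
  expect_error(is_qualifying_admission("X61", d("2010-01-05"), d("2010-01-01")))
})

test_that("index selection takes the earliest qualifying admission", {
  adm <- data.frame(
    patient_id = "p1",
    admission_date = d(c("2014-07-09", "2012-03-01", "2011-05-01")),
    discharge_date = d(c("2014-07-12", "2012-03-03", "2011-05-01")),
    icd_codes = c("X61", "X70", "X61"),  # third is same-day, never qualifies
    stringsAsFactors = FALSE)
  expect_identical(select_index_admission(adm)$admission_date, d("2012-03-01"))

  # tie on date broken by longest stay
  tie <- data.frame(patient_id = "p1",
                    admission_date = d(c("2012-03-01", "2012-03-01")),
                    discharge_date = d(c("2012-03-02", "2012-03-08")),
                    icd_codes = c("X61", "Y25"), stringsAsFactors = FALSE)
  expect_identical(select_index_admission(tie)$icd_codes, "Y25")

  none <- data.frame(patient_id = "p1", admission_date = d("2012-03-01"),
                     discharge_date = d("2012-03-05"), icd_codes = "F20",
                     stringsAsFactors = FALSE)
  expect_null(select_index_admission(none))
  # study-window filter excludes the early admission
  expect_identical(
    select_index_admission(adm, study_start = d("2013-01-01"))$admission_date,
    d("2014-07-09"))
})

test_that("window assignment is inclusive on all four boundaries", {
  idx <- d("2015-06-30")
  got <- assign_window(idx - (-5:120), idx)
  dd <- -5:120
  want <- ifelse(dd >= 1 & dd <= 30, "case",
                 ifelse(dd >= 61 & dd <= 90, "control", "neither"))
  expect_identical(got, want)
  expect_error(assign_window(idx, idx, case_window = c(1, 61),
                             control_window = c(61, 90)), "overlap")
})

test_that("period summaries aggregate documents, appointments and bed-days", {
  idx <- d("2015-06-30")
  no_docs <- data.frame(doc_id = character(), timestamp = d(character()),
                        text = character(), stringsAsFactors = FALSE)
  no_app <- data.frame(date = d(character()), status = character())
  no_stay <- data.frame(start_date = d(character()), end_date = d(character()))

  s <- summarise_period("case", idx, no_docs, NULL, no_app, no_stay)
  expect_identical(s$n_documents, 0L)
  expect_identical(s$any_quote, 0L)
  expect_identical(s$bed_days, 0L)

  docs <- data.frame(doc_id = c("a", "b"), timestamp = idx - c(10, 70),
                     text = "", n_quotes = c(2L, 5L),
                     n_tokens = c(100L, 50L), stringsAsFactors = FALSE)
  s <- summarise_period("case", idx, docs, NULL, no_app, no_stay)
  expect_identical(s$n_quotes, 2L)
  expect_equal(s$quotes_per_token, 0.02)
  expect_identical(s$any_quote, 1L)
  sc <- summarise_period("control", idx, docs, NULL, no_app, no_stay)
  expect_identical(sc$n_quotes, 5L)

  # quote counts can also come from extracted spans
  docs2 <- data.frame(doc_id = c("a", "b"), timestamp = idx - c(10, 70),
                      text = c('x "q" y', "plain"), stringsAsFactors = FALSE)
  spans <- extract_corpus(docs2)
  s2 <- summarise_period("case", idx, docs2, spans, no_app, no_stay)
  expect_identical(s2$n_quotes, 1L)
  expect_identical(s2$n_tokens, 3L)

  app <- data.frame(date = idx - c(1, 15, 30, 31, 65, 5),
                    status = c("attended", "dna", "attended", "attended",
                               "attended", "dna"))
  s3 <- summarise_period("case", idx, no_docs, NULL, app, no_stay)
  expect_identical(s3$face_to_face, 2L)
  expect_identical(s3$dna, 2L)

  # a stay covering the whole case window yields 30 bed-days
  stay <- data.frame(start_date = idx - 40, end_date = idx + 5)
  s4 <- summarise_period("case", idx, no_docs, NULL, no_app, stay)
  expect_identical(s4$bed_days, 30L)
})

test_that("bed-day counting matches a day-by-day oracle", {
  set.seed(601)
  idx <- d("2013-03-15")
  win <- seq(idx - 30, idx - 1, by = "day")
  for (k in 1:50) {
    n_stays <- sample(0:3, 1)
    start <- idx - sample(0:100, n_stays, replace = TRUE)
    len <- sample(0:40, n_stays, replace = TRUE)
    stays <- data.frame(start_date = start, end_date = start + len)
    # oracle: enumerate each window day, check occupancy (nights: start <= day < end)
    occupied <- vapply(win, function(day) {
      any(stays$start_date <= day & day < stays$end_date)
    }, logical(1))
    s <- summarise_period("case", idx,
                          data.frame(doc_id = character(),
                                     timestamp = d(character()),
                                     text = character()),
                          NULL,
                          data.frame(date = d(character()), status = character()),
                          stays)
    expect_identical(s$bed_days, as.integer(sum(occupied)))
    expect_lte(s$bed_days, 30L)
  }
})

test_that("pair construction enforces the both-windows document rule", {
  idx <- d("2016-02-01")
  adm <- data.frame(patient_id = c("p1", "p2", "p3"),
                    admission_date = rep(idx, 3),
                    discharge_date = rep(idx + 2, 3),
                    icd_codes = c("X61", "X61", "F20"),
                    stringsAsFactors = FALSE)
  docs <- data.frame(
    doc_id = c("d1", "d2", "d3"),
    patient_id = c("p1", "p1", "p2"),
    timestamp = c(idx - 5, idx - 70, idx - 5),  # p2 lacks control docs
    doc_type = "case_note",
    text = c('"quoted one" text', "plain note", "plain"),
    stringsAsFactors = FALSE)
  no_app <- data.frame(patient_id = character(), date = d(character()),
                       status = character())
  no_stay <- data.frame(patient_id = character(), start_date = d(character()),
                        end_date = d(character()))
  pairs <- build_matched_pairs(docs, adm, no_app, no_stay)
  expect_identical(pairs$patient_id, "p1")
  expect_identical(pairs$case_any_quote, 1L)
  expect_identical(pairs$control_any_quote, 0L)
  audit <- attr(pairs, "audit")
  expect_identical(audit$included, 1L)
  expect_identical(audit$no_control_documents, 1L)
  expect_identical(audit$no_index_admission, 1L)

  empty <- build_matched_pairs(docs[0, ], adm[0, ], no_app, no_stay)
  expect_identical(nrow(empty), 0L)
})

test_that("summaries are invariant under a constant shift of all dates", {
  corpus <- small_corpus(n = 12, seed = 77)
  shift <- 1234L
  sh <- corpus
  sh$documents$timestamp <- sh$documents$timestamp + shift
  sh$admissions$admission_date <- sh$admissions$admission_date + shift
  sh$admissions$discharge_date <- sh$admissions$discharge_date + shift
  sh$appointments$date <- sh$appointments$date + shift
  sh$stays$start_date <- sh$stays$start_date + shift
  sh$stays$end_date <- sh$stays$end_date + shift
  p1 <- corpus_pair_table(corpus, use_gold = TRUE)
  p2 <- corpus_pair_table(sh, use_gold = TRUE)
  p2$index_date <- p1$index_date  # the index itself shifts; summaries must not
  attr(p1, "audit") <- attr(p2, "audit") <- NULL
  expect_equal(p1, p2)
})
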