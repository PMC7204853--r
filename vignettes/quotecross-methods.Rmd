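---
title: "Quoted speech in clinical text and the case-crossover design: methods"
author: "quotecross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quoted speech in clinical text and the case-crossover design: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quotecross)
```

## The question and the design

Clinicians sometimes record a patient's own words verbatim, inside quotation
marks. If quoting reflects heightened perceived risk, the rate of quoted
speech in a patient's record might rise in the weeks before a suicide
attempt. `quotecross` implements the machinery to test that hypothesis with
a case-crossover design: each patient serves as their own control, comparing
a hazard window (1--30 days before the index admission) against an earlier
referent window (61--90 days before). Because the comparison is within
person, stable confounders — sex, ethnicity, diagnosis, long-run recording
style — cancel out. Time-varying care intensity does not, so attended
appointments, missed (DNA) appointments and inpatient bed-days are carried
as covariates.

The package has four working parts: a rule-based quoted-speech extractor, a
span-level evaluator, a cohort builder that turns raw event tables into a
matched-pair analysis table, and a 1:1 conditional logistic regression
fitter. A synthetic EHR generator makes the whole chain testable without
access to patient records.

## Quoted-speech extraction

The extractor scans each document character by character over a fixed
inventory of delimiter classes: straight double `"` (pairs with itself),
curly `“`...`”`, straight single `'` (pairs with itself), and curly
`‘`...`’`. Cross-style pairing (opening with `“`, closing with `"`) is
deliberately rejected: mismatched styles are overwhelmingly typographical
noise, and accepting them trades a few true spans for many false positives.

The hard part of quote detection in English is the apostrophe. A single
quote is treated as an apostrophe, never a delimiter, when

* it is flanked by a letter on the left and immediately followed by one of
  the contraction suffixes `c, d, e, m, n, s, t, ve, re, ll, all` and then a
  non-letter boundary (`can't`, `she'll`, `o'clock`-style forms are caught
  by the next rule), or
* it sits between two letters (`o'clock`, `D'Souza`).

The same check is applied before accepting a closing quote. Beyond it, a
close-style single quote (`’`, or `'` with a pending opener) is accepted as
a closer only when an unclosed opener of the same class is pending; a
straight single quote glued to the end of a word with no opener pending
(`the patients' needs`) is an apostrophe. This pending-opener reading is the
package's own resolution of an ambiguity in how an "end-quote check" should
behave; it is the conservative choice, biased against false spans, and it is
pinned down by unit tests and a brute-force reference automaton.

Once a quote opens, everything up to its same-class closer is one span:
inner quotations of any class are absorbed, and for the curly classes
(whose openers and closers are distinct) same-class nesting is tracked by
depth, so `“she said “leave ‘now’ then” loudly”` is a single span. Candidate
spans whose content exceeds 1500 characters are discarded outright — an
unclosed quote would otherwise swallow the rest of the document — and
scanning resumes just after the stray opener, so later well-formed quotes
are still found. Spans whose trimmed content is entirely an email address or
URL are dropped. Offsets are 0-based and half-open, with `content` excluding
the delimiters; extraction is deterministic and idempotent.

Exposure is normalised for text volume as quotations per word token, where a
token is a maximal run of letters/digits (the pattern is configurable).
The literal quotes-per-token rate is small by construction — a handful of
quotations against hundreds of words — so analyses of the rate exposure are
interpreted per unit difference, and the binary any-quotation exposure is
the primary contrast.

## Scoring extractions

`match_spans()` counts a predicted span as a true positive only when its
`(start, end)` pair exactly equals a gold span. Exact matching is the
strictest reproducible criterion; overlap-based credit can be layered on
top but is not implemented. Metrics follow the usual definitions
(precision $tp/(tp+fp)$, recall $tp/(tp+fn)$, F the harmonic mean), plus a
span-level accuracy $tp/(tp+fp+fn)$ — a Jaccard-style agreement that, unlike
F, penalises both error types jointly; when precision and recall are 0.92
and 0.93 it evaluates to 0.86. Counts are pooled over documents
(micro-averaging). Degenerate denominators (no predictions, no gold) score 1
by convention and are flagged.

## Cohort construction

An admission qualifies as a hospitalised suicide attempt when any of its
ICD-10 codes falls in the categories X60--X84 (intentional self-harm),
Y10--Y34 (undetermined intent) or Y87 (sequelae), matched on the
three-character category so subcodes inherit, and when the stay lasted at
least 24 hours, operationalised as admission and discharge on different
dates. The index date is the admission date of the earliest qualifying
admission (ties: longest stay, then input order), optionally restricted to a
study period.

All window logic is day-level: with $d$ = index date minus event date,
$d \in [1, 30]$ is the case window and $d \in [61, 90]$ the control window,
boundaries inclusive; the index day itself and the 31--60 day gap belong to
neither. Bed-days are the distinct calendar days of the window intersected
with any stay interval, counting occupied nights (a same-day admission
contributes none), so a window's bed-days never exceed 30. Patients enter
the pair table only with at least one document in *both* windows; exclusion
counts are reported in an audit record. All summaries are invariant under a
constant shift of every date, which the tests assert.

## Matched-pair inference

Univariate comparisons use the classical two-tailed paired t-test on
case-minus-control differences. Two degenerate conventions: identical
vectors return a well-defined null result ($t = 0$, $p = 1$), while constant
nonzero differences are an error, since the statistic is undefined.

The main model is 1:1 conditional logistic regression. For pair $i$ with
covariate vectors $x^{case}_i$ and $x^{ctrl}_i$, the conditional likelihood

$$L(\beta) = \prod_i \frac{e^{\beta' x^{case}_i}}
  {e^{\beta' x^{case}_i} + e^{\beta' x^{ctrl}_i}}$$

depends only on the differences $d_i = x^{case}_i - x^{ctrl}_i$ and equals
an intercept-free logistic regression on $d_i$ with outcome fixed at one.
The fitter maximises it by Newton--Raphson with the analytic score and
observed information, starting at $\beta = 0$, converging when the maximum
absolute score falls below $10^{-8}$ (or the step below $10^{-10}$), capped
at 50 iterations. Columns are internally rescaled to unit maximum absolute
difference so that the divergence guard (|scaled coefficient| > 15, or a
singular information matrix) is scale-free; estimates and the covariance are
mapped back afterwards. Complete separation and all-zero difference sets are
reported as errors, not as numbers. Pairs with all-zero differences carry no
information, are excluded from the likelihood, and are counted out of
`n_informative_pairs`. Confidence intervals are Wald on the log-odds scale,
$\exp(\hat\beta \pm 1.96\,SE)$, matching the symmetric intervals standard in
this literature; profile-likelihood intervals are out of scope.

For a single binary exposure the model collapses to the discordant-pair
closed form $\widehat{OR} = n_{10}/n_{01}$ with
$SE(\log OR) = \sqrt{1/n_{10} + 1/n_{01}}$, and the tests require the
Newton--Raphson path to reproduce it to better than six significant figures
across random tables; `survival::clogit` serves as an independent
cross-check on multi-covariate fits. Covariates enter as raw within-pair
count differences, unscaled, so odds ratios are per unit count.

`reconstruct_pair_exposures()` expands marginal cohort counts (total pairs,
pairs exposed in each window, pairs exposed in both) into an explicit
pair-level exposure table; fitting the unadjusted model to such a
reconstruction is how the package's acceptance script recomputes its
headline odds ratio from cohort counts of 1503 / 919 / 877 / 625, giving
OR 1.17 (95% CI 0.99 to 1.38).

## The synthetic EHR generator

`simulate_cohort()` emulates the data structure the pipeline consumes: per
patient, an index admission carrying a qualifying ICD-10 code (salted with
non-qualifying and later admissions that the index selector must skip),
Poisson document counts in the case window, control window and the 31--60
day gap, per-document quote presence, Poisson appointment and DNA counts,
and occasional inpatient stays.

Defaults were chosen once to mirror the scale of a mental-healthcare record
stream around a hospitalised attempt: 15 documents per 30-day window on
average; per-document quote probabilities 0.0583 (control) and 0.0629
(case), calibrated so the marginal probability of any quotation in a window
is 58.3% and 61.1%; attended-appointment rates 2.47 / 2.92 and DNA rates
0.38 / 0.47 per window (control / case); stays with probability 0.15 per
window and a geometric mean length of 15 days, giving roughly 2.2 expected
bed-days. With document count $N \sim$ Poisson($\lambda$), truncated at
$N \ge 1$ for inclusion-ready cohorts, and per-document probability $p$, the
marginal exposure probability is
$P = 1 - (e^{-\lambda p} - e^{-\lambda})/(1 - e^{-\lambda})$
(`window_quote_probability()`); the implied pair-level discordant odds ratio
is the odds ratio of the case and control marginals, computed numerically
into `true_parameters` rather than assumed, and
`calibrate_case_probability()` inverts the relation to hit a requested OR.

Document text is assembled from clinical-style clause templates over a small
vocabulary, mixing all four delimiter classes, with gold offsets recorded at
insertion. Salting exercises every rejection rule: contractions and
possessives in filler text, email-only and URL-only quotes, and per-document
unclosed quotes (half of them followed by a tail long enough to trip the
1500-character cap). All salt is excluded from gold and designed to be
correctly rejected, so gold-versus-extracted equality is exact on salted
corpora — the round-trip the tests assert on over a thousand documents.

What the generator does not emulate: realistic clinical language, speaker
identity, ICD code frequencies beyond the presence of qualifying codes,
document-length heterogeneity, or correlation between quoting and care
intensity within patient. Passing tests therefore demonstrate the
correctness of the machinery, not the extractor's field performance on real
clinical prose, which can only be estimated against human annotation.

With `text = FALSE` the generator keeps per-document gold quote and token
counts without composing prose. The count-generating process is identical,
so simulation studies of the inference chain run in milliseconds per
replicate; `corpus_pair_table(method = "fast")` aggregates pair tables with
vectorised group sums and is required by the tests to agree exactly with the
row-by-row cohort builder.

## Simulation studies and problem sizes

The calibration study in the test suite uses 500 replicates of 2000-patient
cohorts, a size chosen to keep Monte-Carlo error on a coverage proportion
near one percentage point: at a true pair-level exposure OR of 1.5 the 95%
Wald interval must cover the true log-OR in 92--98% of replicates, and at
the null the Wald test must reject in 3--7%. The extraction round-trip runs
on a corpus of about 1100 gold-annotated salted documents. Equivalence with
the reference automaton is fuzz-tested on several hundred short adversarial
texts dense in quote characters.

## Known limitations

* Exposure windows are fixed at day resolution; time-of-day is ignored.
* The evaluator has no partial-credit overlap scoring.
* Only 1:1 matched sets are supported — no m:n conditional likelihoods,
  robust variances, or exact conditional inference.
* The extractor processes text as-is (no Unicode normalisation); quote
  characters outside the four-class inventory (e.g. `„`) are ignored.
* Speaker attribution is out of scope: a quotation is counted whether the
  quoted words are the patient's or anyone else's.
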