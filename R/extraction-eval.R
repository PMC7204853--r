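# Scoring of predicted quote spans against gold annotations.
#
# Matching is exact on (start, end) offsets: a prediction is a true positive
# only when it reproduces a gold span's boundaries exactly. Counts are
# micro-averaged (pooled) over documents.

.check_spans_sorted <- function(spans, what) {
  if (length(spans$start) == 0L) return(invisible(TRUE))
  if (is.unsorted(spans$start, strictly = FALSE)) {
    stop(what, " spans must be sorted by start offset")
  }
  if (length(spans$start) > 1L &&
      any(spans$start[-1L] < spans$end[-length(spans$end)])) {
    stop(what, " spans must be non-overlapping")
  }
  invisible(TRUE)
}

#' Match predicted spans to gold spans
#'
#' A predicted span is a true positive iff its `(start, end)` pair exactly
#' equals a gold span; each gold span is consumed by at most one prediction.
#' Unmatched predictions are false positives, unmatched gold spans false
#' negatives.
#'
#' @param predicted,gold Data frames (or lists) with `start` and `end`
#'   columns of character offsets, sorted by `start` and non-overlapping.
#'
#' @return Named integer vector with elements `tp`, `fp`, `fn`.
#' @export
#' @examples
#' match_spans(data.frame(start = c(0, 10), end = c(5, 20)),
#'             data.frame(start = c(0, 50), end = c(5, 60)))
match_spans <- function(predicted, gold) {
  p <- data.frame(start = as.integer(predicted$start),
                  end = as.integer(predicted$end))
  g <- data.frame(start = as.integer(gold$start),
                  end = as.integer(gold$end))
  .check_spans_sorted(p, "predicted")
  .check_spans_sorted(g, "gold")
  pk <- paste(p$start, p$end)
  gk <- paste(g$start, g$end)
  # offsets within a document are unique once sorted/non-overlapping, so set
  # intersection is the same as one-to-one matching
  tp <- sum(pk %in% gk)
  c(tp = tp, fp = nrow(p) - tp, fn = nrow(g) - tp)
}

#' Precision, recall, F score and span-level accuracy from match counts
#'
#' Definitions: precision = tp/(tp+fp), recall = tp/(tp+fn), F = harmonic
#' mean of precision and recall, accuracy = tp/(tp+fp+fn) (a Jaccard-style
#' agreement over predicted and gold spans). A degenerate denominator (no
#' predictions, or no gold) scores 1 by convention and is flagged.
#'
#' @param tp,fp,fn Non-negative integer counts.
#'
#' @return Object of class `eval_report`: a list with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f_score`, `accuracy` and a logical
#'   `degenerate` flag.
#' @export
#' @examples
#' compute_metrics(2, 1, 1)
compute_metrics <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  degenerate <- (tp + fp + fn) == 0
  precision <- if ((tp + fp) == 0) 1 else tp / (tp + fp)
  recall <- if ((tp + fn) == 0) 1 else tp / (tp + fn)
  f_score <- if ((precision + recall) == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  accuracy <- if (degenerate) 1 else tp / (tp + fp + fn)
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 precision = precision, recall = recall, f_score = f_score,
                 accuracy = accuracy, degenerate = degenerate),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 2, ...) {
  cat(sprintf("Span evaluation: tp=%d fp=%d fn=%d%s\n", x$tp, x$fp, x$fn,
              if (x$degenerate) " (degenerate: no spans)" else ""))
  cat(sprintf("  precision %.*f  recall %.*f  F %.*f  accuracy %.*f\n",
              digits, x$precision, digits, x$recall,
              digits, x$f_score, digits, x$accuracy))
  invisible(x)
}

#' Score a predicted span set against gold annotations, per corpus
#'
#' Pools exact-match counts over documents (micro-averaging) and optionally
#' reports a per-stratum breakdown.
#'
#' @param predicted Data frame of spans with `doc_id`, `start`, `end` (as
#'   produced by [extract_corpus()]).
#' @param gold Data frame of gold spans with `doc_id`, `start`, `end`.
#' @param doc_ids Character vector of all document ids in the corpus;
#'   defaults to ids present in either input. Documents with no spans in
#'   either set contribute nothing to the counts.
#' @param strata Optional named character vector mapping `doc_id` to a
#'   stratum label for the per-category breakdown.
#'
#' @return An `eval_report`; when `strata` is given, a `by_stratum` element
#'   holds one report per stratum.
#' @export
evaluate_extraction <- function(predicted, gold,
                                doc_ids = union(unique(predicted$doc_id),
                                                unique(gold$doc_id)),
                                strata = NULL) {
  counts_for <- function(ids) {
    tot <- c(tp = 0L, fp = 0L, fn = 0L)
    for (id in ids) {
      p <- predicted[predicted$doc_id == id, , drop = FALSE]
      g <- gold[gold$doc_id == id, , drop = FALSE]
      p <- p[order(p$start), , drop = FALSE]
      g <- g[order(g$start), , drop = FALSE]
      tot <- tot + match_spans(p, g)
    }
    tot
  }
  tot <- counts_for(doc_ids)
  rep <- compute_metrics(tot["tp"], tot["fp"], tot["fn"])
  if (!is.null(strata)) {
    by <- split(names(strata), unname(strata))
    rep$by_stratum <- lapply(by, function(ids) {
      cnt <- counts_for(intersect(ids, doc_ids))
      compute_metrics(cnt["tp"], cnt["fp"], cnt["fn"])
    })
  }
  rep
}
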