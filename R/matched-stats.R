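# Matched-pair univariate statistics: paired t-tests on within-pair
# differences and the closed-form discordant-pair odds ratio, the
# single-binary-covariate special case of 1:1 conditional logistic
# regression.

#' Two-tailed paired t-test on case minus control values
#'
#' @param case_values,control_values Numeric vectors of equal length, paired
#'   by patient.
#' @param conf_level Confidence level for the interval (default 0.95).
#'
#' @return Object of class `paired_t_result`: `mean_difference` (case -
#'   control), `ci_low`, `ci_high`, `t_statistic`, `df`, `p_value`,
#'   `n_pairs`.
#' @export
#' @examples
#' paired_t_test(c(2, 5, 1, 4), c(1, 3, 2, 2))
paired_t_test <- function(case_values, control_values, conf_level = 0.95) {
  stopifnot(length(case_values) == length(control_values))
  d <- case_values - control_values
  if (length(d) < 2L) stop("paired t-test needs at least 2 pairs")
  if (stats::sd(d) == 0) {
    # identical vectors are a well-defined no-difference result; a constant
    # nonzero difference leaves the t statistic undefined
    if (all(d == 0)) {
      return(structure(list(mean_difference = 0, ci_low = 0, ci_high = 0,
                            t_statistic = 0, df = length(d) - 1L, p_value = 1,
                            n_pairs = length(d), conf_level = conf_level),
                       class = "paired_t_result"))
    }
    stop("degenerate input: within-pair differences have zero variance")
  }
  tt <- stats::t.test(case_values, control_values, paired = TRUE,
                      conf.level = conf_level)
  structure(list(mean_difference = unname(tt$estimate),
                 ci_low = tt$conf.int[1L], ci_high = tt$conf.int[2L],
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p_value = tt$p.value,
                 n_pairs = length(d), conf_level = conf_level),
            class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, digits = 3, ...) {
  cat(sprintf("Paired t-test (n = %d pairs)\n", x$n_pairs))
  cat(sprintf("  mean difference %.*f (%.0f%% CI %.*f to %.*f)\n",
              digits, x$mean_difference, 100 * x$conf_level,
              digits, x$ci_low, digits, x$ci_high))
  cat(sprintf("  t = %.*f, df = %d, p = %.3g\n",
              digits, x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Tabulate matched pairs by binary exposure status
#'
#' @param case_exposed,control_exposed Logical (or 0/1) vectors, one element
#'   per pair.
#'
#' @return Object of class `discordant_table` with counts `n11` (exposed in
#'   both windows), `n10` (case only), `n01` (control only), `n00` (neither)
#'   and `n_pairs`.
#' @export
discordant_table <- function(case_exposed, control_exposed) {
  stopifnot(length(case_exposed) == length(control_exposed))
  ca <- as.logical(case_exposed)
  co <- as.logical(control_exposed)
  stopifnot(!anyNA(ca), !anyNA(co))
  structure(list(n11 = sum(ca & co), n10 = sum(ca & !co),
                 n01 = sum(!ca & co), n00 = sum(!ca & !co),
                 n_pairs = length(ca)),
            class = "discordant_table")
}

#' @export
print.discordant_table <- function(x, ...) {
  cat(sprintf("Matched-pair exposure table (%d pairs)\n", x$n_pairs))
  cat(sprintf("  both exposed %d | case only %d | control only %d | neither %d\n",
              x$n11, x$n10, x$n01, x$n00))
  invisible(x)
}

#' Discordant-pair odds ratio with Wald confidence interval
#'
#' Closed form for the single-binary-covariate 1:1 conditional logistic
#' model: OR = n10/n01, SE(log OR) = sqrt(1/n10 + 1/n01), CI =
#' exp(log OR +/- 1.96 SE). Only discordant pairs carry information.
#'
#' @param table A [discordant_table()], or a named list/vector with `n10` and
#'   `n01`.
#'
#' @return List with `or`, `log_or`, `se_log_or`, `ci_low`, `ci_high`,
#'   `p_value` (two-sided Wald), `n10`, `n01`.
#' @export
#' @examples
#' discordant_or(list(n10 = 294, n01 = 252))
discordant_or <- function(table) {
  n10 <- as.numeric(table[["n10"]])
  n01 <- as.numeric(table[["n01"]])
  if (is.na(n10) || is.na(n01) || n10 <= 0 || n01 <= 0) {
    stop("no information: both discordant counts (n10, n01) must be positive")
  }
  log_or <- log(n10 / n01)
  se <- sqrt(1 / n10 + 1 / n01)
  z <- log_or / se
  list(or = n10 / n01, log_or = log_or, se_log_or = se,
       ci_low = exp(log_or - 1.96 * se), ci_high = exp(log_or + 1.96 * se),
       p_value = 2 * stats::pnorm(-abs(z)), n10 = n10, n01 = n01)
}

#' Reconstruct pair-level binary exposures from marginal counts
#'
#' Expands cohort-level counts (total pairs, pairs exposed in the case
#' window, pairs exposed in the control window, pairs exposed in both) into
#' an explicit pair table of binary exposure indicators, suitable for
#' [clr_fit()]. The discordant counts are `n10 = n_case - n_both` and
#' `n01 = n_control - n_both`.
#'
#' @param n_pairs Total number of matched pairs.
#' @param n_case_exposed Pairs with the exposure present in the case window.
#' @param n_control_exposed Pairs with the exposure present in the control
#'   window.
#' @param n_both_exposed Pairs with the exposure present in both windows.
#'
#' @return Data frame with columns `case_any_quote` and `control_any_quote`
#'   (0/1), one row per pair.
#' @export
#' @examples
#' pairs <- reconstruct_pair_exposures(1503, 919, 877, 625)
#' discordant_table(pairs$case_any_quote, pairs$control_any_quote)
reconstruct_pair_exposures <- function(n_pairs, n_case_exposed,
                                       n_control_exposed, n_both_exposed) {
  n11 <- n_both_exposed
  n10 <- n_case_exposed - n_both_exposed
  n01 <- n_control_exposed - n_both_exposed
  n00 <- n_pairs - n11 - n10 - n01
  stopifnot(n11 >= 0, n10 >= 0, n01 >= 0, n00 >= 0)
  data.frame(
    case_any_quote = rep(c(1L, 1L, 0L, 0L), times = c(n11, n10, n01, n00)),
    control_any_quote = rep(c(1L, 0L, 1L, 0L), times = c(n11, n10, n01, n00))
  )
}
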