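# 1:1 matched-pair conditional logistic regression.
#
# The conditional likelihood for pair i with covariate vectors x_case and
# x_control is exp(b'x_case) / (exp(b'x_case) + exp(b'x_control)), i.e. a
# logistic model on within-pair differences d_i = x_case - x_control with no
# intercept and outcome fixed at 1. It is maximised by Newton-Raphson with
# the analytic score and observed information; pairs whose differences are
# all zero carry no information and are excluded from the likelihood.

.clr_newton <- function(d, tol_score = 1e-8, tol_step = 1e-10, max_iter = 50L,
                        beta_cap = 15) {
  p <- ncol(d)
  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(d %*% beta)
    pr <- stats::plogis(eta)
    score <- drop(crossprod(d, 1 - pr))
    w <- pr * (1 - pr)
    info <- crossprod(d * sqrt(w))          # observed information, p x p
    if (max(abs(score)) < tol_score) { converged <- TRUE; break }
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) {
      stop("complete separation (singular information matrix); ",
           "no finite estimate exists", call. = FALSE)
    }
    beta <- beta + step
    if (any(abs(beta) > beta_cap)) {
      stop("complete separation (coefficients diverging); ",
           "no finite estimate exists", call. = FALSE)
    }
    if (max(abs(step)) < tol_step) {
      eta <- drop(d %*% beta)
      score <- drop(crossprod(d, 1 - stats::plogis(eta)))
      converged <- max(abs(score)) < 1e-4
      break
    }
  }
  eta <- drop(d %*% beta)
  pr <- stats::plogis(eta)
  score <- drop(crossprod(d, 1 - pr))
  info <- crossprod(d * sqrt(pr * (1 - pr)))
  if (!converged) {
    stop(sprintf(paste0("conditional likelihood did not converge after %d ",
                        "iterations (last beta: %s; max |score| = %.3g)"),
                 iter, paste(signif(beta, 4), collapse = ", "),
                 max(abs(score))), call. = FALSE)
  }
  vcov <- solve(info)
  list(beta = beta, vcov = vcov, score = score,
       loglik = sum(stats::plogis(eta, log.p = TRUE)), iterations = iter)
}

#' Conditional logistic regression for 1:1 matched pairs
#'
#' Fits the pair-conditional likelihood by Newton-Raphson, starting at zero,
#' with Wald standard errors from the observed information at the optimum.
#' For a single binary exposure the estimate equals the discordant-pair
#' closed form `log(n10/n01)` (see [discordant_or()]).
#'
#' @param x For the data-frame method, a matched-pair table as produced by
#'   [build_matched_pairs()] (columns `case_<v>` and `control_<v>`); for the
#'   matrix method, the n-by-p matrix of within-pair differences (case minus
#'   control), one column per covariate.
#' @param ... Passed between methods.
#'
#' @return Object of class `clr_fit` with elements `coefficients`,
#'   `standard_errors`, `odds_ratios`, `ci_low`, `ci_high` (95% Wald, OR
#'   scale), `p_values`, `log_likelihood`, `vcov`, `n_pairs`,
#'   `n_informative_pairs`, `converged`, `iterations`.
#' @export
#' @examples
#' pairs <- reconstruct_pair_exposures(1503, 919, 877, 625)
#' fit <- clr_fit(pairs, exposure = "binary")
#' summary(fit)
clr_fit <- function(x, ...) UseMethod("clr_fit")

#' @rdname clr_fit
#' @param exposure `"binary"` (the `any_quote` indicator), `"per_token"`
#'   (`quotes_per_token`), or the bare name of any summary variable present
#'   as `case_<name>` / `control_<name>` columns.
#' @param covariates Character vector of additional summary variable names to
#'   adjust for (e.g. `c("face_to_face", "dna", "bed_days")`).
#' @export
clr_fit.data.frame <- function(x, exposure = c("binary", "per_token"),
                               covariates = character(), ...) {
  if (length(exposure) > 1L || exposure %in% c("binary", "per_token")) {
    exposure <- match.arg(exposure)
    exposure <- switch(exposure, binary = "any_quote",
                       per_token = "quotes_per_token")
  }
  vars <- c(exposure, covariates)
  need <- c(paste0("case_", vars), paste0("control_", vars))
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    stop("pair table lacks columns: ", paste(missing, collapse = ", "))
  }
  d <- as.matrix(x[, paste0("case_", vars), drop = FALSE]) -
    as.matrix(x[, paste0("control_", vars), drop = FALSE])
  colnames(d) <- vars
  clr_fit(d, ...)
}

#' @rdname clr_fit
#' @param tol_score Convergence threshold on the maximum absolute score.
#' @param max_iter Newton-Raphson iteration cap.
#' @export
clr_fit.matrix <- function(x, tol_score = 1e-8, max_iter = 50L, ...) {
  d <- x
  storage.mode(d) <- "double"
  if (is.null(colnames(d))) colnames(d) <- paste0("x", seq_len(ncol(d)))
  if (anyNA(d)) stop("difference matrix contains missing values")
  informative <- rowSums(d != 0) > 0L
  n_inf <- sum(informative)
  if (n_inf == 0L) {
    stop("no information: every pair has zero within-pair difference")
  }
  dd <- d[informative, , drop = FALSE]
  scale <- apply(abs(dd), 2L, max)
  if (any(scale == 0)) {
    stop("no within-pair variation in covariate(s): ",
         paste(colnames(d)[scale == 0], collapse = ", "))
  }
  # fit on unit-scaled columns so the divergence guard is scale free
  fit <- .clr_newton(sweep(dd, 2L, scale, "/"),
                     tol_score = tol_score, max_iter = max_iter)
  fit$beta <- fit$beta / scale
  fit$vcov <- fit$vcov / tcrossprod(scale)
  fit$score <- fit$score * scale
  se <- sqrt(diag(fit$vcov))
  beta <- stats::setNames(fit$beta, colnames(d))
  structure(list(coefficients = beta,
                 standard_errors = stats::setNames(se, colnames(d)),
                 odds_ratios = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 p_values = 2 * stats::pnorm(-abs(beta / se)),
                 log_likelihood = fit$loglik,
                 vcov = structure(fit$vcov,
                                  dimnames = list(colnames(d), colnames(d))),
                 score = fit$score,
                 n_pairs = nrow(d), n_informative_pairs = n_inf,
                 converged = TRUE, iterations = fit$iterations),
            class = "clr_fit")
}

#' @export
print.clr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("1:1 conditional logistic regression (%d pairs, %d informative)\n",
              x$n_pairs, x$n_informative_pairs))
  print(round(rbind(coef = x$coefficients, `exp(coef)` = x$odds_ratios,
                    se = x$standard_errors), digits))
  invisible(x)
}

#' @export
summary.clr_fit <- function(object, digits = 3, ...) {
  tab <- data.frame(coef = object$coefficients,
                    se = object$standard_errors,
                    OR = object$odds_ratios,
                    ci_low = object$ci_low,
                    ci_high = object$ci_high,
                    p_value = object$p_values)
  structure(list(table = tab, n_pairs = object$n_pairs,
                 n_informative_pairs = object$n_informative_pairs,
                 log_likelihood = object$log_likelihood,
                 iterations = object$iterations, digits = digits),
            class = "summary.clr_fit")
}

#' @export
print.summary.clr_fit <- function(x, ...) {
  cat(sprintf("1:1 conditional logistic regression\n"))
  cat(sprintf("  pairs: %d (%d informative); log-likelihood %.4f; %d iterations\n",
              x$n_pairs, x$n_informative_pairs, x$log_likelihood, x$iterations))
  tab <- x$table
  tab$p_value <- signif(tab$p_value, 3)
  tab[c("coef", "se", "OR", "ci_low", "ci_high")] <-
    round(tab[c("coef", "se", "OR", "ci_low", "ci_high")], x$digits)
  print(tab)
  invisible(x)
}

#' @export
coef.clr_fit <- function(object, ...) object$coefficients

#' @export
vcov.clr_fit <- function(object, ...) object$vcov

#' @export
logLik.clr_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients),
            nobs = object$n_informative_pairs, class = "logLik")
}

#' @export
confint.clr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm((1 + level) / 2)
  beta <- object$coefficients
  se <- object$standard_errors
  out <- cbind(beta - z * se, beta + z * se)
  colnames(out) <- paste(format(100 * c((1 - level) / 2, (1 + level) / 2),
                                trim = TRUE), "%")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}
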