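test_that("paired t-test matches the textbook formula on a hand fixture", {
  res <- paired_t_test(c(2, 5, 1, 4), c(1, 3, 2, 2))
  dd <- c(1, 2, -1, 2)
  m <- mean(dd)                       # 1
  se <- sd(dd) / sqrt(4)              # sqrt(2)/2
  expect_equal(res$mean_difference, m)
  expect_equal(res$t_statistic, m / se)
  expect_equal(res$df, 3)
  expect_equal(res$p_value, 2 * pt(-abs(m / se), 3))
  expect_equal(res$ci_low, m - qt(0.975, 3) * se)
  expect_equal(res$ci_high, m + qt(0.975, 3) * se)
  expect_identical(res$n_pairs, 4L)
})

test_that("paired t-test handles degenerate inputs per convention", {
  same <- c(3, 1, 4, 1, 5)
  res <- paired_t_test(same, same)
  expect_equal(res$mean_difference, 0)
  expect_equal(res$t_statistic, 0)
  expect_equal(res$p_value, 1)
  # constant nonzero differences leave t undefined
  expect_error(paired_t_test(c(3, 4, 5), c(1, 2, 3)), "zero variance")
  expect_error(paired_t_test(1, 2), "at least 2")
})

test_that("discordant-pair odds ratio follows the closed form", {
  tab <- discordant_table(case_exposed = c(1, 1, 1, 0, 0),
                          control_exposed = c(1, 0, 0, 1, 0))
  expect_identical(c(tab$n11, tab$n10, tab$n01, tab$n00), c(1L, 2L, 1L, 1L))
  expect_identical(tab$n11 + tab$n10 + tab$n01 + tab$n00, tab$n_pairs)

  expect_equal(discordant_or(list(n10 = 7, n01 = 7))$or, 1)
  expect_equal(discordant_or(list(n10 = 2, n01 = 1))$or, 2)
  res <- discordant_or(list(n10 = 294, n01 = 252))
  expect_equal(res$se_log_or, sqrt(1 / 294 + 1 / 252))
  expect_equal(round(res$or, 2), 1.17)
  expect_error(discordant_or(list(n10 = 0, n01 = 3)), "no information")
})

test_that("marginal counts reconstruct the pair-level exposure table", {
  pairs <- reconstruct_pair_exposures(1503, 919, 877, 625)
  expect_identical(nrow(pairs), 1503L)
  expect_identical(sum(pairs$case_any_quote), 919L)
  expect_identical(sum(pairs$control_any_quote), 877L)
  tab <- discordant_table(pairs$case_any_quote, pairs$control_any_quote)
  expect_identical(c(tab$n11, tab$n10, tab$n01, tab$n00),
                   c(625L, 294L, 252L, 332L))
})

test_that("single-binary-covariate fit equals the discordant closed form", {
  set.seed(701)
  for (k in 1:25) {
    n10 <- sample(5:200, 1); n01 <- sample(5:200, 1)
    n11 <- sample(0:100, 1); n00 <- sample(0:100, 1)
    d <- matrix(rep(c(1, -1, 0), times = c(n10, n01, n11 + n00)), ncol = 1)
    fit <- clr_fit(d)
    ref <- discordant_or(list(n10 = n10, n01 = n01))
    expect_equal(unname(coef(fit)), ref$log_or, tolerance = 1e-9)
    expect_equal(unname(fit$standard_errors), ref$se_log_or, tolerance = 1e-9)
    expect_identical(fit$n_informative_pairs, as.integer(n10 + n01))
  }
})

test_that("the optimum beats a dense grid of the reference log-likelihood", {
  set.seed(702)
  d <- matrix(sample(-2:2, 20, replace = TRUE), ncol = 1)
  if (all(d == 0)) d[1] <- 1
  fit <- clr_fit(d)
  grid <- seq(-5, 5, by = 0.001)
  inf <- d[d != 0, , drop = FALSE]
  ll_grid <- vapply(grid, ref_clr_loglik, numeric(1), d = inf)
  expect_gte(fit$log_likelihood, max(ll_grid))
  expect_equal(unname(coef(fit)), grid[which.max(ll_grid)], tolerance = 2e-3)
})

test_that("swapping case and control labels negates the coefficients", {
  set.seed(703)
  d <- cbind(x = sample(-1:1, 60, TRUE), z = sample(-2:2, 60, TRUE))
  fit <- clr_fit(d)
  swapped <- clr_fit(-d)
  expect_equal(coef(swapped), -coef(fit), tolerance = 1e-8)
  expect_equal(swapped$standard_errors, fit$standard_errors, tolerance = 1e-8)
})

test_that("the score vanishes at the reported optimum", {
  set.seed(704)
  d <- cbind(sample(-1:1, 100, TRUE), rpois(100, 1) - rpois(100, 1))
  fit <- clr_fit(d)
  inf <- d[rowSums(d != 0) > 0, ]
  eta <- drop(inf %*% coef(fit))
  score <- drop(crossprod(inf, 1 - plogis(eta)))
  expect_lt(max(abs(score)), 1e-6)
})

test_that("fit agrees with an established conditional-likelihood maximiser", {
  skip_if_not_installed("survival")
  withr::local_package("survival")
  set.seed(705)
  n <- 300
  pairs <- data.frame(
    case_any_quote = rbinom(n, 1, 0.6), control_any_quote = rbinom(n, 1, 0.5),
    case_face_to_face = rpois(n, 3), control_face_to_face = rpois(n, 2.5),
    case_bed_days = rpois(n, 2), control_bed_days = rpois(n, 2))
  fit <- clr_fit(pairs, exposure = "binary",
                 covariates = c("face_to_face", "bed_days"))
  long <- data.frame(
    y = rep(c(1, 0), n),
    any_quote = as.vector(rbind(pairs$case_any_quote, pairs$control_any_quote)),
    face_to_face = as.vector(rbind(pairs$case_face_to_face,
                                   pairs$control_face_to_face)),
    bed_days = as.vector(rbind(pairs$case_bed_days, pairs$control_bed_days)),
    pair = rep(seq_len(n), each = 2))
  cl <- survival::clogit(y ~ any_quote + face_to_face + bed_days +
                           survival::strata(pair), data = long)
  expect_equal(unname(coef(fit)), unname(coef(cl)), tolerance = 1e-6)
  expect_equal(unname(fit$standard_errors),
               unname(sqrt(diag(vcov(cl)))), tolerance = 1e-6)
})

test_that("degenerate and separated data are rejected with diagnostics", {
  expect_error(clr_fit(matrix(0, 10, 1)), "no information")
  expect_error(clr_fit(matrix(1, 20, 1)), "separation")
  pairs <- data.frame(case_any_quote = c(1, 1), control_any_quote = c(1, 1))
  expect_error(clr_fit(pairs, exposure = "binary"), "no information")
  expect_error(clr_fit(pairs, exposure = "nope"), "lacks columns")
})

test_that("confidence intervals and methods are mutually consistent", {
  pairs <- reconstruct_pair_exposures(200, 90, 70, 40)
  fit <- clr_fit(pairs, exposure = "binary")
  expect_equal(unname(fit$odds_ratios), exp(unname(coef(fit))))
  expect_equal(unname(fit$ci_low),
               exp(unname(coef(fit)) - 1.96 * unname(fit$standard_errors)))
  expect_equal(unname(fit$ci_high),
               exp(unname(coef(fit)) + 1.96 * unname(fit$standard_errors)))
  expect_true(fit$ci_low <= fit$odds_ratios & fit$odds_ratios <= fit$ci_high)
  ci <- confint(fit, level = 0.95)
  expect_equal(unname(ci[1, 1]),
               unname(coef(fit) - qnorm(0.975) * fit$standard_errors))
  expect_s3_class(summary(fit), "summary.clr_fit")
  expect_equal(attr(logLik(fit), "df"), 1)
  expect_output(print(fit), "conditional logistic")
})
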