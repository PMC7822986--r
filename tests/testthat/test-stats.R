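# Within-/between-subject correlation machinery and Fisher CIs.

toy_table <- function() {
  # 2 subjects x 3 electrodes, hand-checkable
  data.frame(subject = rep(c("A", "B"), each = 3),
             x = c(1, 2, 4, 10, 11, 15),
             y = c(2, 1, 6, 8, 9, 12))
}

test_that("pooled centring removes subject offsets exactly", {
  d <- data.frame(subject = rep(c("A", "B", "C"), each = 4),
                  x = rep(1:4, 3) + rep(c(0, 50, -30), each = 4),
                  y = rep(c(2, 4, 6, 8), 3) + rep(c(7, -20, 100), each = 4))
  r <- within_subject_correlation(d, "x", "y")
  expect_equal(r$r, 1)
  expect_identical(r$df, 12L - 3L - 1L)
  expect_identical(r$df_between, 2L)

  # per-subject-constant y carries no within-subject signal
  d$y <- rep(c(3, 9, 1), each = 4)
  expect_equal(within_subject_correlation(d, "x", "y")$r, 0)
})

test_that("within-subject r matches the brute-force hand computation", {
  d <- toy_table()
  # centre by hand and apply the product-moment formula directly
  cx <- d$x - ave(d$x, d$subject)
  cy <- d$y - ave(d$y, d$subject)
  r_hand <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  res <- within_subject_correlation(d, "x", "y")
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_identical(res$n_subjects, 2L)
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(res$p, 2 * pt(-abs(t_hand), 3), tolerance = 1e-12)
})

test_that("pooled-centred Pearson equals the random-subject ANCOVA", {
  # general-linear-model oracle: y ~ x + subject, partial r from the
  # t statistic of the covariate
  set.seed(14)
  for (i in 1:5) {
    d <- data.frame(subject = rep(letters[1:4], each = 5),
                    x = rnorm(20) + rep(rnorm(4, sd = 3), each = 5),
                    y = rnorm(20) + rep(rnorm(4, sd = 3), each = 5))
    fit <- lm(y ~ x + factor(subject), data = d)
    tv <- summary(fit)$coefficients["x", "t value"]
    df <- fit$df.residual
    r_oracle <- sign(tv) * sqrt(tv^2 / (tv^2 + df))
    p_oracle <- summary(fit)$coefficients["x", "Pr(>|t|)"]
    res <- within_subject_correlation(d, "x", "y")
    expect_equal(res$r, r_oracle, tolerance = 1e-10)
    expect_equal(res$p, p_oracle, tolerance = 1e-10)
    expect_identical(res$df, df)
  }
})

test_that("within-subject r is invariant to subject-specific offsets", {
  set.seed(15)
  d <- data.frame(subject = rep(1:5, each = 6), x = rnorm(30),
                  y = rnorm(30))
  r0 <- within_subject_correlation(d, "x", "y")$r
  d$x <- d$x + rep(runif(5, -100, 100), each = 6)
  d$y <- d$y + rep(runif(5, -100, 100), each = 6)
  expect_lt(abs(within_subject_correlation(d, "x", "y")$r - r0), 1e-12)
})

test_that("subjects with a single usable electrode are dropped", {
  d <- toy_table()
  d <- rbind(d, data.frame(subject = "C", x = 1, y = 1))
  expect_warning(res <- within_subject_correlation(d, "x", "y"), "single")
  expect_identical(res$n_subjects, 2L)
})

test_that("Fisher r-to-z interval matches the arithmetic chain", {
  expect_equal(fisher_ci_across_subjects(c(0, 0, 0, 0))$mean_r, 0)
  sym <- fisher_ci_across_subjects(c(-0.3, 0, 0.3))
  expect_equal(sym$mean_r, 0, tolerance = 1e-12)

  r <- c(0.2, 0.4, 0.6, 0.8)
  # independent spreadsheet-style computation
  z <- 0.5 * log((1 + r) / (1 - r))
  se <- sd(z) / 2
  lo <- tanh(mean(z) - 1.96 * se)
  hi <- tanh(mean(z) + 1.96 * se)
  got <- fisher_ci_across_subjects(r)
  expect_equal(got$mean_r, tanh(mean(z)), tolerance = 1e-12)
  expect_equal(got$halfwidth, (hi - lo) / 2, tolerance = 1e-12)
  expect_equal(got$lower, lo)
  expect_equal(got$upper, hi)

  expect_warning(cl <- fisher_ci_across_subjects(c(1, 0.5, 0.2)),
                 "clamped")
  expect_lt(cl$mean_r, 1)
  expect_error(fisher_ci_across_subjects(c(0.1, 0.2)), ">= 3")
  # fixed-variance option
  fx <- fisher_ci_across_subjects(r, variance = "fixed", m = 7)
  expect_equal(fx$halfwidth,
               (tanh(mean(z) + 1.96 / sqrt(4 * 4)) -
                  tanh(mean(z) - 1.96 / sqrt(4 * 4))) / 2)
  expect_error(fisher_ci_across_subjects(r, variance = "fixed"), "`m`")
})

test_that("between-subject means correlation", {
  d <- data.frame(subject = rep(1:4, each = 3),
                  x = rep(c(1, 2, 3, 4), each = 3) + rep(c(-1, 0, 1), 4),
                  y = rep(c(2, 4, 6, 8), each = 3) + rep(c(1, 0, -1), 4))
  res <- between_subject_means_correlation(d, "x", "y")
  expect_equal(res$r, 1)
  expect_identical(res$df, 2L)
  # hand Pearson on a non-degenerate 4-subject toy
  d$y <- d$x^2 + rep(c(0, 5, -5, 2), each = 3)
  mx <- tapply(d$x, d$subject, mean)
  my <- tapply(d$y, d$subject, mean)
  r_hand <- sum((mx - mean(mx)) * (my - mean(my))) /
    sqrt(sum((mx - mean(mx))^2) * sum((my - mean(my))^2))
  expect_equal(between_subject_means_correlation(d, "x", "y")$r, r_hand)
  expect_error(between_subject_means_correlation(
    data.frame(subject = 1, x = 1, y = 1)), ">= 3")
})

test_that("plain Pearson wrapper and per-subject correlations", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(pearson_cor(x, x)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  y <- c(2, 1, 4, 3, 6)
  r_hand <- sum((x - 3) * (y - mean(y))) /
    sqrt(sum((x - 3)^2) * sum((y - mean(y))^2))
  res <- pearson_cor(x, y)
  expect_equal(res$r, r_hand)
  expect_equal(res$df, 3)

  d <- toy_table()
  rs <- per_subject_correlations(d, "x", "y")
  expect_identical(names(rs), c("A", "B"))
  expect_equal(unname(rs["A"]), cor(d$x[1:3], d$y[1:3]))
})

test_that("programmed within-subject correlation is recovered", {
  # Monte-Carlo: bivariate data with rho = 0.5 inside each subject,
  # arbitrary subject offsets; 500 replicates
  rho <- 0.5
  set.seed(20)
  est <- vapply(1:500, function(i) {
    n_s <- 5; n_e <- 7
    x <- rnorm(n_s * n_e)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n_s * n_e)
    d <- data.frame(subject = rep(1:n_s, each = n_e),
                    x = x + rep(rnorm(n_s, sd = 4), each = n_e),
                    y = y + rep(rnorm(n_s, sd = 4), each = n_e))
    within_subject_correlation(d, "x", "y")$r
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - rho), 2 * se + 0.02)
})
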