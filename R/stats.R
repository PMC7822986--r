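# Within-subject (across-electrode) and between-subject correlation
# analyses with Fisher r-to-z confidence intervals.

.new_cor_result <- function(r, df, p, n_subjects, method,
                            ci_halfwidth = NA_real_, n = NA_integer_) {
  structure(list(r = r, df = df, p = p, n_subjects = n_subjects,
                 method = method, ci_halfwidth = ci_halfwidth, n = n),
            class = "cor_result")
}

#' @export
print.cor_result <- function(x, ...) {
  cat(sprintf("%s correlation: R(%d) = %.3f, p = %.4g", x$method, x$df,
              x$r, x$p))
  if (!is.na(x$ci_halfwidth))
    cat(sprintf(" [95%% CI halfwidth %.3f]", x$ci_halfwidth))
  cat(sprintf("  (n_subjects = %d)\n", x$n_subjects))
  invisible(x)
}

.pearson_t_p <- function(r, df) {
  if (df <= 0 || abs(r) >= 1) return(if (abs(r) >= 1) 0 else NA_real_)
  t <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(t), df)
}

#' Within-subject correlation across the electrode array
#'
#' Random-subject ANCOVA correlation between two measures observed on
#' several electrodes per subject: each subject's mean is subtracted from
#' both measures and a Pearson correlation is computed on the pooled
#' centred values. This is mathematically equivalent to an ANCOVA with one
#' measure as dependent variable, the other as covariate and subject as a
#' random factor. The p-value uses the pooled-centring degrees of freedom
#' `N - n_subjects - 1`; the per-subject convention `n_subjects - 1` is
#' also reported (as `df_between`) since published reports differ in which
#' they print.
#'
#' @param table Data frame with columns `subject`, and the two measure
#'   columns named by `x` and `y`. Rows with a missing value in either
#'   measure are dropped pairwise; subjects left with fewer than 2
#'   electrodes are dropped with a warning.
#' @param x,y Names of the measure columns.
#' @return A `cor_result` with elements `r`, `df` (pooled), `p`,
#'   `n_subjects` and attribute-like element `df_between`.
#' @export
within_subject_correlation <- function(table, x = "x", y = "y") {
  d <- data.frame(subject = table$subject, x = table[[x]], y = table[[y]])
  d <- d[stats::complete.cases(d), ]
  keep <- names(which(table(d$subject) >= 2))
  if (length(keep) < length(unique(d$subject)))
    warning("dropping subject(s) with a single usable electrode",
            call. = FALSE)
  d <- d[d$subject %in% keep, ]
  ns <- length(unique(d$subject))
  if (ns < 2 || nrow(d) < ns + 2)
    stop("need >= 2 subjects with >= 2 electrodes each", call. = FALSE)
  cx <- stats::ave(d$x, d$subject, FUN = function(v) v - mean(v))
  cy <- stats::ave(d$y, d$subject, FUN = function(v) v - mean(v))
  # a measure that is constant within every subject carries no
  # across-electrode information: define r = 0 rather than NA
  r <- if (stats::sd(cx) == 0 || stats::sd(cy) == 0) 0 else
    stats::cor(cx, cy)
  df <- nrow(d) - ns - 1L
  out <- .new_cor_result(r, df, .pearson_t_p(r, df), ns, "pooled-centred",
                         n = nrow(d))
  out$df_between <- ns - 1L
  out
}

#' Fisher r-to-z confidence interval over per-subject correlations
#'
#' Transforms each subject's correlation with `atanh`, forms a 95 % CI for
#' the mean on the z scale, and back-transforms the centre and endpoints
#' with `tanh`.
#'
#' @param per_subject_r Per-subject correlation coefficients (`|r| = 1` is
#'   clamped to `1 - 1e-6` with a warning; at least 3 values required).
#' @param variance `"sd"` (default): the z-scale standard error is
#'   `sd(z)/sqrt(n)`. `"fixed"`: the large-sample ECAP/electrode-count form
#'   `1/sqrt(m - 3)` per subject, pooled as
#'   `sqrt(mean(1/(m - 3)))/sqrt(n)`; requires `m`.
#' @param m Electrodes per subject (scalar or vector), only for
#'   `variance = "fixed"`.
#' @return List with `mean_r` (back-transformed centre), `halfwidth` (on
#'   the r scale), `lower` and `upper`.
#' @export
fisher_ci_across_subjects <- function(per_subject_r,
                                      variance = c("sd", "fixed"),
                                      m = NULL) {
  variance <- match.arg(variance)
  r <- per_subject_r
  if (length(r) < 3) stop("need >= 3 subjects", call. = FALSE)
  if (any(abs(r) >= 1)) {
    warning("|r| = 1 clamped to 1 - 1e-6", call. = FALSE)
    r <- pmin(pmax(r, -1 + 1e-6), 1 - 1e-6)
  }
  z <- atanh(r)
  n <- length(z)
  se <- if (variance == "sd") stats::sd(z) / sqrt(n) else {
    if (is.null(m)) stop("`m` required for variance = \"fixed\"",
                         call. = FALSE)
    m <- rep_len(m, n)
    if (any(m <= 3)) stop("`m` must exceed 3", call. = FALSE)
    sqrt(mean(1 / (m - 3))) / sqrt(n)
  }
  ctr <- mean(z)
  lo <- tanh(ctr - 1.96 * se)
  hi <- tanh(ctr + 1.96 * se)
  list(mean_r = tanh(ctr), halfwidth = (hi - lo) / 2, lower = lo,
       upper = hi)
}

#' Between-subject correlation of per-subject means
#'
#' Averages each measure across electrodes within subject and correlates
#' the per-subject means with a plain Pearson correlation
#' (`df = n_subjects - 2`). Subjects missing either measure entirely are
#' dropped.
#'
#' @inheritParams within_subject_correlation
#' @export
between_subject_means_correlation <- function(table, x = "x", y = "y") {
  d <- data.frame(subject = table$subject, x = table[[x]], y = table[[y]])
  mx <- tapply(d$x, d$subject, mean, na.rm = TRUE)
  my <- tapply(d$y, d$subject, mean, na.rm = TRUE)
  ok <- is.finite(mx) & is.finite(my)
  if (sum(ok) < 3)
    stop("need >= 3 subjects with both measures", call. = FALSE)
  r <- stats::cor(mx[ok], my[ok])
  df <- sum(ok) - 2L
  .new_cor_result(r, df, .pearson_t_p(r, df), sum(ok), "between-means",
                  n = sum(ok))
}

#' Plain Pearson correlation
#'
#' Product-moment correlation with a two-sided p-value, returned in the
#' same `cor_result` container as the study-level analyses.
#'
#' @param x,y Numeric vectors; pairs with missing values are dropped.
#' @export
pearson_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  ct <- stats::cor.test(x[ok], y[ok])
  .new_cor_result(unname(ct$estimate), unname(ct$parameter), ct$p.value,
                  NA_integer_, "plain", n = sum(ok))
}

#' Per-subject correlation coefficients
#'
#' Pearson correlation between two measures within each subject separately
#' (pairwise-complete), the inputs to [fisher_ci_across_subjects()].
#'
#' @inheritParams within_subject_correlation
#' @param min_electrodes Subjects with fewer complete pairs are skipped.
#' @return Named numeric vector of per-subject r.
#' @export
per_subject_correlations <- function(table, x = "x", y = "y",
                                     min_electrodes = 3) {
  d <- data.frame(subject = table$subject, x = table[[x]], y = table[[y]])
  d <- d[stats::complete.cases(d), ]
  out <- vapply(split(d, d$subject), function(s) {
    if (nrow(s) < min_electrodes || stats::sd(s$x) == 0 ||
        stats::sd(s$y) == 0) return(NA_real_)
    stats::cor(s$x, s$y)
  }, numeric(1))
  out[is.finite(out)]
}
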