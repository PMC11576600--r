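# Method-agreement statistics between an estimation channel and the
# weighing reference. Orientation everywhere is estimated - actual, so
# positive signed quantities mean overestimation.

check_paired <- function(estimated, actual, min_n = 1L) {
  if (!is.numeric(estimated) || !is.numeric(actual)) {
    stop_validation("paired series must be numeric")
  }
  if (length(estimated) != length(actual)) {
    stop_validation("paired series must have equal length")
  }
  if (length(estimated) < min_n) {
    stop_validation(sprintf("paired series needs at least %d observation(s)", min_n))
  }
  if (anyNA(estimated) || anyNA(actual) ||
      any(!is.finite(estimated)) || any(!is.finite(actual))) {
    stop_validation("paired series must be finite with no missing entries")
  }
  invisible(length(estimated))
}

#' Root-mean-square error between estimated and actual values
#'
#' `sqrt(mean((estimated - actual)^2))`. Squaring weights large errors
#' heavily, so a small RMSE indicates few gross disagreements.
#'
#' @param estimated,actual Equal-length numeric vectors aligned by dish
#'   instance or meal.
#' @return Non-negative scalar in the units of the inputs.
#' @export
rmse <- function(estimated, actual) {
  check_paired(estimated, actual)
  sqrt(mean((estimated - actual)^2))
}

#' Mean-reference coefficient of determination
#'
#' `1 - sum((estimated - actual)^2) / sum((actual - mean(actual))^2)`:
#' the error of the estimates relative to a reference model that always
#' predicts the mean of the actual values. Equals 1 for perfect agreement,
#' 0 for an estimator no better than the mean, and can be negative for a
#' worse one (negative values are reported as-is, never clipped). This is
#' not the squared Pearson correlation.
#'
#' @inheritParams rmse
#' @return Scalar `<= 1`.
#' @export
r_squared <- function(estimated, actual) {
  check_paired(estimated, actual, min_n = 2L)
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) {
    stop_validation("actual values are constant; R^2 denominator undefined",
                    class = "intakeval_degenerate_error")
  }
  1 - sum((estimated - actual)^2) / ss_tot
}

#' Signed mean error (bias)
#'
#' `mean(estimated - actual)`; positive values indicate overestimation of
#' intake, negative underestimation.
#'
#' @inheritParams rmse
#' @return Signed scalar.
#' @export
mean_error <- function(estimated, actual) {
  check_paired(estimated, actual)
  mean(estimated - actual)
}

#' Mean absolute error
#'
#' `mean(abs(estimated - actual))`.
#'
#' @inheritParams rmse
#' @return Non-negative scalar.
#' @export
mean_abs_error <- function(estimated, actual) {
  check_paired(estimated, actual)
  mean(abs(estimated - actual))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of midranks. The two-sided p-value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2`
#' degrees of freedom, the standard choice at the sample sizes of
#' method-comparison studies (an exact permutation p is not computed).
#'
#' @inheritParams rmse
#' @return List with elements `rho` and `p`.
#' @export
spearman_rho <- function(estimated, actual) {
  n <- check_paired(estimated, actual, min_n = 3L)
  rx <- rank(estimated)
  ry <- rank(actual)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop_validation("a constant series has no rank correlation",
                    class = "intakeval_degenerate_error")
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p)
}

#' Paired t test on estimated minus actual
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = estimated - actual` and a
#' two-sided p from the t distribution on `n - 1` degrees of freedom.
#' All-zero differences give `t = 0, p = 1` (no evidence of bias); nonzero
#' but identical differences have zero variance and are rejected.
#'
#' @inheritParams rmse
#' @return List with elements `t` and `p`.
#' @export
paired_t_test <- function(estimated, actual) {
  n <- check_paired(estimated, actual, min_n = 2L)
  d <- estimated - actual
  if (all(d == 0)) {
    return(list(t = 0, p = 1))
  }
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    stop_validation("differences are identical and nonzero; t is undefined",
                    class = "intakeval_degenerate_error")
  }
  tval <- mean(d) / (sd_d / sqrt(n))
  list(t = tval, p = 2 * stats::pt(abs(tval), df = n - 1, lower.tail = FALSE))
}

#' Friedman rank test across related method columns
#'
#' Ranks the `k` method values within each of the `n` blocks (midranks for
#' ties) and computes the tie-corrected Friedman chi-square
#' `12 * sum((R_j - n(k+1)/2)^2) / (n k (k+1) - sum(t^3 - t) / (k - 1))`
#' on `k - 1` degrees of freedom, where `R_j` are column rank sums and the
#' tie term sums over tie groups within blocks. Converted intake values are
#' heavily tied at 10, so the correction matters. When every block is a
#' complete tie the statistic is defined as 0 with p = 1.
#'
#' @param blocks Numeric matrix or data frame, one row per block (dish
#'   instance), one column per related method.
#' @return List with elements `chisq`, `df` and `p`.
#' @export
friedman_rank_test <- function(blocks) {
  blocks <- as.matrix(blocks)
  if (!is.numeric(blocks) || anyNA(blocks)) {
    stop_validation("blocks must be a complete numeric matrix")
  }
  n <- nrow(blocks)
  k <- ncol(blocks)
  if (n < 2 || k < 2) {
    stop_validation("Friedman test needs at least 2 blocks and 2 methods")
  }
  r <- t(apply(blocks, 1, rank))
  col_sums <- colSums(r)
  numer <- 12 * sum((col_sums - n * (k + 1) / 2)^2)
  tie_term <- sum(apply(r, 1, function(row) {
    tg <- table(row)
    sum(tg^3 - tg)
  }))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  if (denom <= 0) {
    # all blocks completely tied: no discriminating information
    return(list(chisq = 0, df = k - 1, p = 1))
  }
  chisq <- numer / denom
  list(chisq = chisq, df = k - 1,
       p = stats::pchisq(chisq, df = k - 1, lower.tail = FALSE))
}

#' Bland-Altman limits of agreement
#'
#' Differences are `estimated - actual`; the limits of agreement are the
#' mean difference plus/minus 1.96 times the sample (n-1) standard
#' deviation of the differences. For approximately normal differences about
#' 95% of individual disagreements fall inside the limits.
#'
#' @inheritParams rmse
#' @return List with elements `mean_diff`, `sd_diff`, `loa_lower`,
#'   `loa_upper`.
#' @export
bland_altman <- function(estimated, actual) {
  check_paired(estimated, actual, min_n = 2L)
  d <- estimated - actual
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s,
       loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s)
}

#' Ordinal 11x11 confusion matrix on the converted scale
#'
#' Cross-tabulates actual (rows) against estimated (columns) converted
#' values 0-10, and carries the mean absolute error of the same pairs.
#' Row/column labels are the scale values `"0"` to `"10"`.
#'
#' @inheritParams rmse
#' @return List of class `intake_confusion` with elements `counts` (11x11
#'   integer matrix), `n` and `mae`.
#' @export
confusion_matrix11 <- function(estimated, actual) {
  check_paired(estimated, actual)
  assert_converted(estimated, "estimated")
  assert_converted(actual, "actual")
  lv <- factor(as.integer(actual), levels = 0:10)
  le <- factor(as.integer(estimated), levels = 0:10)
  counts <- unclass(table(actual = lv, estimated = le))
  structure(
    list(counts = counts, n = length(estimated),
         mae = mean_abs_error(estimated, actual)),
    class = "intake_confusion"
  )
}

#' Full agreement summary between one estimation channel and the reference
#'
#' Bundles [rmse()], [r_squared()], [mean_error()], [mean_abs_error()],
#' [spearman_rho()], [paired_t_test()] and [bland_altman()] for one aligned
#' paired series.
#'
#' @inheritParams rmse
#' @return Named list with elements `n`, `rmse`, `r2`, `me`, `mae`, `rho`,
#'   `rho_p`, `t`, `t_p`, and `bland_altman`.
#' @export
agreement_summary <- function(estimated, actual) {
  sp <- spearman_rho(estimated, actual)
  tt <- paired_t_test(estimated, actual)
  list(
    n = length(estimated),
    rmse = rmse(estimated, actual),
    r2 = r_squared(estimated, actual),
    me = mean_error(estimated, actual),
    mae = mean_abs_error(estimated, actual),
    rho = sp$rho, rho_p = sp$p,
    t = tt$t, t_p = tt$p,
    bland_altman = bland_altman(estimated, actual)
  )
}
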