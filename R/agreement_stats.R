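# Method-agreement and study-design statistics.
#
# Differences are always reference - test (CT minus thermodilution).  This
# direction is fixed, not configurable: with an inflated bedside method the
# bias is then negative, and keeping one convention prevents silent sign
# flips between reports.

z_q <- function(p) stats::qnorm(p)

#' Bland-Altman agreement analysis
#'
#' Bias is the mean of the paired differences `reference - test`; limits of
#' agreement are `bias +/- 1.96 * SD` of the differences (sample SD, n-1).
#' The sampling uncertainty of each limit uses the classical approximation
#' `Var(LoA) ~ 3 sigma^2 / n`, giving a 95% CI half-width of
#' `1.96 * sd * sqrt(3/n)`.
#'
#' @param reference,test numeric vectors of equal length >= 2 (ml/kg).
#' @return an object of class `bland_altman_result`: `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, `loa_ci_halfwidth`, `n`.
#' @export
bland_altman <- function(reference, test) {
  if (length(reference) != length(test))
    lw_validation_error("reference and test must have equal length")
  if (anyNA(reference) || anyNA(test))
    lw_validation_error("paired series must not contain missing values")
  n <- length(reference)
  if (n < 2L) lw_validation_error("need at least 2 pairs (got %d)", n)
  d <- reference - test
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(
    bias = bias, sd_diff = sd_diff,
    loa_lower = bias - 1.96 * sd_diff,
    loa_upper = bias + 1.96 * sd_diff,
    loa_ci_halfwidth = 1.96 * sd_diff * sqrt(3 / n),
    n = n
  ), class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Bland-Altman (differences = reference - test, n = %d)\n",
    "  bias : %.2f ml/kg   SD of differences : %.2f ml/kg\n",
    "  limits of agreement : %.2f to %.2f ml/kg\n",
    "  LoA 95%% CI half-width : %.2f ml/kg\n"),
    x$n, x$bias, x$sd_diff, x$loa_lower, x$loa_upper, x$loa_ci_halfwidth))
  invisible(x)
}

#' Minimum n for a target limits-of-agreement precision
#'
#' Smallest integer n such that the 95% CI half-width of each limit of
#' agreement, `z * sd * sqrt(3/n)`, does not exceed the target.  Standard
#' normal quantiles are used throughout the design formulas (this is the
#' convention the printed design numbers assume).
#'
#' @param sd_diff SD of paired differences, ml/kg.
#' @param halfwidth_target desired CI half-width, ml/kg.
#' @param alpha two-sided type-I level for the CI (default 0.05).
#' @return integer sample size (>= 1).
#' @export
min_n_for_loa_precision <- function(sd_diff, halfwidth_target, alpha = 0.05) {
  if (sd_diff <= 0 || halfwidth_target <= 0 || alpha <= 0 || alpha >= 1)
    lw_validation_error("sd_diff and halfwidth_target must be > 0, 0 < alpha < 1")
  z <- z_q(1 - alpha / 2)
  max(1L, as.integer(ceiling(3 * (z * sd_diff / halfwidth_target)^2)))
}

#' Sample size for a paired mean-difference test
#'
#' Normal-approximation paired design:
#' `n = ceil((z_{1-alpha/2} + z_{power})^2 * sd^2 / delta^2)`.
#'
#' @param delta detectable mean difference, ml/kg; > 0.
#' @param sd_diff SD of paired differences, ml/kg.
#' @param alpha two-sided type-I level.
#' @param power target power.
#' @return integer sample size (>= 1).
#' @export
paired_n <- function(delta, sd_diff, alpha = 0.05, power = 0.80) {
  if (delta <= 0) lw_validation_error("delta must be > 0")
  if (sd_diff <= 0) lw_validation_error("sd_diff must be > 0")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    lw_validation_error("alpha and power must lie in (0, 1)")
  z <- z_q(1 - alpha / 2) + z_q(power)
  max(1L, as.integer(ceiling(z^2 * sd_diff^2 / delta^2)))
}

#' Detectable mean difference at fixed n
#'
#' Continuous-scale inverse of [paired_n()]:
#' `delta = (z_{1-alpha/2} + z_{power}) * sd / sqrt(n)`.
#'
#' @param n sample size, >= 2.
#' @param sd_diff SD of paired differences, ml/kg (>= 0).
#' @param alpha,power as in [paired_n()].
#' @return detectable difference, ml/kg.
#' @export
detectable_delta <- function(n, sd_diff, alpha = 0.05, power = 0.80) {
  if (n < 2) lw_validation_error("n must be >= 2")
  if (sd_diff < 0) lw_validation_error("sd_diff must be >= 0")
  (z_q(1 - alpha / 2) + z_q(power)) * sd_diff / sqrt(n)
}

#' Normality-gated paired comparison
#'
#' Shapiro-Wilk on the paired differences decides the branch: paired t-test
#' if `p >= normality_alpha`, Wilcoxon signed-rank otherwise (exact p for
#' n <= 25, normal approximation with continuity correction above).
#'
#' @param reference,test numeric vectors, equal length >= 3.
#' @param normality_alpha gate level for the Shapiro-Wilk test (default 0.05).
#' @return list with `test_name` (`"paired t-test"` or
#'   `"wilcoxon signed-rank"`), `statistic`, `p_value`, `shapiro_p`.
#' @export
paired_compare <- function(reference, test, normality_alpha = 0.05) {
  if (length(reference) != length(test))
    lw_validation_error("reference and test must have equal length")
  n <- length(reference)
  if (n < 3L) lw_validation_error("need at least 3 pairs for Shapiro-Wilk")
  d <- reference - test
  if (all(d == 0)) {
    warning("all paired differences are zero: degenerate comparison, p = 1")
    return(list(test_name = "degenerate", statistic = NA_real_,
                p_value = 1, shapiro_p = NA_real_))
  }
  sw <- stats::shapiro.test(d)
  if (sw$p.value >= normality_alpha) {
    tt <- stats::t.test(d)
    list(test_name = "paired t-test", statistic = unname(tt$statistic),
         p_value = tt$p.value, shapiro_p = sw$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(
      d, exact = n <= 25, correct = TRUE))
    list(test_name = "wilcoxon signed-rank", statistic = unname(wt$statistic),
         p_value = wt$p.value, shapiro_p = sw$p.value)
  }
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; two-sided p-value.
#'
#' @param reference,test numeric vectors, equal length >= 3, neither constant.
#' @return list with `rho` and `p_value`.
#' @export
spearman_corr <- function(reference, test) {
  if (length(reference) != length(test))
    lw_validation_error("reference and test must have equal length")
  if (length(reference) < 3L)
    lw_validation_error("need at least 3 pairs")
  if (stats::var(reference) == 0 || stats::var(test) == 0)
    lw_numeric_error("constant input: Spearman rho undefined")
  ct <- suppressWarnings(stats::cor.test(reference, test, method = "spearman",
                                         alternative = "two.sided"))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Normality-gated descriptive summary
#'
#' Mean and SD when the Shapiro-Wilk test does not reject normality at
#' `normality_alpha`, otherwise median with first and third quartiles
#' (linear-interpolation quartile rule, `stats::quantile` type 7).
#'
#' @param values numeric vector, length >= 3.
#' @param normality_alpha gate level (default 0.05).
#' @return list: either `{summary = "mean_sd", mean, sd}` or
#'   `{summary = "median_iqr", median, q1, q3}`.
#' @export
summarize_values <- function(values, normality_alpha = 0.05) {
  if (length(values) < 3L) lw_validation_error("need at least 3 values")
  if (stats::var(values) == 0)
    return(list(summary = "mean_sd", mean = mean(values), sd = 0))
  sw <- stats::shapiro.test(values)
  if (sw$p.value >= normality_alpha) {
    list(summary = "mean_sd", mean = mean(values), sd = stats::sd(values))
  } else {
    q <- unname(stats::quantile(values, c(.25, .5, .75), type = 7))
    list(summary = "median_iqr", median = q[2], q1 = q[1], q3 = q[3])
  }
}

#' Round half up to a number of decimals
#'
#' Display rule for reported precisions (base R `round` rounds half to even).
#'
#' @param x numeric.
#' @param digits decimals.
#' @return rounded value.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
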