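#' Relative growth rate and pooled-variance two-sample t-test
#'
#' Compares the replicate growth rates of an evolved strain with those of its
#' ancestor at one temperature. The relative growth rate is the ratio of the
#' group means; significance comes from the two-sample statistic
#' `t = (x1bar - x0bar) / (s_p * sqrt(1/n1 + 1/n0))`, where the pooled
#' standard deviation `s_p` is estimated from within-strain deviations across
#' *every* replicate group measured at that temperature (not just the pair
#' being compared), with `df = sum(n_i - 1)`. Pooling across the whole
#' temperature panel stabilizes the variance estimate when groups have only
#' three replicates. The test is two-sided; direction is imposed only at
#' classification time.
#'
#' @param evolved numeric vector of replicate `mu_max` values for the evolved
#'   strain (length >= 2).
#' @param ancestor numeric vector of replicate `mu_max` values for the
#'   ancestor (length >= 2).
#' @param pool list of numeric replicate vectors for every strain measured at
#'   this temperature; must contain at least the two compared groups.
#'   Defaults to just the compared pair, in which case the result is the
#'   classical equal-variance two-sample t-test.
#' @param strain_id,temperature metadata carried into the result.
#' @return object of class `relative_growth_result`: list with `ratio`,
#'   `x1_bar`, `x0_bar`, `n1`, `n0`, `s_p`, `df`, `t_stat`, `p_value`.
#' @export
relative_growth_test <- function(evolved, ancestor,
                                 pool = list(evolved, ancestor),
                                 strain_id = NA_character_,
                                 temperature = NA_real_) {
  if (length(evolved) < 2 || length(ancestor) < 2)
    stop_config("both groups need at least 2 replicates")
  ss <- vapply(pool, function(g) sum((g - mean(g))^2), 0)
  df <- sum(vapply(pool, length, 0L) - 1L)
  s_p <- sqrt(sum(ss) / df)
  if (s_p == 0) stop_config("pooled variance is zero")
  n1 <- length(evolved); n0 <- length(ancestor)
  x1 <- mean(evolved); x0 <- mean(ancestor)
  t_stat <- (x1 - x0) / (s_p * sqrt(1 / n1 + 1 / n0))
  structure(list(strain_id = strain_id, temperature = temperature,
                 ratio = x1 / x0, x1_bar = x1, x0_bar = x0,
                 n1 = n1, n0 = n0, s_p = s_p, df = df, t_stat = t_stat,
                 p_value = 2 * stats::pt(-abs(t_stat), df)),
            class = "relative_growth_result")
}

#' @export
print.relative_growth_result <- function(x, ...) {
  cat(sprintf("<relative_growth_result> %s @ %g C: ratio = %.3f, t = %.3f (df %d), p = %.3g\n",
              x$strain_id, x$temperature, x$ratio, x$t_stat, x$df, x$p_value))
  invisible(x)
}

#' Classify an evolved strain as generalist, specialist or not-significant
#'
#' A strain is a generalist if its relative growth rate increased
#' significantly (two-sided p below `alpha` *and* ratio above 1) at both 15
#' and 43 degrees C; a 15- or 43-degree specialist if it increased at exactly
#' one temperature; and not-significant otherwise. A significant *decrease*
#' never produces a specialist call for that temperature and does not veto
#' the call earned at the other temperature. An optional strict mode
#' additionally requires the ratio to reach 1.15 at 15 degrees and 1.30 at
#' 43 degrees.
#'
#' @param result_15,result_43 [relative_growth_test()] results for the same
#'   strain at 15 and 43 degrees C (either argument order is accepted; the
#'   temperatures recorded in the results decide).
#' @param alpha significance level.
#' @param strict apply the ratio gates 1.15 (15 C) and 1.30 (43 C).
#' @return object of class `strategy_call`: list with `strain_id`,
#'   `category` (one of `"generalist"`, `"specialist_15"`, `"specialist_43"`,
#'   `"not_significant"`) and the supporting per-temperature `(ratio, p)`.
#' @export
classify_strategy <- function(result_15, result_43, alpha = 0.05,
                              strict = FALSE) {
  stopifnot(inherits(result_15, "relative_growth_result"),
            inherits(result_43, "relative_growth_result"))
  if (!identical(result_15$strain_id, result_43$strain_id))
    stop_config("results belong to different strains (%s vs %s)",
                result_15$strain_id, result_43$strain_id)
  # accept the two temperatures in either order
  temps <- c(result_15$temperature, result_43$temperature)
  if (setequal(temps, c(15, 43)) && temps[1] == 43) {
    tmp <- result_15; result_15 <- result_43; result_43 <- tmp
  }
  up <- function(r, gate) {
    sig <- r$p_value < alpha && r$ratio > 1
    if (strict) sig <- sig && r$ratio >= gate
    sig
  }
  up15 <- up(result_15, 1.15)
  up43 <- up(result_43, 1.30)
  category <- if (up15 && up43) "generalist"
  else if (up15) "specialist_15"
  else if (up43) "specialist_43"
  else "not_significant"
  structure(list(strain_id = result_15$strain_id, category = category,
                 ratio_15 = result_15$ratio, p_15 = result_15$p_value,
                 ratio_43 = result_43$ratio, p_43 = result_43$p_value,
                 alpha = alpha),
            class = "strategy_call")
}

#' @export
print.strategy_call <- function(x, ...) {
  cat(sprintf("<strategy_call> %s: %s (15C ratio %.3f p %.3g; 43C ratio %.3f p %.3g)\n",
              x$strain_id, x$category, x$ratio_15, x$p_15, x$ratio_43, x$p_43))
  invisible(x)
}

#' F-test comparing relative-growth-rate variances of two groups
#'
#' Tests whether one group of relative growth rates is more variable than
#' another (e.g. strains evolved under periodic vs random regimes) with the
#' variance ratio `F = var(a) / var(b)` and a two-sided p-value from the F
#' distribution.
#'
#' @param group_a,group_b numeric vectors (each length >= 3).
#' @return list with `F`, `df1`, `df2`, `p_value`.
#' @export
variance_ratio_test <- function(group_a, group_b) {
  if (length(group_a) < 3 || length(group_b) < 3)
    stop_config("each group needs at least 3 values")
  vb <- stats::var(group_b)
  if (vb == 0) stop_config("denominator group has zero variance")
  f <- stats::var(group_a) / vb
  df1 <- length(group_a) - 1L
  df2 <- length(group_b) - 1L
  p <- 2 * min(stats::pf(f, df1, df2), stats::pf(f, df1, df2, lower.tail = FALSE))
  list(F = f, df1 = df1, df2 = df2, p_value = min(p, 1))
}

#' Fisher exact test on a 2x2 strategy-by-group contingency table
#'
#' Two-sided Fisher exact probability, summing every hypergeometric outcome
#' whose probability does not exceed the observed table's. Used for, e.g.,
#' generalist enrichment in periodic vs random regimes.
#'
#' @param counts 2x2 matrix (or coercible) of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_strategy_enrichment <- function(counts) {
  m <- as.matrix(counts)
  if (!all(dim(m) == c(2, 2))) stop_config("counts must form a 2x2 table")
  if (any(m < 0) || any(m != round(m)))
    stop_config("counts must be non-negative integers")
  stats::fisher.test(m)$p.value
}
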