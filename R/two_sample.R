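#' Two-sample summary statistics
#'
#' Means, sample variances, sizes and the pooled standard deviation
#' `s_p = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2))` of two groups -
#' the sufficient statistics for the pooled two-sample t-test.
#'
#' @param g1,g2 Numeric vectors, each of length >= 2.
#' @return Object of class `two_sample_summary` with fields `mean1`,
#'   `mean2`, `var1`, `var2`, `n1`, `n2`, `s_p`, `df`.
#' @export
two_sample_summary <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2L || n2 < 2L) stop("both groups need at least 2 observations")
  v1 <- stats::var(g1); v2 <- stats::var(g2)
  df <- n1 + n2 - 2
  structure(list(mean1 = mean(g1), mean2 = mean(g2),
                 var1 = v1, var2 = v2, n1 = n1, n2 = n2,
                 s_p = sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / df),
                 df = df),
            class = "two_sample_summary")
}

#' Pooled-variance two-sample t-test
#'
#' The classical equal-variance t statistic
#' `t = (mean1 - mean2) / (s_p * sqrt(1/n1 + 1/n2))` with
#' `df = n1 + n2 - 2` degrees of freedom and a two-sided p-value. If the
#' pooled variance is zero and the means differ, the statistic is infinite
#' and flagged.
#'
#' @param g1,g2 Numeric vectors (>= 2 observations each).
#' @return List with `statistic`, `df`, `p_value`, `s_p`, `mean_diff`,
#'   `degenerate` (`TRUE` when the pooled variance is zero).
#' @export
pooled_t_test <- function(g1, g2) {
  s <- two_sample_summary(g1, g2)
  diff <- s$mean1 - s$mean2
  degenerate <- s$s_p == 0
  if (degenerate) {
    t_stat <- if (diff == 0) 0 else sign(diff) * Inf
    p <- if (diff == 0) 1 else 0
  } else {
    t_stat <- diff / (s$s_p * sqrt(1 / s$n1 + 1 / s$n2))
    p <- 2 * stats::pt(-abs(t_stat), df = s$df)
  }
  list(statistic = t_stat, df = s$df, p_value = p, s_p = s$s_p,
       mean_diff = diff, degenerate = degenerate)
}

#' Welch (unequal-variance) two-sample t-test
#'
#' Thin wrapper over [stats::t.test()] with `var.equal = FALSE`, provided
#' alongside [pooled_t_test()] because morphology metrics are compared
#' assuming unequal variances while the qPCR quantification uses the pooled
#' formula.
#'
#' @param g1,g2 Numeric vectors.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(g1, g2) {
  tt <- stats::t.test(g1, g2, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' F-test for equality of two variances
#'
#' `F = larger variance / smaller variance`, with a two-sided p-value from
#' the F distribution; used to check whether two groups' standard
#' deviations differ before pooling them.
#'
#' @param g1,g2 Numeric vectors (>= 2 observations, positive variance).
#' @param alpha Significance level for the `equal_variance` verdict
#'   (default 0.05).
#' @return List with `statistic` (F >= 1), `df` (numerator, denominator),
#'   `p_value`, `equal_variance`.
#' @export
f_test_variances <- function(g1, g2, alpha = 0.05) {
  n1 <- length(g1); n2 <- length(g2)
  if (n1 < 2L || n2 < 2L) stop("both groups need at least 2 observations")
  v1 <- stats::var(g1); v2 <- stats::var(g2)
  if (v1 == 0 || v2 == 0) stop("zero variance: F statistic undefined")
  if (v1 >= v2) {
    f <- v1 / v2; df <- c(n1 - 1, n2 - 1)
  } else {
    f <- v2 / v1; df <- c(n2 - 1, n1 - 1)
  }
  p <- 2 * stats::pf(f, df[1], df[2], lower.tail = FALSE)
  p <- min(1, p)
  list(statistic = f, df = df, p_value = p, equal_variance = p >= alpha)
}
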