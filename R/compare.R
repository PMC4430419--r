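#' Pairwise per-metric condition comparisons
#'
#' For every metric and every non-control condition, compares that
#' condition's values against the control: both groups are first checked for
#' normality (Shapiro-Wilk at `alpha_normality`); if both pass, a two-sided
#' Welch two-sample t-test (unequal variances) is used, otherwise a
#' two-sided Wilcoxon rank-sum test. Groups with fewer than 3 observations
#' or zero variance cannot be assessed by Shapiro-Wilk and are routed to the
#' rank-sum branch. No multiple-testing correction is applied by default;
#' `p_adjust = "holm"` corrects across all comparisons.
#'
#' @param features Feature table with a `Condition` column and metric
#'   columns.
#' @param control Label of the reference condition.
#' @param alpha_normality Shapiro-Wilk significance level gating the
#'   parametric branch (default 0.05).
#' @param metrics Metric columns to compare (default [feature_metrics()]
#'   intersected with the table).
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return `data.frame` with columns `metric`, `condition`, `test`
#'   (`"t"` or `"wilcoxon"`), `statistic`, `p_value`, `normal_condition`,
#'   `normal_control`.
#' @export
compare_conditions <- function(features, control, alpha_normality = 0.05,
                               metrics = NULL,
                               p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot("Condition" %in% names(features))
  if (!control %in% features$Condition) {
    stop("control label '", control, "' not present")
  }
  if (is.null(metrics)) metrics <- intersect(feature_metrics(), names(features))
  conds <- setdiff(unique(features$Condition), control)
  out <- list()
  for (met in metrics) {
    g_ctrl <- features[[met]][features$Condition == control]
    g_ctrl <- g_ctrl[!is.na(g_ctrl)]
    for (cond in conds) {
      g <- features[[met]][features$Condition == cond]
      g <- g[!is.na(g)]
      if (length(g) < 2L || length(g_ctrl) < 2L) {
        stop("group size < 2 for metric ", met, ", condition ", cond)
      }
      n1 <- .is_normal(g, alpha_normality)
      n2 <- .is_normal(g_ctrl, alpha_normality)
      if (n1 && n2) {
        tt <- stats::t.test(g, g_ctrl, var.equal = FALSE)
        res <- data.frame(metric = met, condition = cond, test = "t",
                          statistic = unname(tt$statistic),
                          p_value = tt$p.value)
      } else {
        wt <- suppressWarnings(stats::wilcox.test(g, g_ctrl, exact = FALSE))
        res <- data.frame(metric = met, condition = cond, test = "wilcoxon",
                          statistic = unname(wt$statistic),
                          p_value = wt$p.value)
      }
      res$normal_condition <- n1
      res$normal_control <- n2
      out[[length(out) + 1L]] <- res
    }
  }
  out <- do.call(rbind, out)
  if (p_adjust == "holm") out$p_value <- stats::p.adjust(out$p_value, "holm")
  rownames(out) <- NULL
  out
}

.is_normal <- function(x, alpha) {
  if (length(x) < 3L || length(x) > 5000L || stats::sd(x) == 0) return(FALSE)
  stats::shapiro.test(x)$p.value >= alpha
}
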