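# Group-summary and comparison layer: mean +/- SEM per group and the
# test-selection rule used for such datasets: Student's t-test (two groups)
# or one-way ANOVA with post-hoc Tukey (more), switching to Mann-Whitney U
# or Kruskal-Wallis rank ANOVA when Levene's test (centre = median) detects
# variance heterogeneity.

#' Per-group mean and SEM
#'
#' @param values numeric vector of measurements.
#' @param groups group labels, same length as `values`.
#' @return Data.frame of class `group_summary`: `group_tag`, `n`, `mean`,
#'   `sem` (sample SD / sqrt(n)). Every group must have n >= 2.
#' @export
summarize_groups <- function(values, groups) {
  if (length(values) != length(groups))
    abort_validation("'values' and 'groups' must have the same length")
  g <- factor(groups)
  ns <- tapply(values, g, length)
  if (any(ns < 2L))
    abort_validation("every group needs at least 2 values for a SEM")
  out <- data.frame(
    group_tag = levels(g),
    n = as.integer(ns),
    mean = as.numeric(tapply(values, g, mean)),
    sem = as.numeric(tapply(values, g, stats::sd) / sqrt(ns)))
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Compare groups with the heterogeneity-aware test selection rule
#'
#' Two groups: Student's t-test (pooled variance), or Mann-Whitney U when
#' Levene's test (centre = median) rejects variance homogeneity at
#' `alpha_levene`. More than two: one-way ANOVA with post-hoc Tukey HSD, or
#' Kruskal-Wallis rank ANOVA under heterogeneity.
#'
#' @param values numeric vector of measurements.
#' @param groups group labels, same length as `values` (>= 2 groups, each
#'   with n >= 2).
#' @param alpha significance level reported alongside the result.
#' @param alpha_levene level of the variance-heterogeneity pre-test.
#' @return A list of class `group_comparison`: `groups`, `method_used`
#'   (`"t_test"`, `"mann_whitney"`, `"anova_tukey"`,
#'   `"nonparametric_anova"`), `statistic`, `p_value`, `significant`,
#'   `variance_heterogeneity_detected`, `levene_p`, and `posthoc` (Tukey
#'   table, ANOVA path only).
#' @export
compare_groups <- function(values, groups, alpha = 0.05,
                           alpha_levene = 0.05) {
  if (length(values) != length(groups))
    abort_validation("'values' and 'groups' must have the same length")
  g <- factor(groups)
  if (nlevels(g) < 2L)
    abort_validation("at least two groups are required")
  if (any(tapply(values, g, length) < 2L))
    abort_validation("every group needs at least 2 values")

  lev <- car::leveneTest(values ~ g)
  lev_p <- lev[["Pr(>F)"]][1L]
  het <- is.finite(lev_p) && lev_p < alpha_levene

  posthoc <- NULL
  if (nlevels(g) == 2L) {
    if (het) {
      ht <- stats::wilcox.test(values ~ g, exact = FALSE)
      method <- "mann_whitney"
    } else {
      ht <- stats::t.test(values ~ g, var.equal = TRUE)
      method <- "t_test"
    }
    statistic <- unname(ht$statistic)
    p <- ht$p.value
  } else {
    if (het) {
      ht <- stats::kruskal.test(values ~ g)
      method <- "nonparametric_anova"
      statistic <- unname(ht$statistic)
      p <- ht$p.value
    } else {
      fit <- stats::aov(values ~ g)
      an <- summary(fit)[[1L]]
      method <- "anova_tukey"
      statistic <- an[["F value"]][1L]
      p <- an[["Pr(>F)"]][1L]
      posthoc <- as.data.frame(stats::TukeyHSD(fit)$g)
    }
  }
  structure(list(groups = levels(g), method_used = method,
                 statistic = statistic, p_value = p,
                 significant = is.finite(p) && p < alpha,
                 variance_heterogeneity_detected = het, levene_p = lev_p,
                 alpha = alpha, posthoc = posthoc),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s | %s: statistic = %.4g, p = %.4g%s\n",
              paste(x$groups, collapse = " vs "), x$method_used,
              x$statistic, x$p_value,
              if (x$variance_heterogeneity_detected)
                " (variance heterogeneity detected)" else ""))
  if (!is.null(x$posthoc)) {
    cat("Tukey HSD:\n")
    print(x$posthoc, ...)
  }
  invisible(x)
}
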