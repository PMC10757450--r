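#' Routine assumption checks and nonparametric tests
#'
#' Thin dispatcher over the standard published procedures used alongside the
#' ANOVAs: Shapiro-Wilk normality, Levene homoscedasticity (via
#' \pkg{car}), Spearman rank correlation, and the paired Wilcoxon signed-rank
#' test.
#'
#' @param which One of `"shapiro_wilk"`, `"levene"`, `"spearman"`,
#'   `"wilcoxon_paired"`.
#' @param x Numeric vector (values for Levene).
#' @param y Second vector (Spearman, paired Wilcoxon).
#' @param group Grouping factor (Levene).
#' @param ... Passed to the underlying test.
#' @return A list with `statistic`, `p_value`, `method`, plus the full
#'   underlying test object as `detail`.
#' @export
routine_tests <- function(which = c("shapiro_wilk", "levene", "spearman",
                                    "wilcoxon_paired"),
                          x, y = NULL, group = NULL, ...) {
  which <- match.arg(which)
  out <- switch(
    which,
    shapiro_wilk = {
      if (length(x) < 3) stop("Shapiro-Wilk needs at least 3 observations")
      t <- stats::shapiro.test(x)
      list(statistic = unname(t$statistic), p_value = t$p.value,
           method = "Shapiro-Wilk", detail = t)
    },
    levene = {
      if (is.null(group)) stop("Levene's test needs a grouping factor")
      t <- car::leveneTest(x, factor(group), ...)
      list(statistic = t[1, "F value"], p_value = t[1, "Pr(>F)"],
           method = "Levene", detail = t)
    },
    spearman = {
      if (is.null(y)) stop("Spearman correlation needs two vectors")
      t <- suppressWarnings(stats::cor.test(x, y, method = "spearman", ...))
      list(statistic = unname(t$estimate), p_value = t$p.value,
           method = "Spearman rho", detail = t)
    },
    wilcoxon_paired = {
      if (is.null(y)) stop("paired Wilcoxon needs two vectors")
      if (all(x == y)) {
        # all paired differences are zero: no evidence of a shift
        return(list(statistic = 0, p_value = 1,
                    method = "Wilcoxon signed rank (paired)", detail = NULL))
      }
      t <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE, ...))
      list(statistic = unname(t$statistic), p_value = t$p.value,
           method = "Wilcoxon signed rank (paired)", detail = t)
    }
  )
  out
}
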