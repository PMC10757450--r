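#' Chi-square test of homogeneity with residual post hocs
#'
#' Pearson chi-square test that category frequencies (e.g. presence of the
#' context effect) are homogeneous across groups, with standardized residuals
#' per cell and Bonferroni-adjusted post hoc p-values on the residuals of the
#' first ("effect present") column, one per group.
#'
#' @param x Counts matrix or table, rows = groups, columns = categories.
#' @return A list of class `"chisq_result"`: `chi2`, `df`, `p`,
#'   `std_residuals` (matrix), `posthoc` (data frame of per-group residual
#'   tests), `n_correction_applied = FALSE`, and `bf10` from
#'   [contingency_bf()].
#' @export
chi2_homogeneity <- function(x) {
  x <- as.matrix(x)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) stop("zero marginal in counts table")
  ct <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
  res <- ct$stdres
  g <- nrow(x)
  r1 <- res[, 1]
  p_raw <- 2 * stats::pnorm(-abs(r1))
  posthoc <- data.frame(
    group = if (!is.null(rownames(x))) rownames(x) else paste0("row", seq_len(g)),
    std_residual = as.numeric(r1),
    p_raw = p_raw,
    p_bonferroni = pmin(1, p_raw * g),
    stringsAsFactors = FALSE
  )
  rownames(posthoc) <- NULL
  structure(
    list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
         p = ct$p.value, std_residuals = res, posthoc = posthoc,
         n_correction_applied = FALSE, bf10 = contingency_bf(x)),
    class = "chisq_result"
  )
}

#' Chi-square test of independence with N-1 correction
#'
#' Pearson chi-square for a 2 x 2 table multiplied by `(N - 1) / N` (the
#' "N - 1" correction), with the p-value from the chi-square distribution on
#' 1 df and a contingency-table Bayes factor attached.
#'
#' @param x A 2 x 2 counts matrix or table.
#' @param N Total count used in the correction (defaults to `sum(x)`).
#' @return A list of class `"chisq_result"` with `n_correction_applied = TRUE`.
#' @export
chi2_independence_ncorr <- function(x, N = sum(x)) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, 2L))) stop("x must be a 2 x 2 table")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) stop("zero marginal in counts table")
  ct <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
  chi2_adj <- unname(ct$statistic) * (N - 1) / N
  structure(
    list(chi2 = chi2_adj, df = 1L,
         p = stats::pchisq(chi2_adj, 1, lower.tail = FALSE),
         std_residuals = ct$stdres, posthoc = NULL,
         n_correction_applied = TRUE, bf10 = contingency_bf(x)),
    class = "chisq_result"
  )
}

#' @export
print.chisq_result <- function(x, ...) {
  lab <- if (x$n_correction_applied) " (N-1 corrected)" else ""
  cat(sprintf("chi-square%s: chi2(%d) = %.3f, p = %.4g, BF10 = %.3g\n",
              lab, x$df, x$chi2, x$p, x$bf10))
  invisible(x)
}
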