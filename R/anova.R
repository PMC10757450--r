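#' Mixed-design (split-plot) ANOVA
#'
#' Fits the classical univariate split-plot decomposition for designs with
#' one between-participants factor and one or two (two-level) within-
#' participant factors, on cell means (one observation per participant x
#' within-cell). Between effects are tested against the participants-within-
#' groups stratum; each within effect and its interactions against the
#' corresponding factor x participant stratum. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` with the error of the effect's own
#' stratum. With two-level within factors sphericity holds trivially, so no
#' Greenhouse-Geisser correction is needed.
#'
#' Within-participant cells must be complete; between-group sizes may differ
#' (as when a control group is larger than the patient groups).
#'
#' @param data Long data frame of cell means.
#' @param dv Name of the response column.
#' @param between Name of the between-participants factor.
#' @param within Character vector of within-participant factor names.
#' @param subject Name of the participant identifier column.
#' @return An object of class `"mixed_anova"`: a list with `table` (effect,
#'   df_num, df_den, ss, ms, F, p, partial_eta_sq), the error-stratum mean
#'   squares, and the design information used by [posthoc_pairwise()].
#' @examples
#' d <- expand.grid(participant_id = paste0("p", 1:6),
#'                  treatment = c("OFF", "ON"))
#' d$group <- rep(c("A", "B"), each = 3)[match(d$participant_id, paste0("p", 1:6))]
#' set.seed(1); d$y <- rnorm(nrow(d))
#' mixed_anova(d, "y", between = "group", within = "treatment")
#' @export
mixed_anova <- function(data, dv, between, within,
                        subject = "participant_id") {
  cols <- c(dv, between, within, subject)
  if (!all(cols %in% names(data))) stop("missing columns: ",
                                        paste(setdiff(cols, names(data)), collapse = ", "))
  data <- data[, cols]
  if (anyNA(data)) stop("mixed_anova requires complete data (no NAs)")
  for (f in c(between, within, subject)) data[[f]] <- factor(data[[f]])

  # each subject in exactly one between level, all within cells present once
  tab <- table(data[[subject]])
  n_cells <- prod(vapply(within, function(w) nlevels(data[[w]]), 1L))
  if (any(tab != n_cells)) stop("incomplete within-participant cells")
  gmap <- tapply(data[[between]], data[[subject]],
                 function(g) length(unique(g)))
  if (any(gmap != 1L)) stop("each participant must belong to one between level")

  err_term <- paste0("Error(", subject, "/(", paste(within, collapse = "*"), "))")
  fml <- stats::as.formula(paste(dv, "~", paste(c(between, within), collapse = "*"),
                                 "+", err_term))
  fit <- stats::aov(fml, data = data)
  sm <- summary(fit)

  rows <- list(); err_ms <- list()
  ss_scale <- max(1, sum((data[[dv]] - mean(data[[dv]]))^2))
  for (stratum in names(sm)) {
    st <- sm[[stratum]][[1]]
    effs <- trimws(rownames(st))
    resid_i <- which(effs == "Residuals")
    ss_err <- st[resid_i, "Sum Sq"]; df_err <- st[resid_i, "Df"]
    err_ms[[stratum]] <- list(ms = ss_err / df_err, df = df_err, ss = ss_err)
    for (i in setdiff(seq_along(effs), resid_i)) {
      ss_i <- st[i, "Sum Sq"]
      f_i <- st[i, "F value"]; p_i <- st[i, "Pr(>F)"]
      tol <- 1e-12 * ss_scale
      if (ss_i <= tol) { f_i <- 0; p_i <- 1 }  # constant dv / numerical fuzz
      eta <- if (ss_i + ss_err <= tol) 0 else ss_i / (ss_i + ss_err)
      rows[[length(rows) + 1L]] <- data.frame(
        effect = effs[i], df_num = st[i, "Df"], df_den = df_err,
        ss = ss_i, ms = st[i, "Mean Sq"], F = f_i, p = p_i,
        partial_eta_sq = eta, stringsAsFactors = FALSE
      )
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(
    list(table = table, error_ms = err_ms, data = data, dv = dv,
         between = between, within = within, subject = subject),
    class = "mixed_anova"
  )
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat("Mixed-design ANOVA on", x$dv, "\n")
  tb <- x$table
  tb$F <- round(tb$F, 2); tb$p <- signif(tb$p, 3)
  tb$partial_eta_sq <- round(tb$partial_eta_sq, 3)
  print(tb[, c("effect", "df_num", "df_den", "F", "p", "partial_eta_sq")],
        row.names = FALSE)
  invisible(x)
}

#' Estimated marginal means on a balanced cell grid
#'
#' Unweighted averaging of cell means over collapsed factors: the marginal
#' mean of a level is the plain average of the cell means containing it,
#' which for a balanced design equals the least-squares marginal mean.
#'
#' @param cells Data frame of cell means: factor columns plus a value column.
#' @param margins Character vector of factor columns to keep.
#' @param value Name of the value column.
#' @return A data frame of marginal means, one row per kept-margin level
#'   combination.
#' @examples
#' cells <- data.frame(group = rep(c("H&Y3"), 2),
#'                     treatment = c("OFF", "ON"), mean = c(277.2, 267.7))
#' estimated_marginal_means(cells, "group")  # 272.45
#' @export
estimated_marginal_means <- function(cells, margins, value = "mean") {
  facs <- setdiff(names(cells), value)
  if (!all(margins %in% facs)) stop("margins must name factor columns of `cells`")
  # collapse replicates (if any) to the full cell grid first
  grid <- stats::aggregate(cells[[value]], cells[facs], mean)
  names(grid)[ncol(grid)] <- value
  full <- prod(vapply(facs, function(f) length(unique(grid[[f]])), 1L))
  out <- stats::aggregate(grid[[value]], grid[margins], mean)
  names(out)[ncol(out)] <- value
  out
}

#' Cohen's d effect sizes
#'
#' Two variants used with the post hoc contrasts: `"between_pooled"` divides
#' the mean difference by the pooled SD of the two groups; `"within_av"`
#' (for repeated-measures contrasts) divides by the plain average of the two
#' condition SDs.
#'
#' @param kind `"between_pooled"` or `"within_av"`.
#' @param m1,m2 Condition/group means.
#' @param sd1,sd2 Condition/group SDs.
#' @param n1,n2 Group sizes (pooling weights; equal by default).
#' @return Signed d for `m1 - m2`.
#' @export
cohens_d <- function(kind = c("between_pooled", "within_av"),
                     m1, m2, sd1, sd2, n1 = NULL, n2 = NULL) {
  kind <- match.arg(kind)
  denom <- if (kind == "between_pooled") {
    if (is.null(n1) || is.null(n2)) { n1 <- 2; n2 <- 2 }
    sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  } else {
    (sd1 + sd2) / 2
  }
  if (is.na(denom)) return(NA_real_)
  if (denom <= 0) stop("zero SD: Cohen's d undefined")
  (m1 - m2) / denom
}

# Subject-level means of dv at a subset of within-cells (or all).
subject_means <- function(fit, keep = NULL) {
  d <- fit$data
  if (!is.null(keep)) {
    for (f in names(keep)) d <- d[d[[f]] == keep[[f]], , drop = FALSE]
  }
  agg <- stats::aggregate(d[[fit$dv]],
                          list(subject = d[[fit$subject]], group = d[[fit$between]]),
                          mean)
  names(agg)[3] <- "y"
  agg
}

comparison_row <- function(label, m_diff, se, df, n_family, d, bf) {
  t <- m_diff / se
  p_raw <- 2 * stats::pt(-abs(t), df)
  data.frame(
    label = label, m_diff = m_diff, se = se, t = t, df = df,
    p_raw = p_raw, p_bonferroni = min(1, p_raw * n_family),
    ci_lo = m_diff - stats::qt(0.975, df) * se,
    ci_hi = m_diff + stats::qt(0.975, df) * se,
    cohens_d = d, bf10 = bf, stringsAsFactors = FALSE
  )
}

#' Bonferroni post hoc pairwise comparisons
#'
#' Pairwise contrasts after a [mixed_anova()], using the stratum-appropriate
#' pooled error and its degrees of freedom (for the emulated design both
#' strata give df = N - g):
#' \itemize{
#'   \item `factor = between` (no `at`): pairwise groups on participant
#'     marginal means, pooled one-way residual across all groups.
#'   \item `factor = a within factor`, `by = between`: within-level pairs in
#'     each group, with the difference variance pooled across groups; set
#'     `by = NULL` for the overall (main-effect) contrast.
#'   \item `factor = between`, `at = list(<within> = <level>)`: groups
#'     compared at one within level, residual pooled across groups at that
#'     level.
#' }
#' Raw p-values are Bonferroni-multiplied by the family size (defaults to the
#' number of comparisons generated). Cohen's d uses the pooled-SD variant for
#' between contrasts and the averaged-SD variant for within contrasts; the
#' default JZS Bayes factor is computed from each contrast's t and the group
#' sizes.
#'
#' @param fit A `"mixed_anova"` object.
#' @param factor Name of the factor whose levels are compared.
#' @param by Optional conditioning factor (within contrasts per group).
#' @param at Optional named list fixing within-factor levels.
#' @param family_size Bonferroni family size.
#' @param rscale Cauchy prior scale for the Bayes factor.
#' @return A data frame of comparisons: `label`, `m_diff`, `se`, `t`, `df`,
#'   `p_raw`, `p_bonferroni`, `ci_lo`, `ci_hi`, `cohens_d`, `bf10`.
#' @export
posthoc_pairwise <- function(fit, factor, by = NULL, at = NULL,
                             family_size = NULL, rscale = 0.707) {
  stopifnot(inherits(fit, "mixed_anova"))
  d <- fit$data
  rows <- list()

  if (factor == fit$between) {
    sm <- subject_means(fit, keep = at)
    groups <- levels(sm$group)
    # pooled residual across groups
    resid <- unlist(lapply(split(sm$y, sm$group), function(v) v - mean(v)))
    df_err <- nrow(sm) - length(groups)
    mse <- sum(resid^2) / df_err
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    for (pr in pairs) {
      y1 <- sm$y[sm$group == pr[1]]; y2 <- sm$y[sm$group == pr[2]]
      m_diff <- mean(y1) - mean(y2)
      se <- sqrt(mse * (1 / length(y1) + 1 / length(y2)))
      dd <- cohens_d("between_pooled", mean(y1), mean(y2),
                     stats::sd(y1), stats::sd(y2), length(y1), length(y2))
      t_c <- m_diff / se
      bf <- jzs_ttest_bf(t_c, n1 = length(y1), n2 = length(y2), rscale = rscale)
      lab <- paste(pr[1], "vs", pr[2])
      if (!is.null(at)) lab <- paste0(paste(unlist(at), collapse = "/"), ": ", lab)
      rows[[length(rows) + 1L]] <- list(lab, m_diff, se, df_err, dd, bf)
    }
  } else if (factor %in% fit$within) {
    lv <- levels(d[[factor]])
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    groups <- levels(d[[fit$between]])
    for (pr in pairs) {
      s1 <- subject_means(fit, keep = stats::setNames(list(pr[1]), factor))
      s2 <- subject_means(fit, keep = stats::setNames(list(pr[2]), factor))
      mg <- merge(s1, s2, by = c("subject", "group"), suffixes = c("_1", "_2"))
      mg$diff <- mg$y_1 - mg$y_2
      # difference variance pooled across all groups (factor x subject stratum)
      resid <- unlist(lapply(split(mg$diff, mg$group), function(v) v - mean(v)))
      df_err <- nrow(mg) - length(groups)
      s2_pooled <- sum(resid^2) / df_err
      target_groups <- if (is.null(by)) list(NULL) else as.list(groups)
      for (g in target_groups) {
        sub <- if (is.null(g)) mg else mg[mg$group == g, , drop = FALSE]
        if (is.null(g)) {
          # unweighted main-effect contrast across groups
          gm <- tapply(sub$diff, droplevels(sub$group), mean)
          m_diff <- mean(gm)
          ng <- table(droplevels(sub$group))
          se <- sqrt(s2_pooled * sum(1 / ng) / length(ng)^2)
          n_bf <- nrow(sub)
          lab <- paste(factor, pr[1], "vs", pr[2])
        } else {
          m_diff <- mean(sub$diff)
          se <- sqrt(s2_pooled / nrow(sub))
          n_bf <- nrow(sub)
          lab <- paste0(g, " ", pr[1], " vs ", pr[2])
        }
        dd <- cohens_d("within_av", mean(sub$y_1), mean(sub$y_2),
                       stats::sd(sub$y_1), stats::sd(sub$y_2))
        t_c <- m_diff / se
        bf <- jzs_ttest_bf(t_c, n1 = n_bf, rscale = rscale)
        rows[[length(rows) + 1L]] <- list(lab, m_diff, se, df_err, dd, bf)
      }
    }
  } else {
    stop("`factor` must be the between factor or one of the within factors")
  }

  n_family <- family_size %||% length(rows)
  out <- do.call(rbind, lapply(rows, function(r)
    comparison_row(r[[1]], r[[2]], r[[3]], r[[4]], n_family, r[[5]], r[[6]])))
  rownames(out) <- NULL
  out
}
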