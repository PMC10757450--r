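#' Per-session RT/MT cell means by trial type
#'
#' Averages reaction times and movement times separately for no-stop trials
#' (stop-signal task context) and go-only trials (simple reaction-time task),
#' one row per participant x session. These cell means are the inputs to the
#' mixed-design ANOVAs of the context effect: strategic slowing of the
#' response in a stop-possible context (longer no-stop RTs) together with
#' faster execution once started (shorter no-stop MTs).
#'
#' @param trials Preprocessed trials (see [preprocess_trials()]).
#' @return A data frame with columns `participant_id`, `group`, `treatment`,
#'   `rt_no_stop`, `rt_go_only`, `mt_no_stop`, `mt_go_only`. Missing cells
#'   yield `NA` with a warning.
#' @export
context_cell_means <- function(trials) {
  pool <- trials[trials$outcome %in% rt_pool_outcomes() &
                   trials$trial_type %in% c("go_only", "no_stop"), , drop = FALSE]
  parts <- split(pool, interaction(pool$participant_id, pool$treatment, drop = TRUE))
  rows <- lapply(parts, function(d) {
    cell <- function(tt, col) {
      v <- d[[col]][d$trial_type == tt & !is.na(d[[col]])]
      if (length(v) == 0L) NA_real_ else mean(v)
    }
    data.frame(
      participant_id = d$participant_id[1], group = d$group[1],
      treatment = d$treatment[1],
      rt_no_stop = cell("no_stop", "rt"), rt_go_only = cell("go_only", "rt"),
      mt_no_stop = cell("no_stop", "mt"), mt_go_only = cell("go_only", "mt"),
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (anyNA(res[, c("rt_no_stop", "rt_go_only", "mt_no_stop", "mt_go_only")])) {
    warning("some participant x session cells have no analysable trials")
  }
  res
}

#' Population cumulative distribution
#'
#' Builds the population-level cumulative distribution of a measure by
#' averaging the per-participant empirical CDFs with equal weight on the
#' pooled support grid (so every participant contributes 1/n regardless of
#' trial count).
#'
#' @param trials Preprocessed trials of one group x session.
#' @param measure `"rt"` or `"mt"`.
#' @param trial_type `"no_stop"` or `"go_only"`.
#' @param min_trials Minimum analysable trials for a participant to enter.
#' @return A list of class `"population_cdf"`: `grid` (sorted ms values),
#'   `cdf` (non-decreasing, ending at 1), `n_participants`.
#' @export
build_population_cdf <- function(trials, measure = c("rt", "mt"),
                                 trial_type = c("no_stop", "go_only"),
                                 min_trials = 5) {
  measure <- match.arg(measure)
  trial_type <- match.arg(trial_type)
  pool <- trials[trials$trial_type == trial_type &
                   trials$outcome %in% rt_pool_outcomes() &
                   !is.na(trials[[measure]]), , drop = FALSE]
  vals <- split(pool[[measure]], pool$participant_id, drop = TRUE)
  vals <- vals[vapply(vals, length, 1L) >= min_trials]
  if (length(vals) == 0L) stop("no participant has >= ", min_trials, " trials in this cell")
  grid <- sort(unique(unlist(vals)))
  cdfs <- vapply(vals, function(v) stats::ecdf(v)(grid), numeric(length(grid)))
  cdf <- if (is.matrix(cdfs)) rowMeans(cdfs) else cdfs
  structure(list(grid = grid, cdf = cdf, n_participants = length(vals)),
            class = "population_cdf")
}

# The three directional KS tests behind every context-effect decision.
# The context effect predicts no-stop RTs stochastically larger than go-only
# RTs, and no-stop MTs stochastically smaller than go-only MTs.
context_ks_tests <- function(rt_go, rt_ns, mt_go, mt_ns, exact = NULL) {
  list(
    rt_expected = ks_two_sample(rt_go, rt_ns, "greater", exact = exact),
    rt_opposite = ks_two_sample(rt_go, rt_ns, "less", exact = exact),
    mt_expected = ks_two_sample(mt_go, mt_ns, "less", exact = exact),
    mt_opposite = ks_two_sample(mt_go, mt_ns, "greater", exact = exact)
  )
}

measure_verdict <- function(exp_p, opp_p, alpha) {
  if (exp_p < alpha && opp_p >= alpha) "effect"
  else if (exp_p < alpha && opp_p < alpha) "no_context"  # distributions intersect
  else "no_context"
}

#' Population-level context-effect test
#'
#' Evaluates the context effect for a group x session by a pair of one-tailed
#' two-sample KS tests per measure, run in opposite directions. If only the
#' expected direction is significant the measure shows the effect; if both
#' directions are significant the distributions intersect and no effect is
#' declared; if neither is, there is no evidence of an effect. The overall
#' verdict is `"context"` only when both the RT effect (no-stop slower) and
#' the MT effect (no-stop faster) hold.
#'
#' Tests are run on the trial-level samples pooled over participants (a
#' p-value needs a sample size); the averaged population CDFs of
#' [build_population_cdf()] serve for plotting and direction only.
#'
#' @param trials Preprocessed trials of one group x session.
#' @param alpha Significance level per one-tailed test.
#' @param exact Passed to [ks_two_sample()].
#' @return A list with `rt_verdict`, `mt_verdict` (`"effect"` or
#'   `"no_context"`), `overall` (`"context"` or `"no_context"`), and the four
#'   underlying `tests`.
#' @export
population_context_test <- function(trials, alpha = 0.05, exact = NULL) {
  pool <- trials[trials$outcome %in% rt_pool_outcomes(), , drop = FALSE]
  grab <- function(tt, col) {
    v <- pool[[col]][pool$trial_type == tt]
    v[!is.na(v)]
  }
  tests <- context_ks_tests(grab("go_only", "rt"), grab("no_stop", "rt"),
                            grab("go_only", "mt"), grab("no_stop", "mt"),
                            exact = exact)
  rt_v <- measure_verdict(tests$rt_expected$p_value, tests$rt_opposite$p_value, alpha)
  mt_v <- measure_verdict(tests$mt_expected$p_value, tests$mt_opposite$p_value, alpha)
  list(
    rt_verdict = rt_v, mt_verdict = mt_v,
    overall = if (rt_v == "effect" && mt_v == "effect") "context" else "no_context",
    tests = tests
  )
}

#' Individual-level context-effect classification
#'
#' Classifies one participant x session from the directional KS tests on that
#' participant's own trial distributions:
#' \itemize{
#'   \item `"context"`: no-stop RTs significantly larger, no-stop MTs
#'     significantly smaller, and the opposite MT direction not significant;
#'   \item `"inverse_context"`: no-stop MTs significantly *longer* (opposite
#'     direction significant, expected direction not);
#'   \item `"no_context"`: everything else, including intersecting MT
#'     distributions (both directions significant).
#' }
#' The decision table is total: exactly one category is returned.
#'
#' @param trials Preprocessed trials of one participant x session.
#' @param alpha Significance level per one-tailed test (uncorrected).
#' @param exact Passed to [ks_two_sample()].
#' @return A list of class `"context_category"`: `category` plus the four
#'   tests.
#' @export
classify_individual_context <- function(trials, alpha = 0.05, exact = NULL) {
  pool <- trials[trials$outcome %in% rt_pool_outcomes(), , drop = FALSE]
  grab <- function(tt, col) {
    v <- pool[[col]][pool$trial_type == tt]
    v[!is.na(v)]
  }
  rt_go <- grab("go_only", "rt"); rt_ns <- grab("no_stop", "rt")
  mt_go <- grab("go_only", "mt"); mt_ns <- grab("no_stop", "mt")
  if (!length(rt_go) || !length(rt_ns) || !length(mt_go) || !length(mt_ns)) {
    stop("participant lacks analysable trials in one of the task cells")
  }
  tests <- context_ks_tests(rt_go, rt_ns, mt_go, mt_ns, exact = exact)
  rt_sig <- tests$rt_expected$p_value < alpha
  mt_exp <- tests$mt_expected$p_value < alpha
  mt_opp <- tests$mt_opposite$p_value < alpha
  category <-
    if (rt_sig && mt_exp && !mt_opp) "context"
    else if (mt_opp && !mt_exp) "inverse_context"
    else "no_context"
  structure(
    list(category = category, rt_test = tests$rt_expected,
         mt_test_expected = tests$mt_expected,
         mt_test_opposite = tests$mt_opposite),
    class = "context_category"
  )
}

#' Context-effect frequency table
#'
#' Tabulates counts and percentages of the three individual-level categories
#' per group x session; the counts feed the chi-square procedures.
#'
#' @param categories A data frame with columns `participant_id`, `group`,
#'   `treatment`, `category`.
#' @return A data frame with one row per group x treatment x category,
#'   columns `n` and `percent`.
#' @export
context_frequencies <- function(categories) {
  lv <- c("context", "no_context", "inverse_context")
  cells <- split(categories, interaction(categories$group, categories$treatment,
                                         drop = TRUE))
  rows <- lapply(cells, function(d) {
    counts <- table(factor(d$category, levels = lv))
    data.frame(group = d$group[1], treatment = d$treatment[1],
               category = lv, n = as.integer(counts),
               percent = 100 * as.integer(counts) / nrow(d),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Classify every session in a trial table
#'
#' Convenience wrapper running [classify_individual_context()] on every
#' participant x session.
#'
#' @inheritParams classify_individual_context
#' @return A data frame with `participant_id`, `group`, `treatment`,
#'   `category`.
#' @export
classify_all_sessions <- function(trials, alpha = 0.05, exact = NULL) {
  parts <- split(trials, interaction(trials$participant_id, trials$treatment,
                                     drop = TRUE))
  rows <- lapply(parts, function(d) {
    cat <- tryCatch(classify_individual_context(d, alpha, exact)$category,
                    error = function(e) NA_character_)
    data.frame(participant_id = d$participant_id[1], group = d$group[1],
               treatment = d$treatment[1], category = cat,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
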