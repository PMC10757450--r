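#' Reaction-time limit handling
#'
#' Normalises outcome labels against the no-stop RT-limit rule: recorded
#' responses up to the 800 ms limit are correct, responses inside the 100 ms
#' grace window (800-900 ms) are kept as `overtime_reaching` (their RTs stay
#' in all RT analyses), and later responses are aborted (`aborted_over_900`,
#' RT removed; they count as errors for accuracy but never enter RT pools).
#' Lapse outcomes (`target_miss`, `hold_violation`) and stop-trial outcomes
#' are left untouched.
#'
#' @param trials A trial data frame.
#' @param rt_limit,rt_grace Limit and grace window, ms.
#' @return The trial data frame with consistent outcome labels and an added
#'   logical column `rt_analyzable` marking rows whose RT enters RT analyses.
#' @export
apply_rt_limit <- function(trials, rt_limit = 800, rt_grace = 100) {
  hard <- rt_limit + rt_grace
  reach <- trials$outcome %in% c("correct", "overtime_reaching")
  has_rt <- !is.na(trials$rt)
  over <- has_rt & trials$rt > hard
  trials$outcome[over] <- "aborted_over_900"
  trials$rt[over] <- NA_real_
  trials$mt[over] <- NA_real_
  grace <- reach & has_rt & trials$rt > rt_limit & trials$rt <= hard
  trials$outcome[grace] <- "overtime_reaching"
  ok <- reach & has_rt & trials$rt <= rt_limit
  trials$outcome[ok] <- "correct"
  trials$rt_analyzable <- trials$outcome %in% rt_pool_outcomes() & !is.na(trials$rt)
  trials
}

#' Outlier trimming of reaction times
#'
#' Discards trials whose RT falls outside mean +/- 3 SD, with the mean and
#' sample SD (n - 1 denominator) computed on the untrimmed RTs of each scope
#' cell in a single pass (no re-trimming). The default scope is participant x
#' session x task x trial type, the conventional per-participant scoping that
#' avoids leaking group-level differences into the trimming rule. Trials
#' without an analysable RT (successful stops, aborts, lapses) are never
#' candidates. Scope cells with fewer than two RTs are left untrimmed with a
#' warning.
#'
#' @param trials A trial data frame (after [apply_rt_limit()]).
#' @param scope Character vector of grouping columns.
#' @param n_sd Trimming width in SDs.
#' @return A list with `trials` (trimmed table) and `report`, a data frame
#'   with one row per scope cell: counts in, removed, and fraction removed.
#' @examples
#' d <- data.frame(participant_id = "p1", treatment = "NA", task = "go_only",
#'                 trial_type = "go_only", rt = c(rep(500, 19), 10000),
#'                 mt = 400, outcome = "correct")
#' trim_outliers(d)$report
#' @export
trim_outliers <- function(trials,
                          scope = c("participant_id", "treatment", "task", "trial_type"),
                          n_sd = 3) {
  if (!all(scope %in% names(trials))) stop("scope columns missing from trials")
  if (is.null(trials$rt_analyzable)) {
    trials$rt_analyzable <- trials$outcome %in% rt_pool_outcomes() & !is.na(trials$rt)
  }
  key <- interaction(trials[scope], drop = TRUE, sep = "|")
  drop <- logical(nrow(trials))
  cells <- levels(key)
  report <- data.frame(scope = cells, n_input = 0L, n_removed = 0L,
                       fraction_removed = 0, stringsAsFactors = FALSE)
  few <- character(0)
  for (i in seq_along(cells)) {
    idx <- which(key == cells[i] & trials$rt_analyzable)
    report$n_input[i] <- length(idx)
    if (length(idx) < 2L) {
      if (length(idx) > 0L) few <- c(few, cells[i])
      next
    }
    r <- trials$rt[idx]
    m <- mean(r); s <- stats::sd(r)
    out <- idx[r < m - n_sd * s | r > m + n_sd * s]
    drop[out] <- TRUE
    report$n_removed[i] <- length(out)
    report$fraction_removed[i] <-
      if (length(idx) > 0) length(out) / length(idx) else 0
  }
  if (length(few) > 0) {
    warning("fewer than 2 RTs in scope cell(s): ", paste(few, collapse = ", "),
            " - left untrimmed")
  }
  list(trials = trials[!drop, , drop = FALSE], report = report)
}

#' Task accuracy
#'
#' Accuracy is the ratio of correct go trials to all go trials, where the
#' denominator counts correct trials plus target misses, hold violations and
#' aborted trials. Overtime reaches (800-900 ms) reached the target and are
#' counted as correct by default; set `overtime_as_error = TRUE` to count them
#' as errors instead (the online task feedback treated them as such).
#'
#' @param trials Go-only or no-stop trials of one participant x session.
#' @param overtime_as_error Count overtime reaches as errors?
#' @return Proportion in [0, 1].
#' @export
compute_accuracy <- function(trials, overtime_as_error = FALSE) {
  keep <- trials$trial_type %in% c("go_only", "no_stop")
  oc <- trials$outcome[keep]
  if (length(oc) == 0L) stop("no go trials to compute accuracy from")
  good <- oc == "correct"
  if (!overtime_as_error) good <- good | oc == "overtime_reaching"
  mean(good)
}

#' Preprocess a trial table
#'
#' Applies the RT-limit rule, performs one pass of +/- 3 SD outlier trimming,
#' and tabulates per-session accuracy for both tasks.
#'
#' @param trials A raw trial data frame from [simulate_study()] or
#'   [read_trials()].
#' @param scope Trimming scope, see [trim_outliers()].
#' @param overtime_as_error Accuracy convention, see [compute_accuracy()].
#' @return A list with `trials` (clean table), `trim_report`, and `accuracy`
#'   (per participant x session x task).
#' @export
preprocess_trials <- function(trials,
                              scope = c("participant_id", "treatment", "task", "trial_type"),
                              overtime_as_error = FALSE) {
  trials <- apply_rt_limit(trials)
  tr <- trim_outliers(trials, scope = scope)
  go <- tr$trials[tr$trials$trial_type %in% c("go_only", "no_stop"), ]
  acc <- do.call(rbind, lapply(
    split(go, interaction(go$participant_id, go$treatment, go$task, drop = TRUE)),
    function(d) data.frame(
      participant_id = d$participant_id[1], group = d$group[1],
      treatment = d$treatment[1], task = d$task[1],
      accuracy = compute_accuracy(d, overtime_as_error),
      stringsAsFactors = FALSE
    )
  ))
  rownames(acc) <- NULL
  list(trials = tr$trials, trim_report = tr$report, accuracy = acc)
}
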