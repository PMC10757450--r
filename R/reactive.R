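#' Stop-trial summaries
#'
#' Computes the probability of failing to stop and the mean stop-signal delay
#' over all stop trials of one session (the tracking-method convention: the
#' mean SSD is taken over every stop trial, not only failures).
#'
#' @param stop_trials Data frame of stop trials (columns `ssd`, `outcome`).
#' @return A list with `p_failure`, `mean_ssd` and `n_stop`.
#' @export
stop_summaries <- function(stop_trials) {
  if (nrow(stop_trials) == 0L) stop("no stop trials")
  if (!all(stop_trials$outcome %in% c("stop_failure", "stop_success"))) {
    stop("stop_trials must contain only stop outcomes")
  }
  list(
    p_failure = mean(stop_trials$outcome == "stop_failure"),
    mean_ssd = mean(stop_trials$ssd),
    n_stop = nrow(stop_trials)
  )
}

#' SSRT by the integration method
#'
#' Estimates the stop-signal reaction time under the independent horse-race
#' model: the go-RT distribution is integrated up to the observed probability
#' of failing to stop, and the mean SSD is subtracted from that quantile.
#' Following the consensus tracking-method recipe, go omissions (responses
#' aborted beyond the RT window, passed as `NA`) are replaced by the maximum
#' observed go RT, the RTs are sorted, and the quantile is the RT at rank
#' `ceiling(p_failure * N)` (clamped to `[1, N]`).
#'
#' @param go_rts Numeric vector of the session's no-stop RTs (post trimming,
#'   overtime reaches included), with `NA` marking omissions.
#' @param p_failure Observed probability of failing to stop, strictly inside
#'   (0, 1) for the estimate to exist.
#' @param mean_ssd Mean stop-signal delay, ms.
#' @param n_stop Optional stop-trial count (>= 50 flags a reliable estimate).
#' @return A list of class `"ssrt_estimate"`: `ssrt`, `p_failure`,
#'   `mean_ssd`, `n_stop`, `n_go`, `n_omissions`, `reliable`.
#' @examples
#' est <- estimate_ssrt_integration(c(300, 400, 500, 600, 700),
#'                                  p_failure = 0.4, mean_ssd = 150)
#' est$ssrt  # 400 - 150 = 250
#' @export
estimate_ssrt_integration <- function(go_rts, p_failure, mean_ssd,
                                      n_stop = NA_integer_) {
  if (length(go_rts) == 0L) stop("empty go-RT vector")
  if (all(is.na(go_rts))) stop("go_rts contains only omissions")
  if (!is.numeric(p_failure) || length(p_failure) != 1L ||
      p_failure <= 0 || p_failure >= 1) {
    stop("SSRT undefined: p_failure must lie strictly between 0 and 1")
  }
  n_om <- sum(is.na(go_rts))
  go_rts[is.na(go_rts)] <- max(go_rts, na.rm = TRUE)
  n <- length(go_rts)
  sorted <- sort(go_rts)
  rank <- min(n, max(1L, ceiling(p_failure * n)))
  structure(
    list(ssrt = sorted[rank] - mean_ssd, p_failure = p_failure,
         mean_ssd = mean_ssd, n_stop = n_stop, n_go = n, n_omissions = n_om,
         reliable = !is.na(n_stop) && n_stop >= 50),
    class = "ssrt_estimate"
  )
}

#' @export
print.ssrt_estimate <- function(x, ...) {
  cat(sprintf("SSRT (integration): %.1f ms  [P(failure) %.3f, mean SSD %.1f ms, n_go %d]\n",
              x$ssrt, x$p_failure, x$mean_ssd, x$n_go))
  invisible(x)
}

#' Race-model assumption checks
#'
#' Verifies, for one session, the two diagnostics that license an SSRT
#' estimate: (i) stochastic independence of the go and stop processes, whose
#' race-model signature is that stop-failure RTs are faster on average than
#' no-stop RTs (failures are go processes fast enough to escape inhibition);
#' (ii) that the staircase tracked the 50% failure point. Sessions failing the
#' independence check are flagged, not dropped; exclusion is a pipeline
#' choice.
#'
#' @param trials One participant x session of stop-signal task trials.
#' @param band Half-width of the acceptable `|p_failure - 0.5|` band.
#' @return A list with `mean_rt_stop_failure`, `mean_rt_no_stop`,
#'   `p_failure`, `independence_ok` (NA when no failed stops exist) and
#'   `staircase_ok`.
#' @export
check_race_assumptions <- function(trials, band = 0.1) {
  sst <- trials[trials$task == "sst", , drop = FALSE]
  ns_rt <- sst$rt[sst$trial_type == "no_stop" &
                    sst$outcome %in% rt_pool_outcomes() & !is.na(sst$rt)]
  sf_rt <- sst$rt[sst$outcome == "stop_failure" & !is.na(sst$rt)]
  stops <- sst[sst$trial_type == "stop", , drop = FALSE]
  p_fail <- if (nrow(stops) > 0) mean(stops$outcome == "stop_failure") else NA_real_
  list(
    mean_rt_stop_failure = if (length(sf_rt)) mean(sf_rt) else NA_real_,
    mean_rt_no_stop = if (length(ns_rt)) mean(ns_rt) else NA_real_,
    p_failure = p_fail,
    independence_ok = if (length(sf_rt) && length(ns_rt))
      mean(sf_rt) < mean(ns_rt) else NA,
    staircase_ok = if (!is.na(p_fail)) abs(p_fail - 0.5) <= band else NA
  )
}

#' Per-session reactive-inhibition summaries
#'
#' Runs the integration-method SSRT estimate and the race-model checks for
#' every participant x session in a preprocessed trial table.
#'
#' @param trials Preprocessed trials (see [preprocess_trials()]).
#' @param band Staircase tolerance band, see [check_race_assumptions()].
#' @return A data frame with one row per participant x session: `ssrt`,
#'   `p_failure`, `mean_ssd`, `n_stop`, `n_go`, `n_omissions`,
#'   `independence_ok`, `staircase_ok`, `reliable`.
#' @export
reactive_summaries <- function(trials, band = 0.1) {
  sst <- trials[trials$task == "sst", , drop = FALSE]
  parts <- split(sst, interaction(sst$participant_id, sst$treatment, drop = TRUE))
  rows <- lapply(parts, function(d) {
    stops <- d[d$trial_type == "stop", , drop = FALSE]
    ss <- stop_summaries(stops)
    go_rts <- d$rt[d$trial_type == "no_stop" & d$outcome %in% rt_pool_outcomes()]
    n_om <- sum(d$trial_type == "no_stop" & d$outcome == "aborted_over_900")
    go_vec <- c(go_rts, rep(NA_real_, n_om))
    est <- tryCatch(
      estimate_ssrt_integration(go_vec, ss$p_failure, ss$mean_ssd, ss$n_stop),
      error = function(e) NULL
    )
    chk <- check_race_assumptions(d, band = band)
    data.frame(
      participant_id = d$participant_id[1], group = d$group[1],
      treatment = d$treatment[1],
      ssrt = if (is.null(est)) NA_real_ else est$ssrt,
      p_failure = ss$p_failure, mean_ssd = ss$mean_ssd,
      n_stop = ss$n_stop,
      n_go = length(go_vec), n_omissions = n_om,
      independence_ok = chk$independence_ok,
      staircase_ok = chk$staircase_ok,
      reliable = ss$n_stop >= 50,
      stringsAsFactors = FALSE
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
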