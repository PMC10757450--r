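#' Staircase tracking of the stop-signal delay
#'
#' The stop-signal delay (SSD) is adapted trial by trial so that stopping
#' succeeds on about half of the stop trials: after a successful stop the SSD
#' is increased by one step (stopping becomes harder), after a failed stop it
#' is decreased by the same amount (stopping becomes easier). The SSD starts
#' at nine display refresh periods (119.7 ms at a 13.3 ms refresh) and moves
#' in steps of three refresh periods (39.9 ms), so it always stays on the
#' refresh grid. It is clamped at 0 ms.
#'
#' @param ssd_init Initial SSD in ms.
#' @param ssd_step Step size in ms.
#' @return `staircase_init` returns a staircase state: a list with
#'   `current_ssd`, `ssd_step`, and a `history` data frame of (ssd, outcome)
#'   pairs, one row per processed stop trial.
#' @examples
#' st <- staircase_init()
#' st <- staircase_update(st, "stop_success")   # 119.7 -> 159.6
#' st <- staircase_update(st, "stop_failure")   # 159.6 -> 119.7
#' st$current_ssd
#' @export
staircase_init <- function(ssd_init = 119.7, ssd_step = 39.9) {
  stopifnot(is.numeric(ssd_init), ssd_init >= 0, is.numeric(ssd_step), ssd_step > 0)
  structure(
    list(current_ssd = ssd_init, ssd_step = ssd_step,
         ssd_history = numeric(0), outcome_history = character(0)),
    class = "staircase"
  )
}

#' @rdname staircase_init
#' @param state A staircase state from [staircase_init()].
#' @param outcome Either `"stop_success"` or `"stop_failure"`.
#' @return `staircase_update` returns the updated state; the SSD used on the
#'   processed trial is appended to the history before the update.
#' @export
staircase_update <- function(state, outcome) {
  if (!inherits(state, "staircase")) stop("`state` must come from staircase_init()")
  if (!is.character(outcome) || length(outcome) != 1L ||
      !outcome %in% c("stop_success", "stop_failure")) {
    stop("`outcome` must be \"stop_success\" or \"stop_failure\"")
  }
  state$ssd_history <- c(state$ssd_history, state$current_ssd)
  state$outcome_history <- c(state$outcome_history, outcome)
  delta <- if (outcome == "stop_success") state$ssd_step else -state$ssd_step
  state$current_ssd <- max(0, state$current_ssd + delta)
  state
}

#' @export
print.staircase <- function(x, ...) {
  cat("SSD staircase: current", format(x$current_ssd), "ms,",
      length(x$ssd_history), "stop trials tracked\n")
  invisible(x)
}
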