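#' Group-by-treatment generative presets
#'
#' Population-level behavioural parameters for each simulated cell of the
#' study design: three Parkinson's disease groups staged by Hoehn and Yahr
#' score (H&Y1 = stages 1-1.5, H&Y2 = stage 2, H&Y3 = stages 2.5-3), each
#' assessed ON and OFF dopaminergic medication, plus a single-session healthy
#' control (HC) group. Means and between-participant SDs are the observed
#' behavioural summaries of the cohort the simulator emulates: stop-signal
#' reaction time (SSRT), no-stop and go-only reaction times (RT) and movement
#' times (MT), and task accuracies. The simulator treats these as the
#' population distribution of participant-level parameters.
#'
#' All latencies are in milliseconds; accuracies are proportions.
#'
#' @return A data frame with one row per (group, treatment) cell and columns
#'   \code{group}, \code{treatment}, \code{ssrt_mean}, \code{ssrt_sd},
#'   \code{rt_no_stop_mean}, \code{rt_no_stop_sd}, \code{rt_go_only_mean},
#'   \code{rt_go_only_sd}, \code{mt_no_stop_mean}, \code{mt_no_stop_sd},
#'   \code{mt_go_only_mean}, \code{mt_go_only_sd}, \code{acc_no_stop},
#'   \code{acc_go_only}.
#' @examples
#' cohort_presets()
#' @export
cohort_presets <- function() {
  data.frame(
    group     = c("H&Y1", "H&Y1", "H&Y2", "H&Y2", "H&Y3", "H&Y3", "HC"),
    treatment = c("OFF", "ON", "OFF", "ON", "OFF", "ON", "NA"),
    ssrt_mean = c(227.0, 252.3, 237.7, 254.6, 277.2, 267.7, 221.9),
    ssrt_sd   = c(34.1, 37.7, 29.4, 42.7, 39.0, 42.6, 25.7),
    rt_no_stop_mean = c(614.4, 592.3, 531.6, 517.3, 513.6, 493.0, 492.3),
    rt_no_stop_sd   = c(98.9, 105.2, 72.2, 127.0, 127.8, 136.4, 99.3),
    rt_go_only_mean = c(267.8, 274.9, 294.1, 276.0, 279.3, 293.7, 306.5),
    rt_go_only_sd   = c(52.0, 58.3, 59.7, 53.8, 61.4, 65.9, 85.7),
    mt_no_stop_mean = c(473.8, 468.9, 664.2, 625.1, 634.9, 636.1, 443.8),
    mt_no_stop_sd   = c(163.0, 128.8, 202.6, 219.7, 175.8, 220.7, 129.9),
    mt_go_only_mean = c(539.8, 539.5, 699.6, 634.7, 646.2, 659.7, 509.7),
    mt_go_only_sd   = c(216.4, 169.9, 207.6, 230.4, 141.4, 219.3, 152.2),
    acc_no_stop = c(0.88, 0.87, 0.87, 0.86, 0.84, 0.82, 0.89),
    acc_go_only = c(0.90, 0.89, 0.90, 0.87, 0.86, 0.81, 0.91),
    stringsAsFactors = FALSE
  )
}

preset_row <- function(presets, group, treatment) {
  i <- which(presets$group == group & presets$treatment == treatment)
  if (length(i) != 1L) {
    stop("no preset for group '", group, "', treatment '", treatment, "'")
  }
  presets[i, , drop = FALSE]
}
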