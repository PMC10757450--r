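# Shared fixtures: all data are generated in code at test time.

# A small cohort configuration that keeps simulation-based tests fast.
small_config <- function(seed = 1, ...) {
  cohort_config(n_per_group = 2, n_hc = 2, n_go_only_trials = 12,
                n_sst_trials = 24, block_size = 24, seed = seed, ...)
}

# Deterministic participant at the population mean of a preset cell.
mean_participant <- function(config, group, treatment) {
  row <- cohort_presets()
  row <- row[row$group == group & row$treatment == treatment, ]
  stopsignal:::params_from_preset(config, row, z = rep(0, 5))
}

# Estimate one session's SSRT the way the pipeline does.
session_ssrt <- function(d, config = cohort_config()) {
  d <- apply_rt_limit(d, config$rt_limit, config$rt_grace)
  go <- d$rt[d$trial_type == "no_stop" &
               d$outcome %in% c("correct", "overtime_reaching")]
  n_om <- sum(d$trial_type == "no_stop" & d$outcome == "aborted_over_900")
  ss <- stop_summaries(d[d$trial_type == "stop", ])
  estimate_ssrt_integration(c(go, rep(NA_real_, n_om)),
                            ss$p_failure, ss$mean_ssd, ss$n_stop)
}

# Hand-built single-session trial table from explicit RT/MT vectors.
manual_session <- function(rt_go, rt_ns, mt_go = NULL, mt_ns = NULL,
                           id = "p1", group = "HC", treatment = "NA") {
  mt_go <- mt_go %||% rep(500, length(rt_go))
  mt_ns <- mt_ns %||% rep(500, length(rt_ns))
  rbind(
    data.frame(participant_id = id, group = group, treatment = treatment,
               task = "go_only", trial_type = "go_only",
               block = 1L, trial = seq_along(rt_go), ssd = NA_real_,
               rt = rt_go, mt = mt_go, outcome = "correct",
               stringsAsFactors = FALSE),
    data.frame(participant_id = id, group = group, treatment = treatment,
               task = "sst", trial_type = "no_stop",
               block = 1L, trial = seq_along(rt_ns), ssd = NA_real_,
               rt = rt_ns, mt = mt_ns, outcome = "correct",
               stringsAsFactors = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
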