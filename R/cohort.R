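#' Configuration of the synthetic stop-signal cohort
#'
#' Bundles every tunable of the race-model cohort simulator: the group-level
#' presets (see [cohort_presets()]), sample sizes, trial counts, the staircase
#' geometry and the reaction-time limit. Defaults reproduce the emulated study
#' design: 20 patients per Hoehn-and-Yahr group tested ON and OFF medication,
#' 30 healthy controls tested once, a go-only block of 100 trials, and a
#' stop-signal task of 480 trials in blocks of 120 with exactly one third stop
#' trials.
#'
#' Within-participant trial-level variability is not identified by group-level
#' summaries and is therefore a free generator parameter: go finishing times
#' are ex-Gaussian with within-participant `go_sigma` and `go_tau`, movement
#' times Gaussian with `mt_sigma`. Between-participant spread comes from the
#' preset SDs. `within_subject_rho` is the correlation of a participant's
#' random effects across the ON and OFF sessions.
#'
#' @param presets Preset table, one row per (group, treatment) cell.
#' @param n_per_group Patients per H&Y group.
#' @param n_hc Healthy controls (single session).
#' @param n_go_only_trials Trials in the go-only task.
#' @param n_sst_trials Trials in the stop-signal task (multiple of 3).
#' @param block_size Target stop-signal task block length.
#' @param stop_proportion Proportion of stop trials within each block; fixed
#'   at 1/3 by the design.
#' @param refresh Display refresh period, ms.
#' @param ssd_init Initial stop-signal delay (9 refresh periods), ms.
#' @param ssd_step Staircase step (3 refresh periods), ms.
#' @param rt_limit No-stop reaction-time limit, ms.
#' @param rt_grace Grace period beyond the limit during which responses are
#'   still recorded ("overtime" reaches), ms.
#' @param within_subject_rho Correlation of participant random effects across
#'   ON/OFF sessions, in [0, 1].
#' @param go_sigma,go_tau Within-participant ex-Gaussian RT parameters, ms.
#' @param mt_sigma Within-participant movement-time SD, ms.
#' @param seed Integer seed; [simulate_study()] is deterministic given it.
#' @return A list of class `"cohort_config"`.
#' @examples
#' cfg <- cohort_config(n_per_group = 2, n_hc = 2, n_sst_trials = 48, seed = 1)
#' @export
cohort_config <- function(presets = cohort_presets(),
                          n_per_group = 20,
                          n_hc = 30,
                          n_go_only_trials = 100,
                          n_sst_trials = 480,
                          block_size = 120,
                          stop_proportion = 1 / 3,
                          refresh = 13.3,
                          ssd_init = 9 * refresh,
                          ssd_step = 3 * refresh,
                          rt_limit = 800,
                          rt_grace = 100,
                          within_subject_rho = 0.7,
                          go_sigma = 40,
                          go_tau = 80,
                          mt_sigma = 60,
                          seed = 1L) {
  stopifnot(
    is.data.frame(presets), n_per_group >= 1, n_hc >= 0,
    n_go_only_trials >= 1, n_sst_trials >= 3, block_size >= 3,
    rt_limit > 0, rt_grace >= 0,
    within_subject_rho >= 0, within_subject_rho <= 1,
    go_sigma >= 0, go_tau >= 0, mt_sigma >= 0
  )
  if (abs(stop_proportion - 1 / 3) > 1e-12) {
    stop("the design fixes `stop_proportion` at 1/3")
  }
  if (n_sst_trials %% 3 != 0) stop("`n_sst_trials` must be a multiple of 3")
  if (abs(ssd_init - 9 * refresh) > 1e-9 || abs(ssd_step - 3 * refresh) > 1e-9) {
    stop("staircase must start at 9 refresh periods and step by 3")
  }
  structure(
    list(presets = presets, n_per_group = n_per_group, n_hc = n_hc,
         n_go_only_trials = n_go_only_trials, n_sst_trials = n_sst_trials,
         block_size = block_size, stop_proportion = stop_proportion,
         refresh = refresh, ssd_init = ssd_init, ssd_step = ssd_step,
         rt_limit = rt_limit, rt_grace = rt_grace,
         within_subject_rho = within_subject_rho,
         go_sigma = go_sigma, go_tau = go_tau, mt_sigma = mt_sigma,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Map one preset row + latent standard-normal effects to participant-level
# generative parameters. z is length 3, one latent trait each for response
# speed, stop latency and movement speed. A trait is shared by the two task
# contexts, so a participant's context deltas (proactive slowing of RTs,
# shortening of MTs) are carried by the preset mean differences rather than
# by independent draws; for MTs the two cells also share the averaged
# between-participant SD, making the MT context delta exactly the preset
# delta. Latencies are floored well above zero.
params_from_preset <- function(config, row, z) {
  lapse_ns <- max(0, 1 - row$acc_no_stop)
  lapse_go <- max(0, 1 - row$acc_go_only)
  sd_mt <- (row$mt_no_stop_sd + row$mt_go_only_sd) / 2
  structure(
    list(
      group = row$group,
      treatment = row$treatment,
      go_mu_sst = max(50, row$rt_no_stop_mean - config$go_tau +
                        row$rt_no_stop_sd * z[1]),
      go_mu_go_only = max(50, row$rt_go_only_mean - config$go_tau +
                            row$rt_go_only_sd * z[1]),
      go_sigma = config$go_sigma,
      go_tau = config$go_tau,
      ssrt_true = max(80, row$ssrt_mean + row$ssrt_sd * z[2]),
      mt_mu_no_stop = max(50, row$mt_no_stop_mean + sd_mt * z[3]),
      mt_mu_go_only = max(50, row$mt_go_only_mean + sd_mt * z[3]),
      mt_sigma = config$mt_sigma,
      lapse_miss_no_stop = min(0.2, 0.6 * lapse_ns),
      lapse_hold_no_stop = min(0.2, 0.4 * lapse_ns),
      lapse_miss_go_only = min(0.2, 0.6 * lapse_go),
      lapse_hold_go_only = min(0.2, 0.4 * lapse_go)
    ),
    class = "participant_params"
  )
}

#' Draw participant-level generative parameters
#'
#' Samples one participant's race-model parameters from the population preset
#' of a (group, treatment) cell. Three latent traits -- response speed, stop
#' latency, movement speed -- are drawn as standard normals and scaled by the
#' preset between-participant SDs around the preset means, truncated to
#' plausible positive values. Each trait is shared by the two task contexts,
#' so a participant's proactive-slowing and movement-time context deltas come
#' from the preset mean differences, not from independent draws. The
#' ex-Gaussian mean offset `go_tau` is subtracted from the preset RT means so
#' that the participant's *expected observed* mean RT matches the preset.
#'
#' For patients tested in both medication states use
#' [sample_participant_pair()], which draws the ON and OFF parameter sets with
#' latent random effects correlated at `within_subject_rho` (rho = 1 gives
#' identical effects, rho = 0 independent ones).
#'
#' @param config A [cohort_config()].
#' @param group,treatment Cell labels present in `config$presets`.
#' @param z_common Optional length-3 standard-normal vector of shared latent
#'   traits (used internally for ON/OFF pairing).
#' @return A list of class `"participant_params"`.
#' @export
sample_participant <- function(config, group, treatment, z_common = NULL) {
  row <- preset_row(config$presets, group, treatment)
  rho <- config$within_subject_rho
  z_own <- stats::rnorm(3)
  z <- if (is.null(z_common)) z_own else
    sqrt(rho) * z_common + sqrt(1 - rho) * z_own
  params_from_preset(config, row, z)
}

#' @rdname sample_participant
#' @return `sample_participant_pair` returns a list with elements `OFF` and
#'   `ON`, the two correlated parameter sets of one patient.
#' @export
sample_participant_pair <- function(config, group) {
  z_common <- stats::rnorm(3)
  list(OFF = sample_participant(config, group, "OFF", z_common),
       ON  = sample_participant(config, group, "ON", z_common))
}

# Assign outcome labels for reaching trials given drawn RTs and lapse rates.
# Precedence: >900 ms aborts; then lapses; then the RT-limit overtime rule.
label_reach_trials <- function(rt, mt, lapse_miss, lapse_hold, config) {
  n <- length(rt)
  hard_limit <- config$rt_limit + config$rt_grace
  outcome <- rep("correct", n)
  u <- stats::runif(n)
  outcome[u < lapse_miss] <- "target_miss"
  outcome[u >= lapse_miss & u < lapse_miss + lapse_hold] <- "hold_violation"
  over <- rt > config$rt_limit & rt <= hard_limit & outcome == "correct"
  outcome[over] <- "overtime_reaching"
  aborted <- rt > hard_limit
  outcome[aborted] <- "aborted_over_900"
  rt[aborted] <- NA_real_
  mt[aborted] <- NA_real_
  data.frame(rt = rt, mt = mt, outcome = outcome, stringsAsFactors = FALSE)
}

#' Simulate a go-only session
#'
#' Draws `n` reaching trials for one participant: reaction times from the
#' participant's go-only ex-Gaussian, movement times from the go-only
#' Gaussian, with target-miss and hold-violation lapses injected i.i.d. at the
#' participant's rates. Responses beyond the limit-plus-grace window are
#' aborted (no RT recorded).
#'
#' @param params A `"participant_params"` object.
#' @param n Number of trials.
#' @param config A [cohort_config()].
#' @return A trial data frame (task `"go_only"`).
#' @export
simulate_go_only <- function(params, n, config = cohort_config()) {
  if (!is.numeric(n) || n <= 0) stop("`n` must be a positive trial count")
  n <- as.integer(n)
  rt <- rexgauss(n, params$go_mu_go_only, params$go_sigma, params$go_tau)
  mt <- rtnorm_lower(n, params$mt_mu_go_only, params$mt_sigma, lower = 1)
  lab <- label_reach_trials(rt, mt, params$lapse_miss_go_only,
                            params$lapse_hold_go_only, config)
  data.frame(
    task = "go_only", trial_type = "go_only", block = 1L, trial = seq_len(n),
    ssd = NA_real_, rt = lab$rt, mt = lab$mt, outcome = lab$outcome,
    stringsAsFactors = FALSE
  )
}

# Split n trials into blocks close to block_size, each a multiple of 3 so the
# exact 1/3 stop proportion holds per block.
block_sizes <- function(n, block_size) {
  n3 <- n / 3
  b3 <- max(1, round(block_size / 3))
  k <- max(1L, round(n3 / b3))
  per <- diff(round(seq(0, n3, length.out = k + 1))) * 3
  per[per > 0]
}

#' Simulate a stop-signal session
#'
#' Simulates one participant's stop-signal task under the independent
#' horse-race model. Trials come in blocks with exactly one third stop trials
#' at random positions. Every trial draws a go finishing time from the
#' participant's SST-context ex-Gaussian. On a stop trial presented at the
#' current staircase SSD the response escapes inhibition if the go process
#' finishes before `ssd + ssrt_true` (a stop failure whose RT is the go
#' finishing time); otherwise the stop wins (no RT). The staircase is updated
#' after every stop trial and runs continuously across blocks. No-stop trials
#' follow the RT-limit rule: RTs within the 100 ms grace window are kept as
#' overtime reaches, later responses abort.
#'
#' @param params A `"participant_params"` object.
#' @param config A [cohort_config()].
#' @param n_trials Optional override of `config$n_sst_trials`.
#' @return A trial data frame (task `"sst"`) in presentation order.
#' @export
simulate_sst <- function(params, config = cohort_config(), n_trials = NULL) {
  n <- as.integer(n_trials %||% config$n_sst_trials)
  if (n < 3 || n %% 3 != 0) stop("stop-signal trial count must be a positive multiple of 3")
  sizes <- block_sizes(n, config$block_size)
  block <- rep(seq_along(sizes), sizes)
  is_stop <- logical(n)
  offset <- 0L
  for (b in seq_along(sizes)) {
    nb <- sizes[b]
    is_stop[offset + sample.int(nb, nb / 3)] <- TRUE
    offset <- offset + nb
  }
  t_go <- rexgauss(n, params$go_mu_sst, params$go_sigma, params$go_tau)
  mt_all <- rtnorm_lower(n, params$mt_mu_no_stop, params$mt_sigma, lower = 1)

  rt <- rep(NA_real_, n); mt <- rep(NA_real_, n)
  ssd <- rep(NA_real_, n); outcome <- character(n)

  ns <- which(!is_stop)
  lab <- label_reach_trials(t_go[ns], mt_all[ns], params$lapse_miss_no_stop,
                            params$lapse_hold_no_stop, config)
  rt[ns] <- lab$rt; mt[ns] <- lab$mt; outcome[ns] <- lab$outcome

  hard_limit <- config$rt_limit + config$rt_grace
  st <- staircase_init(config$ssd_init, config$ssd_step)
  for (i in which(is_stop)) {
    ssd[i] <- st$current_ssd
    escaped <- t_go[i] < st$current_ssd + params$ssrt_true && t_go[i] <= hard_limit
    if (escaped) {
      outcome[i] <- "stop_failure"
      rt[i] <- t_go[i]
      mt[i] <- mt_all[i]
    } else {
      outcome[i] <- "stop_success"
    }
    st <- staircase_update(st, outcome[i])
  }

  data.frame(
    task = "sst",
    trial_type = ifelse(is_stop, "stop", "no_stop"),
    block = block, trial = seq_len(n),
    ssd = ssd, rt = rt, mt = mt, outcome = outcome,
    stringsAsFactors = FALSE
  )
}

#' Simulate the whole cohort
#'
#' Generates the full long-format trial table for the study design: each
#' patient group tested in counterbalanced ON and OFF sessions (session order
#' alternating across participants), healthy controls in a single session;
#' every session comprises a go-only task and a stop-signal task. Each
#' participant's ON and OFF parameter sets share correlated random effects
#' (see [sample_participant_pair()]). The result is deterministic given
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A long-format data frame, one row per trial, with columns
#'   `participant_id`, `group`, `treatment`, `session_order`, `task`,
#'   `trial_type`, `block`, `trial`, `ssd`, `rt`, `mt`, `outcome`.
#' @examples
#' cfg <- cohort_config(n_per_group = 1, n_hc = 1, n_go_only_trials = 10,
#'                      n_sst_trials = 12, seed = 7)
#' trials <- simulate_study(cfg)
#' table(trials$group, trials$trial_type)
#' @export
simulate_study <- function(config = cohort_config()) {
  set.seed(config$seed)
  groups <- setdiff(unique(config$presets$group), "HC")
  plan <- list()
  for (g in groups) {
    for (p in seq_len(config$n_per_group)) {
      plan[[length(plan) + 1L]] <- list(group = g, idx = p, patient = TRUE)
    }
  }
  if (config$n_hc > 0 && "HC" %in% config$presets$group) {
    for (p in seq_len(config$n_hc)) {
      plan[[length(plan) + 1L]] <- list(group = "HC", idx = p, patient = FALSE)
    }
  }
  part_seeds <- sample.int(.Machine$integer.max - 1L, length(plan))

  one_session <- function(params, config) {
    go <- simulate_go_only(params, config$n_go_only_trials, config)
    sst <- simulate_sst(params, config)
    rbind(go, sst)
  }

  out <- vector("list", length(plan))
  for (k in seq_along(plan)) {
    set.seed(part_seeds[k])
    info <- plan[[k]]
    id <- sprintf("%s_%02d", gsub("&", "", info$group, fixed = TRUE), info$idx)
    if (info$patient) {
      pair <- sample_participant_pair(config, info$group)
      order_first <- if (info$idx %% 2 == 1) "ON" else "OFF"
      sess_order <- c(order_first, setdiff(c("ON", "OFF"), order_first))
      sess <- lapply(sess_order, function(tr) {
        d <- one_session(pair[[tr]], config)
        d$treatment <- tr
        d
      })
      d <- do.call(rbind, sess)
      d$session_order <- paste0(order_first, "_first")
    } else {
      params <- sample_participant(config, "HC", "NA")
      d <- one_session(params, config)
      d$treatment <- "NA"
      d$session_order <- "single"
    }
    d$participant_id <- id
    d$group <- info$group
    out[[k]] <- d
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("participant_id", "group", "treatment", "session_order",
          "task", "trial_type", "block", "trial", "ssd", "rt", "mt", "outcome")]
}

#' Read and write trial tables
#'
#' Trial tables are exchanged as tab-separated text with a header row and
#' missing values written as `NA`. `read_trials` restores the `"NA"` treatment
#' label of single-session (control) participants.
#'
#' @param trials A trial data frame as produced by [simulate_study()].
#' @param path File path.
#' @return `read_trials` returns the trial data frame.
#' @export
write_trials <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("treatment" %in% names(d)) d$treatment[is.na(d$treatment)] <- "NA"
  d
}
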