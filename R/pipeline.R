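# End-to-end orchestration: simulate -> preprocess -> reactive -> proactive
# -> statistics, with a diffable CSV/JSON report bundle.

# Table-2-shaped behavioural summary: mean +/- SD of each behavioural
# parameter per group x treatment cell.
behavioural_summary <- function(pp, reactive_tab) {
  cc <- context_cell_means(pp$trials)
  sf <- pp$trials[pp$trials$outcome == "stop_failure" & !is.na(pp$trials$rt), ]
  sf_means <- stats::aggregate(sf$rt,
                               list(participant_id = sf$participant_id,
                                    treatment = sf$treatment), mean)
  names(sf_means)[3] <- "rt_stop_failure"
  per <- merge(reactive_tab, cc, by = c("participant_id", "group", "treatment"))
  per <- merge(per, sf_means, by = c("participant_id", "treatment"), all.x = TRUE)
  acc <- pp$accuracy
  acc_w <- stats::reshape(acc, idvar = c("participant_id", "group", "treatment"),
                          timevar = "task", direction = "wide")
  names(acc_w) <- sub("accuracy.go_only", "acc_go_only",
                      sub("accuracy.sst", "acc_no_stop", names(acc_w)))
  per <- merge(per, acc_w, by = c("participant_id", "group", "treatment"),
               all.x = TRUE)
  vars <- c("ssrt", "p_failure", "mean_ssd", "rt_no_stop", "mt_no_stop",
            "rt_stop_failure", "rt_go_only", "mt_go_only",
            "acc_no_stop", "acc_go_only")
  cells <- split(per, interaction(per$group, per$treatment, drop = TRUE))
  rows <- lapply(cells, function(d) {
    out <- data.frame(group = d$group[1], treatment = d$treatment[1],
                      n = nrow(d), stringsAsFactors = FALSE)
    for (v in vars) {
      out[[paste0(v, "_mean")]] <- mean(d[[v]], na.rm = TRUE)
      out[[paste0(v, "_sd")]] <- stats::sd(d[[v]], na.rm = TRUE)
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# Long format for the RT/MT trial-type ANOVAs.
cells_long <- function(cc, measure) {
  lng <- rbind(
    data.frame(participant_id = cc$participant_id, group = cc$group,
               treatment = cc$treatment, trial_type = "no_stop",
               value = cc[[paste0(measure, "_no_stop")]],
               stringsAsFactors = FALSE),
    data.frame(participant_id = cc$participant_id, group = cc$group,
               treatment = cc$treatment, trial_type = "go_only",
               value = cc[[paste0(measure, "_go_only")]],
               stringsAsFactors = FALSE)
  )
  names(lng)[names(lng) == "value"] <- measure
  lng
}

# 2 x 2 context-present/absent table for HC vs one patient group.
present_absent <- function(categories, group, treatment) {
  sel <- categories[(categories$group == group & categories$treatment == treatment) |
                      categories$group == "HC", ]
  sel$present <- sel$category == "context"
  tab <- table(factor(sel$group, levels = c("HC", group)),
               factor(ifelse(sel$present, "present", "absent"),
                      levels = c("present", "absent")))
  as.matrix(tab)
}

#' Run the full analysis pipeline
#'
#' Simulates (or takes) a trial table and produces the complete report
#' bundle: behavioural summary per cell, SSRT mixed ANOVA with post hocs,
#' RT and MT trial-type ANOVAs with post hocs, individual context-effect
#' classification with frequency tables and the chi-square family,
#' population-level context verdicts, race-model check report and trim
#' report. Deterministic given `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param trials Optional trial table; simulated from `config` when `NULL`.
#' @param outdir Optional directory: when given, every table is written as
#'   CSV plus a JSON run manifest.
#' @param alpha Significance level for the KS-based classifications.
#' @return A list with elements `behavioural_summary`, `reactive`,
#'   `ssrt_anova`, `ssrt_posthoc_group`, `ssrt_posthoc_treatment`,
#'   `rt_anova`, `mt_anova`, `rt_posthoc_trial_type`, `categories`,
#'   `frequencies`, `chi2_homogeneity`, `chi2_hc_vs_groups`,
#'   `population_context`, `trim_report`, `accuracy`, `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(), trials = NULL,
                         outdir = NULL, alpha = 0.05) {
  if (is.null(trials)) trials <- simulate_study(config)
  pp <- preprocess_trials(trials)
  re <- reactive_summaries(pp$trials)

  pat <- re[re$treatment %in% c("ON", "OFF"), ]
  # keep only patients with a defined SSRT in both sessions (complete pairs)
  ok <- tapply(!is.na(pat$ssrt), pat$participant_id, all)
  pat <- pat[pat$participant_id %in% names(ok)[ok], ]
  ssrt_anova <- mixed_anova(pat, "ssrt", between = "group", within = "treatment")
  ssrt_ph_group <- posthoc_pairwise(ssrt_anova, "group")
  ssrt_ph_treat <- posthoc_pairwise(ssrt_anova, "treatment", by = "group")

  cc <- context_cell_means(pp$trials)
  ccp <- cc[cc$treatment %in% c("ON", "OFF"), ]
  rt_long <- cells_long(ccp, "rt")
  mt_long <- cells_long(ccp, "mt")
  rt_anova <- mixed_anova(rt_long, "rt", between = "group",
                          within = c("treatment", "trial_type"))
  mt_anova <- mixed_anova(mt_long, "mt", between = "group",
                          within = c("treatment", "trial_type"))
  rt_ph_tt <- posthoc_pairwise(rt_anova, "trial_type", by = "group")

  categories <- classify_all_sessions(pp$trials, alpha = alpha)
  freqs <- context_frequencies(categories)

  chi_hom <- list()
  for (tr in c("OFF", "ON")) {
    sel <- categories[categories$treatment == tr | categories$group == "HC", ]
    tab <- table(factor(sel$group),
                 factor(ifelse(sel$category == "context", "present", "absent"),
                        levels = c("present", "absent")))
    chi_hom[[tr]] <- tryCatch(chi2_homogeneity(as.matrix(tab)),
                              error = function(e) NULL)
  }

  chi_hc <- list()
  pat_groups <- setdiff(unique(categories$group), "HC")
  if ("HC" %in% categories$group) {
    for (tr in c("OFF", "ON")) {
      for (g in pat_groups) {
        tab <- present_absent(categories, g, tr)
        key <- paste0("HC_vs_", gsub("&", "", g, fixed = TRUE), "_", tr)
        chi_hc[[key]] <- tryCatch(chi2_independence_ncorr(tab),
                                  error = function(e) NULL)
      }
    }
  }

  pop_ctx <- list()
  cells <- unique(pp$trials[, c("group", "treatment")])
  for (i in seq_len(nrow(cells))) {
    sel <- pp$trials[pp$trials$group == cells$group[i] &
                       pp$trials$treatment == cells$treatment[i], ]
    key <- paste0(gsub("&", "", cells$group[i], fixed = TRUE), "_",
                  cells$treatment[i])
    pop_ctx[[key]] <- tryCatch(
      population_context_test(sel, alpha = alpha)[c("rt_verdict", "mt_verdict", "overall")],
      error = function(e) NULL)
  }

  manifest <- list(
    package = "stopsignal",
    version = as.character(utils::packageVersion("stopsignal")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    n_per_group = config$n_per_group, n_hc = config$n_hc,
    n_go_only_trials = config$n_go_only_trials,
    n_sst_trials = config$n_sst_trials,
    alpha = alpha
  )

  res <- list(
    behavioural_summary = behavioural_summary(pp, re),
    reactive = re,
    ssrt_anova = ssrt_anova,
    ssrt_posthoc_group = ssrt_ph_group,
    ssrt_posthoc_treatment = ssrt_ph_treat,
    rt_anova = rt_anova, mt_anova = mt_anova,
    rt_posthoc_trial_type = rt_ph_tt,
    categories = categories, frequencies = freqs,
    chi2_homogeneity = chi_hom, chi2_hc_vs_groups = chi_hc,
    population_context = pop_ctx,
    trim_report = pp$trim_report, accuracy = pp$accuracy,
    manifest = manifest
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, name) utils::write.csv(x, file.path(outdir, paste0(name, ".csv")),
                                             row.names = FALSE)
    wr(res$behavioural_summary, "behavioural_summary")
    wr(res$reactive, "reactive_summaries")
    wr(res$ssrt_anova$table, "ssrt_anova")
    wr(rbind(res$ssrt_posthoc_group, res$ssrt_posthoc_treatment), "ssrt_posthocs")
    wr(res$rt_anova$table, "rt_anova")
    wr(res$mt_anova$table, "mt_anova")
    wr(res$rt_posthoc_trial_type, "rt_posthocs")
    wr(res$categories, "context_categories")
    wr(res$frequencies, "context_frequencies")
    wr(res$trim_report, "trim_report")
    wr(res$accuracy, "accuracy")
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}
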