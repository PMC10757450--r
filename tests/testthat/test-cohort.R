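test_that("participant sampling honours the ON/OFF random-effect correlation", {
  cfg <- cohort_config(within_subject_rho = 1)
  set.seed(1)
  pair <- sample_participant_pair(cfg, "H&Y1")
  pres <- cohort_presets()
  off <- pres[pres$group == "H&Y1" & pres$treatment == "OFF", ]
  on <- pres[pres$group == "H&Y1" & pres$treatment == "ON", ]
  # rho = 1: the standardized latent effect is identical across sessions
  z_off <- (pair$OFF$ssrt_true - off$ssrt_mean) / off$ssrt_sd
  z_on <- (pair$ON$ssrt_true - on$ssrt_mean) / on$ssrt_sd
  expect_equal(z_off, z_on, tolerance = 1e-12)

  cfg0 <- cohort_config(within_subject_rho = 0)
  set.seed(2)
  zs <- replicate(1e4, {
    pr <- sample_participant_pair(cfg0, "H&Y1")
    c((pr$OFF$ssrt_true - off$ssrt_mean) / off$ssrt_sd,
      (pr$ON$ssrt_true - on$ssrt_mean) / on$ssrt_sd)
  })
  expect_lt(abs(cor(zs[1, ], zs[2, ])), 0.05)
})

test_that("unknown presets are rejected", {
  cfg <- cohort_config()
  expect_error(sample_participant(cfg, "H&Y9", "ON"), "no preset")
})

test_that("population mean of the stop latency matches the HC preset", {
  cfg <- cohort_config()
  set.seed(3)
  draws <- replicate(4000, sample_participant(cfg, "HC", "NA")$ssrt_true)
  expect_equal(mean(draws), 221.9, tolerance = 2 / 221.9)
})

test_that("go-only simulation reproduces the preset mean RT and lapse rates", {
  cfg <- cohort_config()
  p <- mean_participant(cfg, "HC", "NA")
  p$lapse_miss_go_only <- 0; p$lapse_hold_go_only <- 0
  set.seed(4)
  d <- simulate_go_only(p, 1e4, cfg)
  expect_equal(mean(d$rt, na.rm = TRUE), 306.5, tolerance = 3 / 306.5)
  expect_true(all(d$outcome %in% c("correct", "overtime_reaching",
                                   "aborted_over_900")))

  # degenerate spread: every RT equals the location parameter
  cfg0 <- cohort_config(go_sigma = 0, go_tau = 0)
  p0 <- mean_participant(cfg0, "HC", "NA")
  d0 <- simulate_go_only(p0, 50, cfg0)
  expect_true(all(abs(d0$rt - p0$go_mu_go_only) < 1e-9))

  # binomial lapse check
  p$lapse_miss_go_only <- 0.1
  set.seed(5)
  d1 <- simulate_go_only(p, 1e4, cfg)
  expect_equal(mean(d1$outcome == "target_miss"), 0.1, tolerance = 0.01 / 0.1)
  expect_error(simulate_go_only(p, 0), "positive")
})

test_that("the race in the stop-signal task behaves as constructed", {
  cfg <- cohort_config()
  p <- mean_participant(cfg, "HC", "NA")
  p$lapse_miss_no_stop <- 0; p$lapse_hold_no_stop <- 0
  set.seed(6)
  d <- simulate_sst(p, cfg, n_trials = 9999)  # 3333 stop trials
  stops <- d[d$trial_type == "stop", ]
  expect_true(all(!is.na(stops$ssd)))
  expect_true(all(is.na(d$ssd[d$trial_type == "no_stop"])))
  # staircase keeps failures near 50%
  expect_lt(abs(mean(stops$outcome == "stop_failure") - 0.5), 0.05)
  # censoring property of the race: failures are fast go processes
  sf <- d$rt[d$outcome == "stop_failure"]
  ns <- d$rt[d$trial_type == "no_stop" &
               d$outcome %in% c("correct", "overtime_reaching")]
  expect_lt(mean(sf), mean(ns))

  # an unbeatable go process: stop never wins
  p_inf <- p; p_inf$ssrt_true <- Inf
  set.seed(7)
  d_inf <- simulate_sst(p_inf, cfg, n_trials = 300)
  expect_true(all(d_inf$outcome[d_inf$trial_type == "stop"] == "stop_failure"))
})

test_that("staircase converges and mean SSD tracks the go median minus SSRT", {
  cfg <- cohort_config()
  p <- mean_participant(cfg, "HC", "NA")
  set.seed(8)
  d <- simulate_sst(p, cfg, n_trials = 30000)  # 1e4 stop trials
  stops <- d[d$trial_type == "stop", ]
  second_half <- stops[seq(nrow(stops) / 2 + 1, nrow(stops)), ]
  expect_lt(abs(mean(second_half$outcome == "stop_failure") - 0.5), 0.05)
  # independent oracle for the go median: direct Monte Carlo quantile
  med_go <- median(stopsignal:::rexgauss(1e6, p$go_mu_sst, p$go_sigma, p$go_tau))
  expect_lt(abs(mean(second_half$ssd) - (med_go - p$ssrt_true)), 15)
})

test_that("whole-cohort simulation is deterministic with the right shape", {
  cfg <- small_config(seed = 99)
  t1 <- simulate_study(cfg)
  t2 <- simulate_study(cfg)
  expect_identical(t1, t2)
  expect_setequal(unique(t1$group), c("H&Y1", "H&Y2", "H&Y3", "HC"))
  # patients have two sessions, controls one
  sess <- unique(t1[, c("participant_id", "group", "treatment")])
  n_sess <- table(sess$group)
  expect_equal(as.integer(n_sess[c("H&Y1", "H&Y2", "H&Y3")]), rep(4L, 3)) # 2 x 2
  expect_equal(as.integer(n_sess["HC"]), 2L)
  # exact stop proportion within each session
  sst <- t1[t1$task == "sst", ]
  by_sess <- split(sst, interaction(sst$participant_id, sst$treatment, drop = TRUE))
  for (d in by_sess) expect_equal(mean(d$trial_type == "stop"), 1 / 3)
  # round-trip through the TSV representation
  f <- tempfile(fileext = ".tsv")
  write_trials(t1, f)
  t3 <- read_trials(f)
  expect_equal(t3$rt, t1$rt)
  expect_identical(t3$treatment, t1$treatment)
})

test_that("simulated per-cell grand means are unbiased for the presets", {
  cfg <- cohort_config(seed = 10)
  pres <- cohort_presets()
  n_rep <- 6
  accum <- NULL
  for (r in seq_len(n_rep)) {
    cfg_r <- cohort_config(seed = 10 + r)
    tr <- simulate_study(cfg_r)
    pp <- preprocess_trials(tr)
    cc <- context_cell_means(pp$trials)
    agg <- aggregate(cc[, c("rt_no_stop", "rt_go_only", "mt_no_stop", "mt_go_only")],
                     list(group = cc$group, treatment = cc$treatment), mean)
    accum <- if (is.null(accum)) agg else
      within(merge(accum, agg, by = c("group", "treatment")), {
        rt_no_stop <- rt_no_stop.x + rt_no_stop.y
        rt_go_only <- rt_go_only.x + rt_go_only.y
        mt_no_stop <- mt_no_stop.x + mt_no_stop.y
        mt_go_only <- mt_go_only.x + mt_go_only.y
      })[, c("group", "treatment", "rt_no_stop", "rt_go_only",
             "mt_no_stop", "mt_go_only")]
  }
  accum[, 3:6] <- accum[, 3:6] / n_rep
  for (i in seq_len(nrow(pres))) {
    row <- pres[i, ]
    got <- accum[accum$group == row$group & accum$treatment == row$treatment, ]
    n_cell <- if (row$group == "HC") cfg$n_hc else cfg$n_per_group
    expect_lt(abs(got$rt_no_stop - row$rt_no_stop_mean),
              2 * row$rt_no_stop_sd / sqrt(n_cell))
    expect_lt(abs(got$rt_go_only - row$rt_go_only_mean),
              2 * row$rt_go_only_sd / sqrt(n_cell))
    expect_lt(abs(got$mt_no_stop - row$mt_no_stop_mean),
              2 * row$mt_no_stop_sd / sqrt(n_cell))
    expect_lt(abs(got$mt_go_only - row$mt_go_only_mean),
              2 * row$mt_go_only_sd / sqrt(n_cell))
  }
})
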