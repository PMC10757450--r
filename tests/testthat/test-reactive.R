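test_that("integration-method arithmetic follows the rank definition", {
  est <- estimate_ssrt_integration(c(300, 400, 500, 600, 700),
                                   p_failure = 0.4, mean_ssd = 150)
  expect_equal(est$ssrt, 250)
  expect_equal(est$n_go, 5L)
  expect_error(estimate_ssrt_integration(c(300, 400), 0, 100), "strictly between")
  expect_error(estimate_ssrt_integration(c(300, 400), 1, 100), "strictly between")
  expect_error(estimate_ssrt_integration(numeric(0), 0.5, 100), "empty")
  # omissions are replaced by the maximum observed RT
  est_om <- estimate_ssrt_integration(c(300, 400, NA), p_failure = 0.99,
                                      mean_ssd = 100)
  expect_equal(est_om$ssrt, 400 - 100)
  expect_equal(est_om$n_omissions, 1L)
})

test_that("the SSRT estimate is monotone in the failure probability", {
  set.seed(1)
  rts <- round(rnorm(40, 500, 60))
  prev <- -Inf
  for (p in seq(0.05, 0.95, by = 0.05)) {
    cur <- estimate_ssrt_integration(rts, p, 200)$ssrt
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("rank selection matches a counting oracle on small inputs", {
  # oracle: smallest RT value v such that #(rt <= v) >= ceiling(p * N)
  brute_quantile <- function(rts, p) {
    target <- min(length(rts), max(1, ceiling(p * length(rts))))
    for (v in sort(rts)) if (sum(rts <= v) >= target) return(v)
  }
  set.seed(2)
  for (k in 1:25) {
    rts <- sample(200:900, sample(3:15, 1), replace = TRUE)
    p <- runif(1, 0.05, 0.95)
    est <- estimate_ssrt_integration(rts, p, 0)
    expect_equal(est$ssrt, brute_quantile(rts, p))
  }
})

test_that("stop summaries are plain proportions and means", {
  stops <- data.frame(ssd = c(119.7, 159.6),
                      outcome = c("stop_failure", "stop_success"))
  ss <- stop_summaries(stops)
  expect_equal(ss$p_failure, 0.5)
  expect_equal(ss$mean_ssd, 139.65)
  expect_error(stop_summaries(stops[0, ]), "no stop trials")
  expect_error(stop_summaries(data.frame(ssd = 1, outcome = "correct")),
               "stop outcomes")
})

test_that("integration method recovers a constant true SSRT within 10 ms", {
  cfg <- cohort_config()
  set.seed(3)
  for (true_ssrt in c(200, 250, 300)) {
    p <- mean_participant(cfg, "HC", "NA")
    p$ssrt_true <- true_ssrt
    ests <- replicate(40, {
      d <- simulate_sst(p, cfg, n_trials = 480)  # 160 stop trials
      session_ssrt(d, cfg)$ssrt
    })
    expect_lt(abs(mean(ests) - true_ssrt), 10)
  }
})

test_that("race-model checks flag constructed independence violations", {
  # race-model data: failures must be faster than no-stop responses
  cfg <- cohort_config()
  p <- mean_participant(cfg, "HC", "NA")
  set.seed(4)
  d <- simulate_sst(p, cfg, n_trials = 480)
  d$participant_id <- "p"; d$group <- "HC"; d$treatment <- "NA"
  chk <- check_race_assumptions(d)
  expect_true(chk$independence_ok)
  expect_true(chk$staircase_ok)

  # shift the stop-failure RTs far above the no-stop RTs
  d_bad <- d
  bad <- d_bad$outcome == "stop_failure"
  d_bad$rt[bad] <- d_bad$rt[bad] + 2000
  expect_false(check_race_assumptions(d_bad)$independence_ok)

  # no failed stops: the independence check is undefined, not false
  d_nf <- d[d$outcome != "stop_failure", ]
  expect_true(is.na(check_race_assumptions(d_nf)$independence_ok))
})

test_that("per-session summaries carry the reliability flag and checks", {
  cfg <- small_config(seed = 31)
  trials <- simulate_study(cfg)
  pp <- preprocess_trials(trials)
  re <- reactive_summaries(pp$trials)
  expect_equal(nrow(re), 3 * 2 * 2 + 2)  # patient sessions + HC
  expect_true(all(re$n_stop == cfg$n_sst_trials / 3))
  expect_true(all(!re$reliable))  # 8 stop trials < 50
  re_full <- reactive_summaries(
    preprocess_trials(simulate_study(
      cohort_config(n_per_group = 1, n_hc = 1, n_go_only_trials = 80,
                    n_sst_trials = 480, seed = 32)))$trials)
  expect_true(all(re_full$reliable))
  expect_true(all(re_full$independence_ok))
})
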