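test_that("cell means are exact arithmetic means per trial type", {
  d <- manual_session(rt_go = c(200, 300), rt_ns = c(500, 700),
                      mt_go = c(600, 650), mt_ns = c(400, 450))
  cc <- context_cell_means(d)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$rt_go_only, 250)
  expect_equal(cc$rt_no_stop, 600)
  expect_equal(cc$mt_go_only, 625)
  expect_equal(cc$mt_no_stop, 425)

  # identical trials in both contexts: zero difference everywhere
  d2 <- manual_session(rt_go = 1:10 * 50, rt_ns = 1:10 * 50,
                       mt_go = 1:10 * 40, mt_ns = 1:10 * 40)
  cc2 <- context_cell_means(d2)
  expect_equal(cc2$rt_no_stop - cc2$rt_go_only, 0)
  expect_equal(cc2$mt_no_stop - cc2$mt_go_only, 0)
})

test_that("population CDFs average participant ECDFs with equal weight", {
  d1 <- manual_session(rt_go = rep(1, 6), rt_ns = c(100, 110, 120, 130, 140, 150))
  pc1 <- build_population_cdf(d1, "rt", "no_stop")
  expect_equal(pc1$cdf, ecdf(c(100, 110, 120, 130, 140, 150))(pc1$grid))

  d2 <- manual_session(rt_go = rep(1, 6), rt_ns = c(200, 210, 220, 230, 240, 250),
                       id = "p2")
  pc <- build_population_cdf(rbind(d1, d2), "rt", "no_stop")
  expect_equal(pc$n_participants, 2L)
  # disjoint supports: the averaged CDF sits at 0.5 between them
  expect_equal(pc$cdf[pc$grid == 150], 0.5)
  expect_equal(pc$cdf[length(pc$cdf)], 1)
  expect_true(all(diff(pc$cdf) >= 0))
  expect_error(build_population_cdf(d1[0, ], "rt", "no_stop"), "trials")
})

strong_effect_session <- function(n = 200, rt_delta = 150, mt_delta = -150,
                                  id = "p1") {
  manual_session(
    rt_go = rnorm(n, 300, 50), rt_ns = rnorm(n, 300 + rt_delta, 50),
    mt_go = rnorm(n, 550, 60), mt_ns = rnorm(n, 550 + mt_delta, 60),
    id = id
  )
}

test_that("individual classification recovers constructed regimes", {
  set.seed(1)
  # large opposed deltas: the canonical context effect
  ctx <- classify_individual_context(strong_effect_session())
  expect_equal(ctx$category, "context")

  # identical distributions: no evidence of any effect
  d_null <- manual_session(rt_go = rep(1:20 * 10, 5), rt_ns = rep(1:20 * 10, 5),
                           mt_go = rep(1:20 * 10, 5), mt_ns = rep(1:20 * 10, 5))
  expect_equal(classify_individual_context(d_null)$category, "no_context")

  # movement times slower under stop context: the inverse effect
  set.seed(2)
  inv <- classify_individual_context(
    strong_effect_session(mt_delta = +150))
  expect_equal(inv$category, "inverse_context")

  d_miss <- manual_session(rt_go = 1:10 * 50, rt_ns = 1:10 * 50)
  d_miss <- d_miss[d_miss$trial_type != "go_only", ]
  expect_error(classify_individual_context(d_miss), "lacks analysable")
})

test_that("swapping task labels flips the MT component to inverse", {
  set.seed(3)
  d <- strong_effect_session()
  expect_equal(classify_individual_context(d)$category, "context")
  d_sw <- d
  d_sw$trial_type <- ifelse(d$trial_type == "go_only", "no_stop", "go_only")
  d_sw$task <- ifelse(d$task == "go_only", "sst", "go_only")
  expect_equal(classify_individual_context(d_sw)$category, "inverse_context")
})

test_that("population-level verdicts follow the dual one-tailed logic", {
  set.seed(4)
  strong <- rbind(strong_effect_session(id = "p1"),
                  strong_effect_session(id = "p2"))
  v <- population_context_test(strong)
  expect_equal(v$rt_verdict, "effect")
  expect_equal(v$mt_verdict, "effect")
  expect_equal(v$overall, "context")

  # no MT difference: the MT pair of tests cannot both stay one-sided
  set.seed(5)
  flat <- rbind(strong_effect_session(mt_delta = 0, id = "p1"),
                strong_effect_session(mt_delta = 0, id = "p2"))
  v2 <- population_context_test(flat)
  expect_equal(v2$overall, "no_context")

  d_same <- manual_session(rt_go = rep(1:20 * 10, 5), rt_ns = rep(1:20 * 10, 5))
  v3 <- population_context_test(d_same)
  expect_equal(v3$overall, "no_context")
})

test_that("frequency tables count and percentage correctly", {
  cats <- data.frame(
    participant_id = sprintf("p%02d", 1:20), group = "H&Y1", treatment = "OFF",
    category = c(rep("context", 12), rep("no_context", 6),
                 rep("inverse_context", 2)),
    stringsAsFactors = FALSE
  )
  fr <- context_frequencies(cats)
  expect_equal(fr$n[fr$category == "context"], 12L)
  expect_equal(fr$percent[fr$category == "context"], 60)
  expect_equal(sum(fr$n), 20L)
  cats$category <- "context"
  fr2 <- context_frequencies(cats)
  expect_equal(fr2$percent[fr2$category == "context"], 100)
})
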