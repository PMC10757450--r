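test_that("a constant response gives zero F and zero effect size", {
  d <- random_design()
  d$y <- 5
  fit <- mixed_anova(d, "y", between = "g", within = "a")
  expect_true(all(fit$table$F == 0))
  expect_true(all(fit$table$partial_eta_sq == 0))
  expect_true(all(fit$table$p == 1))
})

test_that("split-plot sums of squares match the brute-force oracle exactly", {
  for (seed in 1:6) {
    nd <- if (seed %% 2 == 0) c(2, 2) else c(3, 4)  # groups, subjects/group
    d <- random_design(nd[1], nd[2], 2, seed = seed)
    fit <- mixed_anova(d, "y", between = "g", within = "a")
    o <- oracle_split_plot(data.frame(y = d$y, g = d$g, a = d$a,
                                      s = d$participant_id))
    tb <- fit$table
    expect_equal(tb$ss[tb$effect == "g"], unname(o$group), tolerance = 1e-10)
    expect_equal(tb$ss[tb$effect == "a"], unname(o$a), tolerance = 1e-10)
    expect_equal(tb$ss[tb$effect == "g:a"], unname(o$ga), tolerance = 1e-10)
    expect_equal(fit$error_ms[[1]]$ss, unname(o$subj_err), tolerance = 1e-10)
    expect_equal(fit$error_ms[[2]]$ss, unname(o$as_err), tolerance = 1e-10)
    # eta_p^2 definition against the oracle strata
    expect_equal(tb$partial_eta_sq[tb$effect == "g"],
                 o$group / (o$group + o$subj_err), tolerance = 1e-10)
  }
})

test_that("all strata sum to the total sum of squares", {
  for (seed in 1:4) {
    d <- random_design(3, 4, 2, seed = seed)
    d2 <- rbind(d, d)
    d2$b <- rep(c("b1", "b2"), each = nrow(d))
    set.seed(seed + 100)
    d2$y <- d2$y + rnorm(nrow(d2), 0, 1)
    fit <- mixed_anova(d2, "y", between = "g", within = c("a", "b"))
    ss_total <- sum((d2$y - mean(d2$y))^2)
    ss_sum <- sum(fit$table$ss) + sum(vapply(fit$error_ms, `[[`, 1, "ss"))
    expect_equal(ss_sum, ss_total, tolerance = 1e-8)
    expect_equal(nrow(fit$table), 7L)  # g, a, b and all interactions
  }
})

test_that("degenerate designs are rejected", {
  d <- random_design(2, 3, 2, seed = 9)
  expect_error(mixed_anova(d[-1, ], "y", between = "g", within = "a"),
               "incomplete")
  d_bad <- d
  d_bad$g[d_bad$participant_id == "s1"] <- c("g1", "g2")
  expect_error(mixed_anova(d_bad, "y", between = "g", within = "a"),
               "one between level")
  d_na <- d; d_na$y[1] <- NA
  expect_error(mixed_anova(d_na, "y", between = "g", within = "a"), "complete")
})

test_that("marginal means average cells without weighting", {
  cells <- expand.grid(f1 = c("x", "y"), f2 = c("u", "v"))
  cells$mean <- 1:4
  expect_equal(estimated_marginal_means(cells, c("f1", "f2"))$mean, 1:4)
  gm <- estimated_marginal_means(cells, "f1")
  expect_equal(sort(gm$mean), c(2, 3))
  one <- data.frame(f1 = "x", mean = 7)
  expect_equal(estimated_marginal_means(one, "f1")$mean, 7)
  expect_error(estimated_marginal_means(cells, "nope"), "margins")
})

test_that("post hoc contrasts use stratum df and respect Bonferroni", {
  d <- random_design(3, 5, 2, seed = 11)
  fit <- mixed_anova(d, "y", between = "g", within = "a")
  ph_b <- posthoc_pairwise(fit, "g")
  expect_equal(nrow(ph_b), 3L)
  expect_true(all(ph_b$df == 15 - 3))           # N - g
  ph_w <- posthoc_pairwise(fit, "a", by = "g")
  expect_true(all(ph_w$df == 15 - 3))
  expect_true(all(ph_w$p_bonferroni >= ph_w$p_raw - 1e-12))
  expect_true(all(ph_b$ci_lo <= ph_b$m_diff & ph_b$m_diff <= ph_b$ci_hi))
  # Bonferroni caps at 1
  expect_true(all(ph_w$p_bonferroni <= 1))

  # mirror-symmetric groups: identical means give t = 0, p_bonferroni = 1
  d_sym <- d[d$g %in% c("g1", "g2"), ]
  d_sym$y <- rep(c(1, 2, 3, 4, 5), 4)  # same subject profile in both groups
  fit_sym <- mixed_anova(d_sym, "y", between = "g", within = "a")
  ph_sym <- posthoc_pairwise(fit_sym, "g")
  expect_equal(ph_sym$t, 0)
  expect_equal(ph_sym$p_bonferroni, 1)
})

test_that("effect-size variants follow their definitions", {
  expect_equal(cohens_d("between_pooled", 1, 0, 1, 1, 10, 10), 1)
  d_within <- cohens_d("within_av", 252.3, 227.0, 37.7, 34.1)
  expect_equal(d_within, 25.3 / ((37.7 + 34.1) / 2), tolerance = 1e-12)
  expect_equal(round(d_within, 2), 0.70)
  expect_error(cohens_d("within_av", 1, 0, 0, 0), "zero SD")
})
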