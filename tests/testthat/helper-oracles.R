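# Brute-force cell-means oracle for the split-plot decomposition with one
# between factor g, one within factor a, subjects s nested in g (balanced
# within; group sizes may differ). Independent of the aov-based fitting path.
oracle_split_plot <- function(d) {
  grand <- mean(d$y)
  yg <- tapply(d$y, d$g, mean)
  ya <- tapply(d$y, d$a, mean)
  ys <- tapply(d$y, d$s, mean)
  yga <- tapply(d$y, list(d$g, d$a), mean)
  ysa <- tapply(d$y, list(d$s, d$a), mean)
  subj_g <- tapply(as.character(d$g), d$s, function(v) v[1])
  n_g <- table(subj_g)
  nw <- length(unique(d$a))
  ss_g <- nw * sum(n_g * (yg[names(n_g)] - grand)^2)
  ss_subj <- nw * sum((ys - yg[subj_g[names(ys)]])^2)
  ss_a <- length(ys) * sum((ya - grand)^2)
  ss_ga <- 0
  for (g in rownames(yga)) for (a in colnames(yga)) {
    ss_ga <- ss_ga + n_g[[g]] * (yga[g, a] - yg[[g]] - ya[[a]] + grand)^2
  }
  ss_as <- 0
  for (s in rownames(ysa)) for (a in colnames(ysa)) {
    g <- subj_g[[s]]
    ss_as <- ss_as + (ysa[s, a] - ys[[s]] - yga[g, a] + yg[[g]])^2
  }
  list(group = ss_g, subj_err = ss_subj, a = ss_a, ga = ss_ga, as_err = ss_as)
}

random_design <- function(n_groups = 2, n_subj = 2, n_within = 2, seed = 1) {
  set.seed(seed)
  d <- expand.grid(
    s = paste0("s", seq_len(n_groups * n_subj)),
    a = paste0("a", seq_len(n_within)), stringsAsFactors = FALSE)
  d$g <- paste0("g", rep(rep(seq_len(n_groups), each = n_subj), n_within))
  d$y <- rnorm(nrow(d), 10, 3) + rep(rnorm(n_groups * n_subj, 0, 2), n_within)
  names(d) <- c("participant_id", "a", "g", "y")
  d
}
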