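# Internal helpers shared across modules.

# Ex-Gaussian deviates: Normal(mu, sigma) + Exp(rate = 1/tau).
# Degenerate sigma/tau (= 0) are allowed and collapse the component.
rexgauss <- function(n, mu, sigma, tau) {
  g <- if (sigma > 0) stats::rnorm(n, mu, sigma) else rep(mu, n)
  e <- if (tau > 0) stats::rexp(n, rate = 1 / tau) else 0
  g + e
}

# Normal draw truncated below at `lower` by resampling (means here sit many
# SDs above the bound, so the loop almost never iterates).
rtnorm_lower <- function(n, mean, sd, lower = 0) {
  if (sd <= 0) return(pmax(rep(mean, n), lower))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  tries <- 0L
  while (length(bad) > 0L && tries < 1000L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower]
    tries <- tries + 1L
  }
  x[x < lower] <- lower
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Outcomes whose RT enters reaction-time analyses (correct reaches plus
# overtime reaches, which are kept per the RT-limit grace rule).
rt_pool_outcomes <- function() c("correct", "overtime_reaching")
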