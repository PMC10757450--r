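---
title: "Models and methods behind stopsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stopsignal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopsignal)
```

## The scientific problem

Motor inhibitory control has two experimentally separable domains. *Reactive
inhibition* is the outright cancellation of an initiated action when a stop
signal appears; it is quantified by the stop-signal reaction time (SSRT), the
latency of the covert stopping process. *Proactive inhibition* is the
anticipatory adjustment of responding when stopping might be required; it is
quantified by the *context effect*: in a stop-signal task (SST) context,
participants lengthen the reaction times (RTs) of trials that in fact require
no stopping ("no-stop" trials) relative to an otherwise identical go-only
task, and — in the reaching version of the task — shorten the corresponding
movement times (MTs), presumably because the extra waiting time lets them
pre-compute the reach.

`stopsignal` implements the full analysis chain for such designs — SSRT
estimation with race-model diagnostics, three context-effect procedures, and
the mixed-design statistics that compare disease stages (Hoehn & Yahr groups)
and medication states (ON/OFF) — together with a generative cohort simulator
used to test every step.

## The race-model observer

The simulator implements the independent horse-race model. On every trial a
go process finishes at

$$T_{go} \sim \mathrm{exGauss}(\mu, \sigma, \tau),$$

an ex-Gaussian (normal plus exponential) finishing time. The ex-Gaussian is
the standard trial-level RT model: it produces the right-skewed distributions
that make the 800/900 ms censoring rules non-trivial. On stop trials a stop
process of constant participant-level latency `ssrt_true` launches at the
stop-signal delay (SSD); the response escapes inhibition iff
$T_{go} < \mathrm{SSD} + \mathrm{SSRT}$. A constant stop latency (rather than
a stochastic one) makes recovery targets well defined: the integration
estimator should return `ssrt_true` itself.

The SSD follows the tracking staircase of the emulated task geometry: it
starts at 119.7 ms (nine 13.3 ms display refresh periods), increases by
39.9 ms (three refresh periods) after each successful stop and decreases by
the same amount after each failure, clamped at 0 ms (the floor is our choice;
a negative delay is physically meaningless). Because the start and the step
are both multiples of the refresh period, the SSD stays on the refresh grid
by construction. The staircase runs continuously across blocks (whether the
real task reset it between blocks is unstated; a continuous staircase
preserves convergence and is the conservative choice).

Sessions comprise a go-only block (default 100 trials) and an SST of 480
trials in blocks of 120 with *exactly* one third stop trials per block at
uniformly random positions ("pseudorandom intermix" is under-specified; a
uniform permutation with an exact per-block quota is the simplest scheme that
fixes the stop proportion). No-stop trials obey the RT-limit rule: responses
up to 800 ms are correct, responses in the 100 ms grace window are kept as
`overtime_reaching` (and stay in all RT analyses), later responses abort with
no recorded RT. Target-miss and hold-violation lapses are injected i.i.d. at
rates calibrated so that simulated task accuracy matches the preset accuracy
rows; stop trials carry no lapses, keeping the race outcomes clean.

### Population structure

Group × treatment presets (`cohort_presets()`) give the population mean and
between-participant SD of every behavioural parameter, transcribed from the
behavioural summary of the emulated cohort (three patient groups staged
H&Y 1–1.5, 2, 2.5–3, each ON and OFF dopaminergic medication, plus healthy
controls). A participant is three latent traits — response speed, stop
latency, movement speed — drawn as standard normals, scaled by the preset
SDs, and *shared across the two task contexts*: a participant's proactive
slowing (no-stop minus go-only RT) and MT context delta therefore come from
the preset mean differences, not from independent draws. For MTs the two
context cells also share the averaged between-participant SD, so the MT
context delta equals the preset delta exactly. We adopted this after finding
that independent per-cell effects let individual MT deltas vary by hundreds
of ms and made the pooled population CDFs cross, contradicting the clean
population-level context separation such cohorts show. The cost is that the
generator understates between-participant variance in the context *delta*
itself; it matches the variance of the levels.

Patients' ON and OFF trait vectors share a correlation
`within_subject_rho = 0.7` (a within-subject design implies substantial
positive correlation; the exact value is not identifiable from group-level
summaries). Trial-level spread (`go_sigma = 40` ms, `go_tau = 80` ms,
`mt_sigma = 60` ms) is likewise a free generator choice: group summaries
only constrain between-participant SDs, and these values give realistic
skewed single-session RT distributions with a small (\<1–5%) overtime/abort
mass at the slower presets.

### What the generator does and does not emulate

It emulates: the trial-count design (66.6%/33.3% no-stop/stop), staircase SSD
dynamics, the censoring rules, proactive slowing with shortened no-stop MTs,
ON/OFF within-participant correlation, counterbalanced session order
annotation, and lapse-driven accuracy. It does not emulate: stimulus
geometry or timing within a trial, learning/fatigue across blocks,
trigger failures or stochastic stop latencies, tremor artefacts, or RT/MT
dependence within a trial. Tests passing on generator output therefore
certify the *estimators and statistics* under a faithful race model, not
robustness to every pathology of real recordings.

## Preprocessing

RTs are trimmed once (non-iteratively) at mean ± 3 sample SDs, computed on
the untrimmed RTs of each participant × session × task × trial-type cell —
per-participant scoping is the field convention and prevents group
differences from leaking into the trimming rule. Cells with fewer than two
RTs are left untrimmed with a warning. MTs are not trimmed. Accuracy is
correct go trials over all go trials; overtime reaches count as correct by
default (they did reach the target) with a flag to count them as errors
instead, since the printed-accuracy convention is ambiguous.

## Reactive inhibition

`estimate_ssrt_integration()` follows the consensus tracking-method recipe:
omissions (aborted no-stop trials) are replaced by the maximum observed RT;
the go-RT distribution (overtime included, post-trim) is sorted; the quantile
at rank `ceiling(p_failure * N)` (clamped to `[1, N]`) is taken; and the mean
SSD *over all stop trials* (not only failures — the tracking convention) is
subtracted. The estimate is undefined when `p_failure` is 0 or 1 and the
function says so rather than extrapolating; `run_pipeline()` drops such
sessions (they cannot occur at study-sized stop counts). Estimates from
fewer than 50 stop trials are flagged unreliable.

`check_race_assumptions()` verifies the two diagnostics that license the
estimate: mean stop-failure RT below mean no-stop RT (the observable
signature of go/stop independence — failures are the fast tail of the go
distribution) and staircase convergence (`|p_failure − 0.5|` within a band,
default 0.1). Failing sessions are flagged, never silently dropped.

## Proactive inhibition

Three procedures, in increasing granularity:

1. **Cell means.** Per-session mean RT and MT by trial type feed the
   split-plot ANOVAs.
2. **Population CDFs.** Per-participant empirical CDFs are averaged with
   equal weight on the pooled grid (each participant contributes `1/n`
   regardless of trial count). Directional hypotheses are evaluated by a
   *pair* of one-tailed two-sample KS tests per measure, run in opposite
   directions: only-expected-direction significant → effect; both directions
   significant → the distributions intersect → no effect; neither → no
   evidence. The overall verdict is `context` only when the RT effect
   (no-stop slower) and the MT effect (no-stop faster) both hold. The tests
   run on trial-level samples pooled over participants — a p-value needs a
   sample size, and the averaged curves have none; the averaged CDFs are for
   plotting and direction. This is a deliberate, documented choice of
   effective n whose direction of deviation from curve-level testing is
   unknown.
3. **Individual classification.** The same directional tests on one
   participant's own trials yield `context` (RT up, MT down, MT-opposite not
   significant), `inverse_context` (MT-opposite significant, expected not),
   else `no_context`. The decision table is total; alpha is 0.05 per
   one-tailed test, uncorrected (the classification is descriptive, feeding
   the χ² frequency analyses).

### Exact Kolmogorov–Smirnov p-values

Participant-level cells hold at most a few hundred trials, where asymptotic
KS p-values are poor, so `ks_two_sample()` computes exact p-values by lattice
path counting whenever `n·m ≤ 10⁴`: orderings of the pooled sample are
monotone paths from (0,0) to (n,m); the p-value is the fraction of paths
whose maximal signed (one-sided) or absolute (two-sided) deviation reaches
the observed statistic. Deviations are compared as exact integers in units
of `1/(n·m)`, ties are handled by applying the constraint only at boundaries
between distinct pooled values (the conditional-on-ties distribution), and
the count matrix is rescaled in blocks to avoid overflow. Beyond `10⁴` the
classical asymptotic series is used. Against brute-force enumeration of all
`choose(n+m, n)` assignments the path-counting p is exact; note that for
*tied* samples base R's `ks.test(..., alternative = "less")` evaluates the
D⁻ statistic against the tie-conditional distribution of D⁺, which can
differ — our implementation conditions on the correct direction.

## The statistics engine

`mixed_anova()` fits the classical univariate split-plot decomposition on
cell means (one observation per participant × within-cell): between effects
are tested against the participants-within-groups stratum, each within
effect and its interactions against the corresponding factor × participant
stratum; partial η² is `SS_effect/(SS_effect + SS_stratum error)`. With
two-level within factors sphericity holds trivially, so no
Greenhouse–Geisser machinery is included (three-level within factors are out
of scope). Within-participant cells must be complete; between-group sizes
may differ, as when a 30-participant control group joins 20-participant
patient groups.

`posthoc_pairwise()` forms pairwise contrasts with the stratum-appropriate
pooled error: between contrasts pool the one-way residual of participant
marginals (df `N − g`); within contrasts pool the condition-difference
variance across groups (also df `N − g` for a two-level factor); contrasts at
a fixed within level pool that level's residual. Raw p-values are
Bonferroni-multiplied by the family size. Cohen's *d* uses the pooled-SD
variant for between contrasts and the averaged-SD variant for
repeated-measures contrasts; the latter ignores the ON/OFF correlation, so
it will not numerically match correlation-corrected variants. 95% CIs come
from the same SE and df, unadjusted for multiplicity.

Bayes factors: the JZS t-test BF places a Cauchy(0, r = 0.707) prior on the
standardized effect and integrates the noncentral-t density against it by
adaptive quadrature split at the likelihood peak; post hoc BFs use the
contrast t with the per-group n. The contingency-table BF is the conjugate
Dirichlet–multinomial homogeneity Bayes factor (Gunel–Dickey family, prior
concentration a = 1, row totals fixed): both marginal likelihoods are closed
form, and the BF favours the null on homogeneous tables and grows with n
under a fixed association. χ² procedures are Pearson tests with
standardized-residual post hocs (two-sided normal p, Bonferroni over groups)
and, for the 2 × 2 control-vs-group comparisons, the N−1 correction
`χ²·(N−1)/N` on 1 df.

## Numerical and testing choices

Degenerate inputs are handled explicitly: zero `sigma`/`tau` collapse the
ex-Gaussian; constant responses give F = 0 and η² = 0 (guarded against
floating-point fuzz relative to the total SS); identical paired samples give
a Wilcoxon p of 1; zero-SD effect sizes and empty samples raise errors.

The test suite builds every fixture in code. Simulation-backed checks use
problem sizes chosen to balance resolution against runtime: SSRT recovery
uses 30 participants × 480 trials and a 40-session bias grid at 160 stop
trials; the staircase convergence check uses 10⁴ stop trials; type-I
calibration of the ANOVA engine uses 1000 null cohorts of 60 patients with
60 SST + 18 go-only trials per session (trial counts only set within-cell
noise, not the null F distributions, and every generative cell — including
the two task contexts — is equalized so that every omnibus effect is truly
null); population-level classification recovery uses 20 replicate
20-participant cohorts per regime. The split-plot engine is checked for
exact sums-of-squares agreement against a hand-written cell-means oracle,
and the exact KS routine against base R's exact reference over the full
`n, m ≤ 20` grid including tied data.

## Known limitations

- The stop process has no trigger failures and no latency variability;
  SSRT recovery targets are correspondingly idealized.
- The generator's context deltas are (by design) constant across
  participants within a cell; individual-difference studies of the *delta*
  would need a richer population model.
- Population-level KS tests pool trials across participants, treating trials
  as exchangeable within group × session; hierarchical dependence is ignored
  there (it is respected in the ANOVAs, which operate on cell means).
- Unbalanced *within* data (dropped sessions) are rejected rather than
  modelled; a mixed-effects route would be needed for incomplete designs.
- The a-priori power analysis of the emulated study is not reproduced (its
  inputs are not public), and clinical/demographic characterization is out
  of scope.
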