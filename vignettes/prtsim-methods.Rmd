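---
title: "Simulating and analysing the probabilistic reward task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing the probabilistic reward task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prtsim)
```

## The task and what it measures

The probabilistic reward task is a line-discrimination paradigm with
asymmetric reinforcement, used to measure *reward responsiveness* — the
propensity to develop a response bias toward a more frequently rewarded
stimulus.  On each trial one of two barely distinguishable stimuli (a
"short" or "long" mouth on a cartoon face) is flashed briefly and the
participant reports which one appeared.  Correct responses are sometimes
followed by a small monetary reward (5 pence), and the rewards are
distributed asymmetrically: in each block of 100 trials, 30 rewards are
scheduled on correct responses to one stimulus (the *rich* stimulus) and
only 10 on the other (the *lean* stimulus).  Reward-responsive participants
gradually shift their decision criterion toward the rich response; the size
of that shift is the phenotype.  Crucially, the bias measure (criterion) is
separable from perceptual ability (discriminability, d′), so group
differences in reward responsiveness can be interpreted even when
discrimination performance is identical.

`prtsim` implements this paradigm end to end for *in silico* studies:
constrained schedule generation, a session engine with the task's reward
rules, signal-detection scoring, a genotype-aware cohort simulator, and the
statistical toolkit used in candidate-gene association analyses of the
task.  Because no raw behavioural data from the motivating study design are
publicly deposited, the package's synthetic cohorts are the substrate on
which every downstream stage is exercised and tested.

## Schedule generation

A session is `n_blocks = 3` blocks of `trials_per_block = 100` trials.  Per
block, the two stimuli appear exactly 50 times each in pseudo-random order
with no more than `max_stimulus_run = 4` successive identical stimuli, and
40 scheduled rewards (30 rich + 10 lean) are placed so that no more than
`max_reward_run = 3` consecutive trials are scheduled for reward.  Blocks
are generated independently and the run caps are enforced within blocks
only, since the design is described per block; nothing constrains runs that
straddle a block boundary.

The stimulus order is built by a rejection-free constrained shuffle: the
sequence is drawn position by position, uniformly among the symbols whose
placement leaves a completable remainder.  For two symbols the
completability condition is exact — with `a` and `b` items left, a current
run of A of length `L`, and cap `r`, the sequence can be finished iff
`a <= r(b+1) - L` and `b <= r(a+1)` — so the construction never backtracks
and always terminates.  Reward positions are then sampled uniformly within
each stimulus class and redrawn until the reward-run cap holds, with a
bounded retry budget (10,000 draws); combinations that cannot satisfy the
cap are rejected at configuration time by the necessary condition
`rewards <= max_reward_run * (non_rewarded + 1)`, so the generator fails
fast rather than looping.  Everything is driven by a single integer seed:
identical configurations produce identical schedules.

## The session engine and the reward rules

The engine plays a schedule against any *responder* — an object that maps a
trial plan to a response and reaction time and is told after every trial
whether it was rewarded.  The reward rules are:

* feedback is only ever delivered on correct trials, at most once per
  trial;
* a scheduled reward on a correct trial is delivered immediately;
* a scheduled reward on an incorrect trial is *postponed*: it is delivered
  at the next correct trial of the same stimulus that is not itself
  scheduled for reward (scheduled rewards take precedence over pending
  ones);
* pending rewards carry across block boundaries within a session, since
  the delivery rule refers only to "a later" qualifying trial; rewards
  still pending at session end are reported, not forced.

Two readings of the "no more than three consecutive reinforced correct
trials" constraint are possible: a constraint on the planned schedule, or
on the realised reward sequence after postponement.  The package enforces
it on the planned schedule; postponements can in principle create longer
realised runs, which are recorded in the trial log but not prevented.  This
matches the natural reading of a *pseudo-random reward schedule* as a
design-time object.

Earnings accumulate at 5 pence per delivered reward (maximum £6 for a full
default session); sessions earning less than £5 are flagged excluded, the
task's performance-based exclusion rule.  Trials with reaction times
faster than 200 ms or slower than 3000 ms are removed before scoring;
because the rule removes strictly faster/slower trials, RTs of exactly
200 ms or 3000 ms are retained.

## Signal-detection scoring

Scoring treats the rich stimulus as the signal category: a *hit* is a
rich-stimulus trial answered with the rich response and a *false alarm* a
lean-stimulus trial answered with the rich response.  (The alternative
convention — a fixed physical stimulus as signal — is available through the
`signal_stimulus` argument, but the rich-stimulus convention is the default
because the criterion then directly measures bias toward the reinforced
category.)  Rates use the log-linear edge correction

H = (hits + 0.5) / (n_rich + 1),  F = (fa + 0.5) / (n_lean + 1),

applied uniformly to every block rather than only where a rate would be 0
or 1, keeping the estimator continuous.  The measures are

* discriminability d′ = z(H) − z(F), and
* criterion, reported sign-reversed relative to the conventional
  c = −½[z(H) + z(F)]: the package reports +½[z(H) + z(F)], so positive
  values mean stronger bias toward the rich response.

The development of bias over the task is summarised by
Δresponse bias = criterion(block 3) − criterion(block 1).  Scores are
functions of per-block counts only, so they are invariant to trial order
within a block.

## The synthetic participant

The paradigm's published group effects are behavioural; no mechanistic
model is implied.  The package's agent is therefore the simplest generative
mechanism that produces reward-responsiveness differences without
discriminability differences: a signal-detection observer with a drifting
decision threshold.  On each trial the agent draws a percept from
N(±s/2, 1) — s is its true d′ — and reports "long" iff the percept exceeds
its internal threshold.  Whenever a response is rewarded, the threshold
moves by the *reward learning rate* toward that response category.  Because
rich-stimulus rewards outnumber lean ones 3:1, a positive learning rate
produces a growing bias toward the rich response, while s (and hence scored
d′) is untouched.  An optional proportional decay of the threshold toward
its starting point models forgetting; it defaults to 0.  Reaction times are
lognormal (median 600 ms, sdlog 0.35) with 2% anticipatory fast guesses
(< 200 ms) and 2% lapses (> 3000 ms), so realistic sessions exercise the
validity filter (roughly 12 of 300 trials removed).

## Cohort generation and effect-size calibration

A cohort draws genotypes at a biallelic locus either from Hardy–Weinberg
proportions (p², 2pq, q²) at risk-allele frequency 0.33 — the frequency
implied by the study design the defaults emulate — or with fixed genotype
counts (e.g. 23/62/79) when a specific composition is wanted.  Demographics
(age ~ N(22.3, 4.4²) years truncated at 18, 44% male, two recruitment
sites at 79%/21%) are generated for pipeline completeness and are
independent of genotype by default, mirroring the null demographic checks
such studies report.  The rich stimulus is counterbalanced by alternating
it across participants.

The genotype effect enters through the reward learning rate: per-genotype
means with a common within-genotype SD (draws truncated at 0), with
perceptual sensitivity drawn from one distribution shared by all genotypes
(N(1.0, 0.15²) truncated at 0.2).  The calibration targets are the
standardized effects the design aims to detect: Cohen's d ≈ 0.66 for the
AA-vs-GG contrast on mean criterion and d ≈ 0.37 for the dominant
(carriers vs GG) contrast, with d′ flat across groups.

Calibration proceeded in two stages (the script and sweep table ship in
`inst/calibration/`).  First, a Monte-Carlo sweep established that mean
scored criterion is nearly linear in the learning rate (slope ≈ 29.4
criterion units per unit learning rate over the relevant range) with
per-participant measurement SD ≈ 0.076 + 1.17·lr.  Second, the genotype
means and variance components were solved against the target effect sizes.
One structural point emerged: a single wide learning-rate distribution
cannot supply all the between-subject variance, because truncation at 0
converts spread into a spurious positive mean bias in the zero-learning
(AA-like) group.  The extra variance is therefore carried by an
idiosyncratic *baseline response bias* — the agent's starting threshold,
drawn N(0, 0.30²) identically across genotypes — which adds
between-participant criterion variance without shifting any group mean.
The frozen defaults are learning-rate means (AA, AG, GG) =
(0, 0.0068, 0.0080), within-genotype SD 0.0024, and baseline-bias SD 0.30.
At 500 participants per genotype these produce d(GG−AA) ≈ 0.68 and
dominant d ≈ 0.41.  Note that the dominant-contrast effect depends on the
cohort's genotype composition: at a Hardy–Weinberg-like composition
(23/62/79) the heavily AG-weighted carrier group sits closer to GG, so the
expected dominant d is smaller (≈ 0.25–0.30) than at balanced composition,
and single cohorts of 164 participants scatter widely around it.

What the generator does *not* emulate: within-session non-stationarities
other than criterion drift (fatigue, attention waves), sequential RT
dependencies, response-time/accuracy coupling, stimulus-specific response
preferences, or any genotype–demographic correlation.  Its earnings-based
exclusion rate (around 3–4% of default cohorts fall below £5) is also
somewhat higher than a typical human sample's, because a unit-d′ observer
recovers slightly fewer postponed rewards than well-practised humans.  Passing tests
therefore show that the pipeline's *inference machinery* behaves correctly
on data with the assumed structure, not that real task data have that
structure.

## Statistical procedures

All tests return a common result object (statistic, df, p, effect size,
correction).  Choices that matter:

* **Hardy–Weinberg χ²** uses expected counts from the estimated allele
  frequency on 1 df (3 classes − 1 − 1 estimated parameter).
* **Contingency χ²** is the Pearson test without continuity correction.
* **One-way ANOVA** exists in a raw-data and a summary-statistics form
  (SS within reconstructed as Σ(nᵍ−1)sᵍ²), the latter for checking
  published descriptive tables; partial η² = SSB/(SSB+SSW).
* **Mixed repeated-measures ANOVA** uses the classical univariate
  decomposition, implemented in closed form from cell means.  The design is
  complete (every subject in every block), so cell frequencies are
  proportional and the block and group factors are orthogonal even with
  unbalanced groups — the sums of squares are unique and coincide across
  Type I/II/III.  With a covariate, the between-subjects stratum becomes an
  ANCOVA on subject means with the covariate entered first.  No sphericity
  correction is applied by default; a Greenhouse–Geisser correction of the
  within-subject degrees of freedom is available.  Degrees of freedom are
  always derived
  from the data supplied, not from any published table (published df for
  this design are internally inconsistent across analyses of the same
  sample, so matching them is not a meaningful target).  The implementation
  is validated against `aov()` + `Error(subject)` strata in the test suite.
* **t-tests** are two-sided by default (one-sample, and pooled-variance
  independent); Cohen's d uses the pooled SD.
* **Pairwise contrasts** use Bonferroni correction (raw p × number of
  comparisons, capped at 1); the correction is configurable in name only
  because no other method is currently implemented.
* **Power** for a two-sample comparison uses the noncentral-t method
  (noncentrality d/√(1/n₁+1/n₂), critical value from the central t), with a
  normal approximation available; the design-level power calculations are
  one-sided.

## Numerical and degenerate-input policy

The z-transform requires rates strictly inside (0,1); `sdt_measures()`
refuses uncorrected rates rather than clamping silently.  Blocks with zero
valid trials of either stimulus are a scoring error, not an NA.  Zero
variance (one-sample t, correlations, pooled variance) and monomorphic
samples (HWE) raise errors.  The schedule generator distinguishes
unsatisfiable configurations (configuration error at validation) from
unlucky sampling (bounded retries).  All simulation entry points take
integer seeds; per-participant sub-seeds are derived by integer hashing so
any participant can be re-simulated in isolation and the caller's RNG
state is never disturbed.

## Problem sizes used in the shipped checks

The package's own verification uses: 1000 schedule seeds for the run-cap
property; 200 sessions per learning rate on the grid {0, 0.05, 0.1, 0.2}
for parameter recovery; 500 participants per genotype for the effect-size
calibration check; 2000 replicates for the mixed-ANOVA type-I-error and
p-uniformity checks (n = 30 per group under the null).  These sizes give
Monte-Carlo standard errors comfortably below the tolerances being
checked (e.g. ±0.005 on a 5% rejection rate at 2000 replicates).

## Known limitations

* Absolute criterion levels are calibrated only indirectly (through the
  standardized effect targets); no published numeric group means exist to
  validate them against, so only signs, orderings and standardized effects
  are meaningful.
* The agent's learning is a fixed-step criterion drift; it saturates for
  large learning rates and is not a reinforcement-learning model with
  value estimates.  Monotonicity of scored bias in the learning rate
  holds over the tested range, not unboundedly.
* The mixed ANOVA assumes a complete design and will not impute missing
  blocks; with 3 within-subject levels and no sphericity correction by
  default, liberal within-subject p-values are possible under strong
  non-sphericity (a Greenhouse–Geisser correction is available via the
  `sphericity` argument).
* Analysis presets run a fixed sequence; the package is not a general
  ANOVA engine.
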