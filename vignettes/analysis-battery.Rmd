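---
title: "The metapsi analysis battery: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The metapsi analysis battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapsi)
```

## The paradigm and what the simulator emulates

A session consists of 36 forced-choice trials. On each trial the
participant guesses whether a reward image will appear behind the left or
the right curtain; the target side is then drawn by a random event
generator (REG), with replacement, nominally at P(left) = 0.5. A *pure*
session uses 18 erotic-image (X) and 18 neutral-image (O) trials; a
*mixed* session interleaves 18 true trials with 18 *sham* trials (SX, SO)
on which the reward image is never displayed whatever the outcome. The 36
reward images (18 erotic, 18 neutral) are drawn without replacement, so
each session exhausts the pool exactly once. Counterfactual arms replace
the participant's guess with a second, independent REG channel.

`simulate_study()` reproduces this structure at the trial level. Its key
modelling decisions:

* **Only the hit process is statistically identified.** On the human arm
  the hit indicator is drawn directly as Bernoulli at
  `plogis(qlogis(base_rate) + u_i + bias terms)`, and the guess side is
  back-filled to agree with the independently drawn target side exactly
  when the trial is a hit. Nothing in the downstream analysis
  distinguishes this from a mechanistic guess-then-target draw with the
  same hit probability, and it keeps every condition's null exact: with
  all biases zero and `heterogeneity_sd = 0`, hits are exchangeable
  Bernoulli(base_rate).
* **REG arms have no base rate.** Hits arise from the agreement of two
  independent binary channels; with a shared class-A side offset delta on
  both channels the agreement probability is
  (0.5+delta)^2 + (0.5-delta)^2 = 0.5 + 2 delta^2. This closed form is the
  oracle for the simulator's counterfactual contract in the test suite.
* **Mixed-session composition.** The split of the 18 true trials between X
  and O (and of the 18 sham trials between SX and SO) is fixed at 9/9.
  The symmetric split is the simplest reading of the published session
  diagrams, keeps erotic and neutral images in one-to-one correspondence
  with erotic- and neutral-labelled trials, and makes condition counts
  deterministic; a per-session random split would only add bookkeeping
  noise that the analysis (which pools per condition) cannot see.
* **Participant heterogeneity** is a normal random intercept on the
  log-odds scale with SD `heterogeneity_sd` (default 0); repeated sessions
  of one participant share the intercept.
* **Systematic errors** are injectable through `bias_spec()`: `side_delta`
  (class A) offsets P(left) of both random channels; `session_drift`
  (class B, default 0) adds a per-repeated-session log-odds drift;
  `control_delta` (class C, default 0) offsets only the neutral control
  conditions. Dedicated *detection* machinery exists only for class-A
  error (`class_a_check()`), mirroring the counterfactual design's focus;
  class-B/C injections surface qualitatively through condition contrasts.
* **Incomplete and over-run sessions.** Sessions are abandoned with
  probability `incomplete_session_prob` (truncated uniformly to 1–35
  trials) and over-run with probability `overrun_prob` (default 5e-4,
  chosen so that well under 0.1% of trials are unplanned extras, matching
  the rare connection-latency overruns of web-delivered sessions), adding
  1–6 trials up to the hard 42-trial cap.
* The paradigm's randomisation used a seedable JavaScript PRNG in the
  original software; the contract here is statistical, not bit-exact, so
  R's default generator with an integer `seed` is used throughout.

What the simulator does **not** emulate: image-level effects (images carry
identities but no effect on the hit probability), reaction times,
questionnaire covariates, and temporal autocorrelation within sessions.
Passing tests therefore certify the analysis chain's behaviour under the
idealised data-generating process, not the absence of such structure in
real data.

## The Bayes tests

For k hits in n trials, `bf01_one_sided()` contrasts M0 (p = 1/2 exactly)
with M1 (p above 1/2, beta prior truncated and renormalised to (0.5, 1]):

$$ m_0 = \binom{n}{k} 2^{-n}, \qquad
   m_1 = \binom{n}{k}\frac{B(k+\alpha,\,n-k+\beta)}{B(\alpha,\beta)}
         \cdot\frac{1 - I_{0.5}(k+\alpha,\,n-k+\beta)}{1 - I_{0.5}(\alpha,\beta)}, $$

with $I$ the regularised incomplete beta function, and BF01 = m0/m1.
Everything is computed in log space via `lbeta()` and
`pbeta(..., log.p = TRUE)`; the test suite checks the closed form against
adaptive quadrature of the defining integral at relative tolerance 1e-8,
and the uniform-prior case against its independent closed form.

The three analysis priors are Beta(1, 1) (uniform), Beta(7, 7) (the
knowledge-based "BUJ" prior, whose directional mass places 90% below the
probability equivalent of Cohen's d = 0.5 under
$p = e^{d\pi/\sqrt3}/(1+e^{d\pi/\sqrt3})$) and Beta(829, 733) (the
plus-one update of 828 successes in 1,560 historical erotic trials,
`make_replication_prior(0.531, 1560)`). Classification uses strict
thresholds: BF01 > 25 supports M0, BF01 < 1/25 supports M1, and boundary
values are deliberately classified inconclusive, reading "higher than" /
"lower than" literally.

Published aggregates print hit rates rounded to two decimals of a percent,
so the hit count is ambiguous; `counts_for_proportion()` enumerates every
integer count consistent with a printed value, and the package's own
headline checks require all admissible counts to agree to within one
integer of the published Bayes factor.

## The frequentist model

`fit_random_intercept_logit()` maximises

$$ \ell(\beta_0,\sigma) = \sum_i \log \int
   \mathrm{Binom}(k_i;\,n_i,\,\mathrm{logit}^{-1}(\beta_0+u))\,
   \phi(u;0,\sigma^2)\,du $$

over per-participant counts, evaluating each integral by Gauss–Hermite
quadrature (default 25 nodes — exact to ~1e-10 for the heterogeneity
range these designs consider, σ ≲ 0.8; the suite verifies 50-node
agreement with adaptive integration at 1e-8). Numerical choices:

* initialisation at β0 = logit(pooled proportion), σ = 0.1; L-BFGS-B with
  σ bounded below by 0 and a relative log-likelihood tolerance of 1e-8;
* the σ = 0 boundary is handled by profiling: the boundary fit (exactly
  the pooled binomial logit) is reported whenever the interior search does
  not improve on it, with the binomial Wald SE — so homogeneous data
  reduce *exactly* to the pooled analysis;
* otherwise the SE of β0 comes from the inverse observed information over
  both parameters (numerical Hessian), falling back to the σ-profiled
  curvature if the two-parameter information is ill-conditioned near the
  boundary;
* REG arms have no grouping structure and collapse to a single
  pseudo-group, i.e. a pooled binomial Wald test.

`wald_interval()` forms the CI on the log-odds scale and maps the
endpoints through the inverse logit; the reported SE is the delta-method
probability-scale SE in percentage points, and the p-value is the
two-sided Wald tail. The preregistered decision rule
(`decide_frequentist()`) supports M0 when the CI's upper bound is below
0.51 and M1 when its lower bound exceeds 0.5; the two-sided confirmatory
rule (`confirm_bidirectional()`) asks whether 0.5 falls outside the 95%
CI, with touching endpoints counted as containment.

## The sequential design

`design_spec()` fixes the three analysis points at 37,836 / 62,388 /
86,958 trials per analysed condition — taken as given constants of the
consensus design — with Bonferroni-adjusted CI levels 99.5% / 99.75% /
99.875%. At each look `evaluate_analysis_point()` runs four tests (the
frequentist CI rule plus the three Bayes factors) and `run_sequential()`
stops at the first look where all four conclusively support the same
model; any inconclusive test forces continuation. "Conclusive" means the
CI decision rule fires, or a BF passes its 25-fold threshold. Inclusion
rules follow the preregistration: incomplete sessions retained, over-runs
retained to 42 trials, and each condition truncated at exactly the
analysis point's N in arrival order (idempotently). Sequential evaluation
applies to the condition under analysis (the erotic conditions in the
original design); other conditions are analysed at their final N.

`sequential_power_tpp()` measures the design's operating characteristics
by Monte Carlo. With no heterogeneity each simulated study reduces to
cumulative binomial counts at the three looks, and the battery is applied
to the counts directly (the pooled Wald test coincides with the mixed
model when heterogeneity is negligible, which keeps 10,000-study runs
cheap); with heterogeneity, participant blocks of 18 trials receive
normal random intercepts before pooling. The "large personal differences"
scenario of the original design papers is exposed through this τ
parameter without a default claim, since no published value quantifies
it. Computed under this design, the M1-stop probability at a true rate of
51% with τ = 0 comes out slightly above the 95% figure the consensus
design papers reported from their own simulation code (the acceptance
script prints the package's value); the package reports what its own
faithful reading of the published decision rules produces rather than
tuning toward the citation.

## Power and sample size

`analytic_power()` uses the two-sided normal approximation with the
variance at the true rate, *including both rejection tails*, so the null
case returns exactly α (the single-tail shortcut would return α/2 there;
away from the null the minor tail is negligible and the two agree).
`mc_power()` draws binomial counts and applies the same Wald test the
analysis uses. `required_n()` inverts the analytic formula and then
refines to the smallest n meeting the target, so its output is a design
*minimum*; the published study sizes (127,000 and 217,800) sit above the
minima their stated assumptions produce, as sponsors round designs up.

## Problem sizes in the test suite

The suite favours closed-form oracles (quadrature cross-checks,
channel-agreement algebra, Bonferroni bounds) over brute replication.
Monte-Carlo checks use sizes chosen to keep each property's Monte-Carlo
standard error well inside the effect it certifies: ~10^5–10^6 simulator
trials for channel calibrations, 800 null refits for CI coverage under
heterogeneity (τ = 0.1, 200 participants × 18 trials), 300–400 replicates
for detection-power comparisons, and 10^4 count-level studies for the
sequential design. Two full-size sequential runs (4,831 and 2,102
sessions) exercise the trial-level path end to end.

## Known limitations

* The mixed-model p-values printed for the original participant-level
  data cannot be reproduced exactly from published aggregates (they depend
  on the unpublished per-participant counts); the package's calibration
  properties cover them qualitatively instead.
* The sequential battery's Bayes components are evaluated on pooled
  counts, as preregistered; participant heterogeneity therefore affects
  them only through the count distribution.
* `estimate_error_rates()` calibrates the count-level pipeline; it does
  not re-run the trial-level simulator per replicate.
* Session-level artefacts of real web delivery (latency clusters,
  device effects) are outside the generator's scope.
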