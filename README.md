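# metapsi

Simulation and preregistered analysis battery for forced-choice guessing
experiments with counterfactual controls.

## The problem

Large replication studies of the Bem Experiment 1 precognition paradigm ask
whether people can guess, above chance, which side of a screen will later be
chosen by a random event generator (REG). Each 36-trial session presents 18
erotic and 18 neutral reward images drawn without replacement; the target
side is drawn *after* the guess, with replacement, at P = 0.5. Because the
claimed effect is tiny (a percentage point or less around 50%), the analysis
machinery itself becomes the main scientific risk: systematic bias anywhere
in the measurement or analysis chain (class-A error) can masquerade as a
psi effect. Modern protocols therefore combine a preregistered multi-look
test battery with *counterfactual* controls — sham trials on which the
reward is never displayed, and whole study arms in which a REG substitutes
for the participants, so that every analysis can be re-run on data where no
effect can possibly exist.

`metapsi` implements this machinery as a tested, reusable package for
methodologists and replication researchers:

- a trial-level **simulator** of the paradigm (pure and mixed sessions,
  sham trials, REG arms, participant heterogeneity, injectable class-A/B/C
  biases) — `simulate_study()`;
- the **directional Bayes factor** BF01 for a binomial count, contrasting
  M0 (p = 0.5 exactly) against M1 (p > 0.5 with a truncated beta prior),
  under the three analysis priors Beta(1, 1), Beta(7, 7) ("BUJ") and
  Beta(829, 733) (replication) — `bf01_one_sided()`;
- the intercept-only **random-intercept logistic regression** fitted by
  Gauss–Hermite maximum likelihood, with probability-scale Wald intervals
  and the preregistered CI decision rules — `fit_random_intercept_logit()`,
  `wald_interval()`, `decide_frequentist()`;
- the **three-look sequential design** (analysis points 37,836 / 62,388 /
  86,958 with 99.5% / 99.75% / 99.875% Bonferroni-adjusted CIs) with its
  four-test all-agree stopping rule — `run_sequential()`;
- **power and sample-size** tools, analytic and Monte-Carlo, including the
  operating characteristics of the whole sequential design —
  `mc_power()`, `required_n()`, `sequential_power_tpp()`;
- **diagnostics**: the full battery per condition and arm
  (`condition_battery()`), class-A error detection on REG arms
  (`class_a_check()`), side-bias checks and whole-pipeline error-rate
  calibration.

## The statistics in brief

For k hits in n trials, the directional Bayes factor is

    BF01 = Binom(k; n, 1/2) / m1,
    m1   = C(n,k) B(k+a, n-k+b) / B(a,b) * (1 - I_0.5(k+a, n-k+b)) / (1 - I_0.5(a, b)),

with I_x the regularised incomplete beta function; all terms are evaluated
in log space. BF01 > 25 supports M0, BF01 < 1/25 supports M1. The BUJ prior
is calibrated on the Cohen's-d scale through p = exp(d·π/√3)/(1+exp(d·π/√3)),
so that d = 0.5 corresponds to p = 0.712. The frequentist test fits
logit P(hit) = β0 + u_i with u_i ~ N(0, σ²) by Gauss–Hermite quadrature,
forms the Wald CI for β0, and maps it to the probability scale; the study
supports M0 when the upper CI bound is below 0.51 and M1 when the lower
bound exceeds 0.5.

## Worked example

Simulate a null mixed-session study and run the battery:

```r
library(metapsi)
trials  <- simulate_study(study_config(n_participants = 200,
                                       session_type = "mixed", seed = 42))
battery <- condition_battery(trials)
cat(render_study_table(battery))
```

```
| Condition | Arm | Result (%) | No. Trials | BF01 (uniform) | BF01 (buj) | BF01 (replication) |
|---|---|---|---|---|---|---|
| X | human | 51.88 ± 1.25; p = 0.132 | 1,801 | 5.17 | 1.78 | 0.538 |
| O | human | 50.94 ± 1.18; p = 0.423 | 1,800 | 15.6 | 5.35 | 2.29 |
| SX | human | 51.78 ± 1.28; p = 0.164 | 1,803 | 6.06 | 2.09 | 0.653 |
| SO | human | 49.36 ± 1.21; p = 0.595 | 1,801 | 49.7 | 17 | 14.1 |
```

Each row reports the hit percentage with its delta-method SE in percentage
points, the two-sided Wald p-value against 50%, and BF01 under the three
priors (values above 1 favour the null; above 25 support it conclusively).
At ~1,800 trials per condition nothing is conclusive — which is the point:
the preregistered design needs 37,836 trials per condition at its first
analysis look.

A single Bayes test from published aggregates (18,721 hits in 37,836
trials, i.e. 49.48%):

```r
bf01_one_sided(k = 18721, n = 37836, prior_spec("buj"))
#>       k     n prior log_m0 log_m1  bf01 support
#> 1 18721 37836 buj    -7.55  -12.6  159. M0
```

BF01 ≈ 159: the data are 159 times more likely under chance guessing than
under the directional alternative. The sequential design's operating
characteristics at a true 51% rate:

```r
sequential_power_tpp(0.51, reps = 2000, seed = 1)
#>   power   mc_se method        stop_m0 inconclusive
#> 1 0.975 0.00349 sequential_mc   0.002        0.023
```

A command-line wrapper with `simulate`, `analyze`, `bayes`, `sequential`,
`power`, `diagnose` and `report` subcommands is installed at
`system.file("cli", "metapsi", package = "metapsi")`.

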