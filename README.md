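# vollearn

Valence-specific volatility learning: task generation, behavioural
modelling, grid-posterior fitting and pupillometry for dual-valence
probabilistic learning experiments.

## What this package is for

A rational learner weights each outcome by how informative it is, and an
outcome whose contingency is *volatile* (changeable) is more informative
than one that is stable. If people keep separate volatility estimates for
positive and negative outcomes, those estimates are a mechanism for
affective bias: learning more from losses than wins, or the reverse.

`vollearn` implements the full computational pipeline for a task that
tests this. On each trial two shapes are shown; one carries a 15 p win and
one a 15 p loss, positioned *independently*, and both outcome locations
are revealed whatever the choice. Across three 80-trial blocks the
volatility of each valence is manipulated independently: volatile
trajectories alternate between 15% and 85% in runs of 14–30 trials
(averaging exactly 50% over the block), stable ones stay at 50%.

The core behavioural model estimates the win and loss locations with
independent Rescorla–Wagner updates and valence-specific parameters,

    r_win(i+1) = r_win(i) + α_win · (win_out(i) − r_win(i))
    P(choose A) = 1 / (1 + exp(−(β_win·r_win − β_loss·r_loss)))

and the key question is whether the fitted learning rates α_win, α_loss
(and outcome-locked pupil dilation, a norepinephrine proxy) track each
valence's volatility — the block volatility × valence interaction.

The package provides, per module:

* **Schedules** — `generate_block()`, `generate_session()`,
  `validate_schedule()`: seeded task schedules with the independent
  win/loss volatility manipulation.
* **Models** — `model_variant_run()` and friends: five model variants
  (dual-valence RW; model-free net value; a no-free-parameter Bayesian
  volatility-tracking learner, `bayesian_learner()`; single-temperature
  RW; risk-distorted RW), usable generatively and for likelihoods.
* **Fitting** — `grid_posterior()`, `marginal_expectation()`,
  `fit_participant()`, `compare_models()`: full grid posteriors with
  marginal-expected parameters (C++ inner loop), per-block BIC
  (k·ln n − 2·lnL over the 70 likelihood-contributing trials) summed
  across blocks.
* **Synthetic data** — `simulate_cohort()`, `simulate_agent()`,
  `simulate_pupil()`: cohorts with recorded ground truth and matching
  500 Hz pupil traces with blinks, drift, noise and injectable
  volatility × valence effects.
* **Pupillometry** — `preprocess_pupil()`: blink interpolation,
  zero-phase 3.75 Hz Butterworth filtering, session z-transform,
  baseline-corrected 6 s outcome epochs, exclusion rules, and binned
  obtained-vs-unobtained difference timeseries.
* **Statistics** — `rm_anova_mixed()`, `change_scores()`, `correlate()`,
  `fisher_compare()`, `analyze_cohort()`: the mixed repeated-measures
  ANOVAs, change-score correlations and correlation comparison.

## Worked example

```r
library(vollearn)

# simulate a small cohort of dual-valence RW agents with known parameters
cohort <- simulate_cohort(6, variant = "m1", seed = 42)
head(cohort$ground_truth[, c("participant", "alpha_win", "alpha_loss")], 3)
#>   participant alpha_win alpha_loss
#> 1           1 0.4173085  0.2069003
#> 2           2 0.4595236  0.5552506
#> 3           3 0.1182448  0.2241726

# fit the primary model to one participant (grid posterior per block)
fit <- fit_participant("m1", cohort$sessions[[1]])
round(fit$params, 3)
#>   block alpha_win alpha_loss beta_win beta_loss
#> 1     1     0.335      0.254    4.737     3.708
#> 2     2     0.479      0.493    2.293     0.916
#> 3     3     0.685      0.616    2.336     0.656
round(fit$bic_total, 1)
#> [1] 280.6

# compare two correlations the way the change-score analysis does
fisher_compare(0.50, -0.08, 29, 29)
#> $z
#> [1] 2.269613
#> $p
#> [1] 0.02323106
```

Participant 1's generating parameters were α_win 0.42, α_loss 0.21 with
low temperatures (β ≈ 2–3), so the per-block estimates scatter around the
truth with the win rate above the loss rate in two of three blocks; the
Fisher comparison of a loss-change correlation of 0.50 against a
win-change correlation of −0.08 at n = 29 per group gives z ≈ 2.27,
p ≈ 0.02.

## Package layout

```
R/            schedule, models, bayesian-learner, fitting, agents,
              pupil-sim, pupil, stats, io
src/          C++ grid-likelihood kernel
tests/        testthat suite (unit, property and acceptance tests)
vignettes/    methods vignette: models, assumptions, numerical choices
scripts/      acceptance.R
```
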