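# wheeltask

Simulation and cross-laboratory analysis of a standardized visual
two-alternative forced-choice (2AFC) wheel task for head-fixed mice.

In the task, a grating of contrast c (percent, signed: negative = left
hemifield) appears on one side of a screen and the mouse reports its side by
turning a wheel. Training proceeds through automated stages that introduce
progressively harder contrasts; in the *basic* task both sides are equally
likely, while the *full* task opens with 90 unbiased trials and then
alternates unsignaled 20:80 / 80:20 blocks whose lengths are
truncated-geometric (mean 51 trials, bounds [20, 100]), inviting the animal
to combine vision with an estimate of the stimulus prior.

The package is aimed at behavioral neuroscientists who want to (a) generate
realistic synthetic cohorts of this task with known ground truth, and (b)
run the complete analysis stack used to ask whether trained behaviour is
reproducible across laboratories — without any access to real data.

## The models at the core

**Psychometric curve** — the probability of a rightward choice is the
four-parameter erf model

    P(c) = gamma + (1 - gamma - lambda) * (erf((c - mu) / sigma) + 1) / 2

with left/right lapse rates gamma, lambda, bias mu and contrast threshold
sigma, fitted by constrained maximum likelihood with multi-start.

**Trial-history choice model** — a logistic regression on the decision
variable

    z(i) = sum_c W_c I_c(i) + W_r r(i-1) + W_u u(i-1) + W_0 [+ W_b b(i)]

where I_c is the signed indicator of contrast c, r/u encode the previous
rewarded/unrewarded choice (+1 right, -1 left, 0 otherwise), and b is the
block label (full task). The same model doubles as the generative agent of
the simulator, which makes parameter recovery the package's natural
self-validation: simulate from known weights, refit, compare.

**Proficiency criteria** — the automated 1a/1b (basic) and full-task
criteria on trial counts, easy-trial performance, psychometric parameters
and 0%-contrast reaction times, each requiring three consecutive passing
sessions.

**Reproducibility assessment** — per-mouse featurization from the three
proficiency sessions, lab-membership classification (naive Bayes, random
forest, logistic; 2000 subsamples of 8 mice/lab, leave-one-out CV) against
a shuffle null with a timezone positive control, plus Kruskal-Wallis /
Levene / ANOVA cross-lab tests with Benjamini-Hochberg correction.

## Worked example

```r
library(wheeltask)
set.seed(1)

# three trained-stage full-task sessions from the default generative agent
agent <- default_agent_params("full")
stage <- training_stage(5, gain = 4, reward_volume = 1.5,
                        debias_active = FALSE)
trials <- do.call(rbind, lapply(1:3, function(day) {
  sch <- build_session_schedule("full", 700)
  tr <- simulate_session(agent, stage, sch, "full", n_target = 700)
  tr$session_day <- day
  tr
}))

# refit the generative model
fit <- fit_choice_glm(build_design(trials, "full"), penalty_strength = 1e-6)
round(fit$weights, 2)
#>      c6.25      c12.5        c25        c50       c100   rewarded
#>       0.88       1.92       3.24       3.26       2.96       0.38
#> unrewarded      block  intercept
#>       0.30       0.43       0.02
round(fit$condition_number, 2)
#> [1] 3.45
```

The recovered weights sit near the generative truth (visual weights rise to
about 3 at 100% contrast; history weights W_r = 0.42, W_u = 0.46; block
weight W_b = 0.40), and the design's condition number is low — the
coefficients are interpretable, not collinear.

```r
# bias shift between block types at 0% contrast (percentage points)
f20 <- choice_fractions(trials, 0.2)
f80 <- choice_fractions(trials, 0.8)
subset(bias_shift(f20, f80), signed_contrast == 0)
#>   signed_contrast    shift
#> 6               0 35.05376
```

Block priors shift choices most where sensory evidence is absent; across
many sessions this averages near 28.5 points, the calibration anchor of the
simulator's block weight.

## Command-line pipeline

```sh
Rscript -e 'wheeltask::run_pipeline(commandArgs(TRUE))' \
  simulate --seed 5 --out-dir out/
Rscript -e 'wheeltask::run_pipeline(commandArgs(TRUE))' \
  fit-glm --trials out/trials.csv --variant basic --out-dir out/
```

Subcommands: `simulate`, `fit-psychometric`, `fit-glm`, `assess-status`,
`classify-labs`; all take `--seed`, `--config` (flat `key: value` file),
`--out-dir`, `--log-level`. Trials tables are plain CSV (see
`?read_trials_table` for the schema); reports are JSON.

## What the synthetic data does and does not establish

The methods vignette (`vignettes/wheeltask-methods.Rmd`) documents the
generative assumptions, every calibrated default, and the limits of what a
green test on synthetic data can show about real cohorts.
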