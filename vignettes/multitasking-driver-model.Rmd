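---
title: "A hierarchical reinforcement-learning model of driver multitasking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical reinforcement-learning model of driver multitasking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multidrive)
```

## Overview

`multidrive` simulates a driver who must keep a car in its lane while
intermittently searching a small in-car display for a visual target. The
simulated driver is a hierarchy of three learned policies:

1. a **driving policy** that steers the car using a belief about its
   lateral lane position (a POMDP: the true position is observed only
   noisily, and not at all while the eyes are on the display);
2. a **search policy** that chooses where to fixate next on the display,
   with eye-movement durations given by the EMMA model of encoding and
   saccades;
3. a **supervisory policy** that allocates attention between the two
   tasks, observing only the value estimates the two subtask policies
   place on their own current situations.

All three are trained by tabular SARSA with softmax (Boltzmann) action
selection. The package then reproduces a 2x2 driving-simulator protocol —
speed (60 vs 120 km/h) crossed with search set size (6 vs 9 items) — and
extracts the standard distraction metrics from simulated trial traces.

## The driving task

The car travels at a fixed speed `v`. Its state is the signed lateral
offset from the lane centre plus a bounded, dimensionless steering state;
actions are small steering adjustments. The dynamics are the minimal
speed-sensitive linear form

    offset' = offset + v * dt * steering' + drift * dt + N(0, sigma_d)

so the speed condition has mechanical force: the same steering moves the
car laterally twice as fast at 120 km/h. The reward is 0 while the car is
within the half-lane bound (1.75 m for the standard 3.5 m lane) and a
negative rate per second beyond it.

The driver never sees the true offset. A belief distribution over 21
discretized positions is maintained by Bayes' rule: each cycle it is
pushed through a *learned* stochastic transition model (the prediction
step), and, only when the eyes are on the road, corrected by a noisy
position observation that is accurate with probability 0.9. The
transition model is tallied from fully observed random-action rollouts,
and deliberately conditions on the discretized position and action alone —
the hidden steering state is marginalized out — so it is a coarse
approximation whose extra dispersion makes belief uncertainty grow
quickly while driving blind.

The tabular policy state is a sufficient statistic of the belief: its
argmax position, its Shannon entropy (binned), and the steering state.

```{r driving-params}
p <- driving_params(speed_kmh = 60)
p$lane_half_bound_m
p$speed_mps
```

## The in-car search task

Each trial shows `n_items` items (6 or 9) placed uniformly at random on a
10 x 6 degree display, at least 2 degrees apart. On half the trials one
item is the target; the trial ends when the target is encoded
(target-present) or when every item has been encoded (foil). Encoding and
eye-movement time follow EMMA:

* encoding time `T_e = K * (-log f) * exp(k * eccentricity)`,
* saccade duration `T_s = t_prep + t_exec + D * t_sacc`,

with defaults `K = 0.006`, `k = 0.4`, `f = 0.01` (novel trigram stimuli),
`t_prep = 0.135 s`, `t_exec = 0.070 s` and `t_sacc = 0.002 s/degree`. If
`T_e < t_prep` the item is encoded covertly without moving the eyes;
otherwise a saccade brings fixation to the item and the remaining
fraction of the encoding completes there. Each encode is charged its
duration as negative reward; completing the trial pays a large positive
reward (default 10).

```{r emma}
encoding_time(0.01, 5, search_params())
saccade_time(34, search_params())  # also the task-switch cost
```

The tabular policy state is the fixation cell of a coarse 3x3 partition
of the display plus the 9-bit pattern of cells already cleared of
unencoded items; the 9 actions aim the next encode at a cell.

## The supervisory task

The supervisory policy chooses, at each decision point, whether the next
moment of attention goes to driving or to search. Its observation is
deliberately impoverished: the discretized best-action utilities of the
two subtask policies (max Q at their current states, 12 bins each, ranges
calibrated in a random-allocation warm-up) plus the task currently in
focus. Changing focus costs the saccade duration for the 34-degree
road-to-display separation (0.273 s), during which neither task
progresses and the car drives blind. While the eyes are on the display,
driving continues without observations for the duration of every
eye-movement action: the driving policy keeps steering on its propagated
belief, and lane penalties keep accruing. The supervisory reward is the
joint subtask reward accrued over the step.

Because the driving belief entropy rises while blind, and the driving
policy's value estimates fall with entropy, the max-q_d observation is a
risk signal: the longer the eyes stay in-car, the stronger the pull back
to the road.

## Training pipeline

`train_policies()` enforces the stage ordering: transition-model rollout,
driving policy, search policy, observation-bin calibration, supervisory
policy. Two effort profiles exist (`training_profile()`): `"full"`
(study-scale) and `"fast"` (continuous-testing scale). The problem sizes
— 21 position bins, 5 entropy bins, 3x3 display cells, 12 value bins —
are this package's own choices, set to keep tabular learning tractable on
one CPU.

```{r train, eval = FALSE}
policies <- train_policies(speed_kmh = 60, n_items = 6, profile = "fast",
                           seed = 1)
trace <- run_trial(policies, target_present = FALSE, seed = 1)
ggplot2::autoplot(trace)
```

## Numerical and design decisions

Several quantities are this package's design decisions rather than given
constants; all are exposed in the configuration objects:

* **Exploration schedule.** The softmax temperature anneals linearly
  over the first 60% of episodes and then holds at its floor; the
  learning rate decays per state-action cell as
  `alpha / (1 + alpha_decay * n)` (Robbins-Monro), so estimates settle
  where visited often while remaining plastic elsewhere.
* **Temperature scale.** Exploration temperatures are only meaningful
  relative to the magnitude of the utilities. Both the search and the
  supervisory learners face returns dominated by the search completion
  reward (10), so both start their temperature at `reward_found / 2`; a
  starting temperature of 1 is effectively greedy once utilities reach
  ~3, which locks the search learner onto revisit cycles and freezes the
  supervisory glance structure on whatever the first lucky episodes did.
* **Intermittent-observation driving training.** The driving policy is
  trained with occasional blind stretches (`observe = "intermittent"`),
  not with an observation on every cycle. High-entropy belief states are
  otherwise never visited during training, and their value estimates
  would default to 0 — making the supervisory model's risk observation
  uninformative. The fully observed variant remains available.
* **Episode budgets.** The fast profile trains driving for 8,000 and
  search for 10,000 episodes — more than a naive scale-down of the full
  profile — because lane keeping has a sparse reward over a large state
  space, and the nine-item search task spreads its visits over thousands
  of cleared-pattern states.
* **Sub-step noise.** Driving noise over a partial cycle of duration
  `d` has standard deviation `sigma_d * sqrt(d / dt)`, so composing
  sub-steps of a blind glance accumulates exactly one cycle's variance
  per cycle.
* **Glance accounting.** An in-car glance spans from the start of the
  switch toward the display to the start of the switch back: the
  outbound travel belongs to the glance, the return travel to the
  following road span. Span durations partition trial time exactly.
* **Lane deviations** are counted once at the onset of each maximal
  excursion beyond the half-lane bound, as simulator logs are
  conventionally reduced.
* **Baseline comparisons.** `evaluate_supervisory_policy()` compares
  attention-allocation policies on the per-step *discounted* return the
  supervisory learner optimizes. The undiscounted trial reward cannot
  separate policies that complete the search with similar encoding
  effort — waiting is free in raw reward terms — whereas discounting
  penalizes the delayed completion caused by over-frequent switching.

## The simulated experiment

`run_experiment()` trains one policy set per condition and runs the trial
protocol (24 trials per participant, half target-present, half foil,
shuffled). A "participant" is an independent evaluation seed over the
shared trained policies, which is known to understate human
between-participant variance. `aggregate_metrics()` averages within and
then across participants; `compute_fit_indices()` compares cell means
with a human summary (mean absolute error, relative error, error in human
SD units, and the R-squared of regressing human values on model
predictions).

```{r experiment, eval = FALSE}
exp <- run_experiment(n_participants = 4, n_trials = 24,
                      profile = "fast", seed = 1)
summ <- aggregate_metrics(exp$metrics)
ggplot2::autoplot(summ)
compute_fit_indices(summ, read_human_summary())
```

The bundled human summary (`extdata/human_summary_synthetic.csv`) is a
clearly labelled synthetic stand-in with plausible effect directions, for
exercising the fit machinery; it is not participant data.

## Limitations

* Tabular learners over hand-discretized states: no generalization
  across similar beliefs or layouts, so training budgets matter and rare
  states can carry poor value estimates.
* The eye-movement constants and the driving noise magnitude are adopted
  defaults, exposed in configuration; conclusions that hinge on their
  precise values (for example, absolute glance durations) should be read
  as qualitative.
* One car, one lane, constant speed, no other traffic; no manual
  response modelling; no letter-level perception of the search stimuli.
* Model "participants" differ only in simulation stochasticity, so
  between-participant variance is smaller than in human data.
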