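---
title: "Model-free learning and action sequences in the two-step task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-free learning and action sequences in the two-step task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostep)
library(dplyr)
```

## The scientific problem

Habit-like behavior in sequential decision tasks has two competing formal
accounts. The first is **model-free reinforcement learning** (MF RL):
actions accumulate cached value directly from experienced reward, without
any representation of the environment's transition structure. The second is
**model-based selection of chunked action sequences**: a planner that knows
the transition structure chooses among both single actions and precompiled
multi-action chunks (e.g., "press left, then left again"), and a chunk, once
launched, executes open-loop — ignoring whatever happens mid-sequence.

In the classic two-step task these accounts are confounded. A Stage-1 choice
(L1/R1) leads with probability 0.8 to its designated Stage-2 state (green or
yellow) and with probability 0.2 to the other; a Stage-2 choice (L2/R2) then
yields reward. The MF signature is a *main effect* of the last trial's
reward on repeating the Stage-1 choice; a model-based learner instead shows
a reward-by-transition *interaction*. But when the task's outcomes are
binary and the terminal screen is just "reward" or "no reward"
(a **reward-based terminal state** representation), a purely model-based
agent with sequences reproduces the MF main effect: exiting autopilot it
knows only that the chunk it launched paid off, so it repeats the chunk —
mimicking MF credit assignment. If instead each Stage-2 state–action pair
has its own terminal state with a drifting *graded* value (a **path-based**
representation), the terminal state itself reveals whether the transition
was rare, the planner credits the correct path, and the mimicry collapses.

This package implements that whole research program as reusable code: the
three task variants, the agent models, the cohort simulations, the
one-trial-back signature regressions with their trial-restriction filters,
and trial-level model fitting with random-effects model selection.

## Task environments

`make_task()` builds one of three variants:

* `original_binary` — rewards in {0, 1}; each Stage-2 pair's reward
  *probability* drifts by a reflecting Gaussian walk. This variant's walk
  parameters are a convention of the original two-step literature rather
  than of the graded-reward studies, so the package uses the conventional
  values (`sigma = 0.025` on bounds `[0.25, 0.75]`) and exposes both as
  arguments.
* `graded_expt1` — rewards are the current point value of the visited
  Stage-2 pair, drifting on `[-5, 5]` with `sigma = 1.75` (reflecting,
  mean-zero Gaussian steps; one step between trials).
* `redstate_expt2` — as the graded task, but *both* Stage-1 actions rarely
  (p = 0.2) lead to one shared red state whose two actions produce a single
  common outcome value (a fifth walk channel, drifting like the others so
  that red-state feedback varies over trials). Because the red state is
  equally reachable from both Stage-1 actions, a model-based controller
  integrates it out: red-state outcomes cannot rationally influence Stage-1
  choice, which isolates model-free credit assignment.

Walk channels are initialized uniformly over their bounds, independently per
agent. Graded rewards are kept continuous; nothing is rounded.

The `representation` argument controls outcome encoding.
`reward_based` is accepted only for the binary variant: for graded rewards
it would need one terminal state per point value (eleven states, forty-four
transition probabilities), which is not a representation a participant would
plausibly adopt — requesting it raises an error.

## Agent models

Five candidate models (`model_spec()`, `list_models()`) cross two factors:
whether the agent can select sequences at Stage 1, and whether single-step
actions and sequences are valued purely model-based or by a convex
MF/MB mixture with weight `omega` (`omega = 1` is pure model-based; one
shared `omega` serves every mixed controller in a model).

* **Model-based values.** The transition model is fixed at the true
  probabilities — participants are told the transition structure explicitly,
  and the program of analyses assumes they use it — so the planner learns
  only a reward model `R'`, one delta-rule estimate per terminal channel,
  with the same learning rate `alpha` as the MF system. Stage-1 single
  actions are valued by the Bellman recursion with a `max` over Stage-2
  actions, exactly as the planning equation is written. A sequence is
  valued as the expectation over its open-loop outcome distribution; in the
  reward-based representation this reduces to a learned per-sequence reward
  probability, which is the entire mimicry mechanism.
* **Model-free values.** Q-learning at both stages with an eligibility
  trace: the Stage-2 reward prediction error is passed back to the Stage-1
  action discounted by `lam` (without this, reward could not influence the
  next trial's Stage-1 choice at all). Models with model-free sequence
  control additionally cache one value per sequence, updated toward the
  trial's terminal reward with rate `alpha`; a sequence is one temporally
  extended action, so it receives one prediction error and the trace does
  not apply. Sequence caches are updated also when the agent happens to
  choose a sequence's component actions one at a time
  (`update_sequences_from_components = TRUE` by default; all headline
  results are insensitive to this flag).
* **Choice rule.** A softmax with inverse temperature `beta1` over the
  Stage-1 option set ({L1, R1} plus the four sequences where available) and
  `beta2` over the Stage-2 pair, with a stay bonus `nu` added to the logit
  of every Stage-1 option whose first action repeats the previous trial's
  Stage-1 action. The stay bonus is applied at Stage 1 only (the standard
  perseveration convention). This was a genuinely open design point: a
  Stage-2 bonus sharing the same `nu` turns one parameter into a driver of
  *both* Stage-1 and Stage-2 repetition, which imitates a weak
  sequence-like stay1–stay2 coupling even in the no-sequence model and
  measurably contaminates the "no interaction" cells of the
  sequence-controller prediction matrix. The Stage-2 bonus remains
  available via `model_spec(stay_bonus_stage2 = TRUE)`.
* **Open-loop execution.** If a sequence is drawn, the Stage-2 action is
  executed regardless of the realized Stage-2 state. In path-based tasks
  the terminal state then still reveals the path taken, so all value stores
  update correctly; in the reward-based binary task a chunked trial updates
  *only* the sequence's reward probability — the agent never registers
  which Stage-2 state it passed — which is precisely why the mimicry exists
  there and nowhere else.

Simulation priors (`sample_params()`): `alpha ~ Beta(1.1, 1.1)`,
`beta1, beta2 ~ Gamma(shape 1.2, scale 5)`, drawn independently,
`nu ~ Normal(0, 1)`,
`omega, lam ~ Uniform(0, 1)` where used. Unused parameters are pinned
(`omega = 1` for pure-MB control, `lam = 0` when no single-step MF values
exist). Cohorts default to 1,000 agents of 125 trials, the simulation
conditions under which the headline dissociations are established.

## Signature analyses

All analyses consume the long trial table produced by `simulate_cohort()` /
`generate_dataset()` / `read_trials()`. Predictor coding (documented because
coefficients depend on it): previous reward is mean-centered over the
analyzed table and always enters *unbinned*; binary predictors are coded
±0.5 (common = +0.5, repeat = +0.5). `bin_reward()` sign-bins for display
only, with zero assigned to "negative" by fixed convention.

* `stay1_signature()` — Stage-1 repetition on previous reward × previous
  transition. Main effect of reward = MF signature; interaction = MB
  signature.
* `expt2_stay1_after_rare()` — the red-state design's unconfounded MF test:
  Stage-1 repetition on previous reward, restricted to trials following a
  red-state (rare) transition.
* `filter_sequence_trials()` — the sequence-diagnostic restriction: keep
  trials whose previous transition matches the requested type *and* whose
  Stage-2 state differs from the previous trial's. The state-change
  restriction is what rules out attention/arousal confounds: a single-step
  agent cannot carry a learned Stage-2 preference into a different state,
  while an open-loop chunk is insensitive to the state change.
* `stage2_choice_signature()` — Stage-2 repetition on Stage-1 repetition ×
  previous reward; the positive interaction is the behavioral signature of
  sequences. With `split_by_prev_transition = TRUE` the previous transition
  type enters, and the three-way interaction tests whether the sequence
  signature is confined to post-common trials (the model-based
  sequence-control prediction).
* `stage2_rt_signature()` — the reaction-time analog: the Stage-2
  switch-cost (`switch2`, +0.5 when the Stage-2 action changed) grows with
  Stage-1 repetition × previous reward when open-loop re-execution skips
  the Stage-2 decision. The factorial parameterization is the default; the
  classic verbal description of this contrast maps onto the
  `switch2 x stay1 x reward` coefficient, and a difference-score
  formulation (only the `switch2` terms) is available via `formulation =
  "difference"`.
* `graded_vs_binned()` — per-subject AIC comparison of Stage-1 stay
  predicted from graded versus sign-binned reward, on post-common trials;
  positive `delta` means subjects track the full reward scale.

### Regression backends

The headline analyses are classically run as random-slopes logistic GLMMs.
This package's default is a dependency-light two-estimator scheme, with the
GLMM available as `backend = "mixed"` (via lme4):

* Stage-1 analyses (`stay1_signature()`, `expt2_stay1_after_rare()`): per
  subject logistic fits, then a one-sample t-test across subjects on each
  coefficient (the summary-statistics approach). The group test is
  deliberately *unweighted*: in 80/20 designs with strongly heterogeneous
  softmax temperatures, per-subject standard errors correlate with the
  estimates, and a precision-weighted fixed-effect z rejects true nulls —
  the pure-MB sequence cohort on the graded task, whose reward main effect
  must be null, shows |z| near 9 under precision weighting but |t| under 1
  under the t-test, the behavior a random-slopes mixed model also shows.
  Subjects whose fits are
  degenerate (separation, absent outcome variance) are dropped and counted
  in `glance()`.
* Stage-2 analyses (`stage2_choice_signature()`, `stage2_rt_signature()`):
  the trial-restriction filters leave too few trials per subject for stable
  subject-level logistic fits (quasi-separation is the rule, not the
  exception), so the default is a pooled fit with CR0 cluster-robust
  standard errors by subject — a GEE-style population-averaged estimator
  that is stable on sparse designs and preserves every presence/absence
  cell of the controller prediction matrix.

## Trial-level fitting and model selection

`trial_loglik()` evaluates a subject's choices sequentially under any of
the five models, updating values exactly as the simulator does (the inner
loop is compiled; a plain-R twin of the same computation backs the test
suite). Because sequence use is unobservable in choice data, the likelihood
of each observed (Stage-1, Stage-2) pair marginalizes the latent execution
mode: `P(a1, a2) = P(chunk a1-a2) + P(single a1) * P(a2 | realized s2)`.
Learning updates treat the Stage-2 path as visible, which is exact for the
graded (path-based) tasks the models are fit to.

`fit_map()` maximizes log-likelihood plus log prior — the same priors as the
simulations — with 10 random restarts by default. Optimization runs in an
unconstrained transformed space (logit for `alpha`, `omega`, `lam`; log for
the temperatures; identity for `nu`) with the priors mapped by change of
variables. A constrained optimizer in natural space is the common
alternative in this literature; the transformed space is preferred here
because it keeps the curvature used by the Laplace approximation finite
when the MAP sits near a bound. The Hessian is computed by central finite
differences (step 1e-4 in transformed units); `laplace_evidence()` then
gives the subject-level log marginal likelihood, ridge-regularizing (and
flagging) the rare non-positive-definite case.

`bms_pxp()` implements the random-effects model-selection hierarchy: a
variational Dirichlet-multinomial posterior over model frequencies,
exceedance probabilities by Monte-Carlo sampling of that Dirichlet (1e6
draws, seeded), the Bayes omnibus risk from the free-energy comparison
against the equal-frequency null, and protected exceedance probabilities
`PXP = EP * (1 - BOR) + BOR / K`. `bic_bayes_factor()` supplies the BIC
approximation used for the directed null tests, with `n_obs` counted in
trials (not button presses). `model_recovery()` closes the loop:
simulate from each generating model, fit all candidates, and tabulate which
model the PXP selects.

## Synthetic human-like data

`generate_dataset()` produces complete datasets — choices from any agent
model plus reaction times — so the full pipeline, including the RT
signatures, is testable without any external data. The agent models do not
generate latencies, so RTs come from a deliberately minimal additive model
(`rt_model()`): a Stage-2 baseline (700 ms), minus a speedup when the trial
was executed open-loop (150 ms), plus a switch cost when the Stage-2 action
changed (100 ms), plus Gaussian noise (200 ms), truncated positive. These
constants are round numbers on the scale of two-step reaction times, chosen
once; the generator makes no attempt to match real RT distributions, skew,
or autocorrelation — passing RT tests shows the analysis detects an
injected open-loop speedup, not that human RTs look like this. The
`observed` view omits the latent chunk flag, as a human study would; the
`hidden` view retains it for validation.

## Numerical and design notes

* **Problem sizes.** The acceptance script and test suite simulate the
  study-scale cohorts (1,000 agents × 125 trials) for the signature
  dissociations; fitting-based checks use 20–50 subjects × 250 trials with
  3 restarts, a deliberately scaled-down analog of the full fitting runs
  (96–197 subjects, 10 restarts) that preserves the qualitative findings.
* **Determinism.** Every stochastic entry point takes a seed; per-agent
  substreams are derived from the cohort seed by an integer mixing map, so
  cohorts are reproducible independent of evaluation order. All derived
  seeds stay below 2^31.
* **Numerical safeguards.** Softmaxes are computed with max-subtraction;
  likelihood evaluations that overflow during optimization are treated as
  objective value 1e10 rather than crashing a restart; the group t-test
  drops per-subject fits with any standard error above 25 (separation).
* **Q-value boundedness.** With `lam = 0` the Q-learning update is a convex
  contraction, so cached values stay inside the attainable reward range
  (tested as a property). The eligibility pass-back can transiently
  overshoot that range when the Stage-1 target (`max` over Stage-2 values)
  and the chosen Stage-2 action disagree; this is a property of the printed
  update rule, not an implementation artifact.
* **Known limits.** The two-stage backends approximate, and do not
  reproduce coefficient-for-coefficient, a full random-slopes GLMM;
  analyses of human data additionally require human data, which the
  package does not ship. The likelihood's component-visible update
  assumption makes it inexact for hypothetical *reward-based* sequence
  data, which the fitting pipeline is not used for.

## A worked example

```{r example, eval = FALSE}
library(twostep)

task <- make_task("graded_expt1")
cohort <- simulate_cohort(
  model_spec("Mixture-actions/Mixture-sequences"),
  task, n_agents = 300, seed = 1
)

stay1_signature(cohort) # MF main effect + MB interaction
cohort |>
  filter_sequence_trials("common") |>
  stage2_choice_signature() # the sequence signature

ds <- generate_dataset(experiment = 2, n_subjects = 100, seed = 2)
fits <- fit_cohort(
  ds$observed[ds$observed$subject <= 10, ],
  list(
    model_spec("Mixture-actions/MB-sequences"),
    model_spec("Mixture-actions/Mixture-sequences")
  ),
  make_task("redstate_expt2"),
  n_restarts = 3
)
bms_pxp(fits$evidence)
```
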