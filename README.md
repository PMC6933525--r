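# twostep

Simulation, behavioral signature analysis, and trial-level model comparison
for variants of the **two-step task** — the workhorse paradigm for
dissociating *model-free reinforcement learning* (cached action values,
updated directly from reward) from *model-based planning over chunked
action sequences* (a planner choosing among single actions and precompiled
open-loop chunks like "L1 then L2").

The package is for computational cognitive modellers who want to:

* simulate cohorts of hybrid MF/MB Q-learning agents and action-sequence
  agents on three task variants — the original binary-reward task, a
  graded-reward task (drifting point values on [−5, 5]), and a "red-state"
  design in which both Stage-1 actions rarely lead to one shared state;
* run the one-trial-back signature regressions: the Stage-1 stay analysis
  (reward main effect = MF signature; reward × transition interaction = MB
  signature), the Stage-2 choice and reaction-time sequence signatures with
  their trial-restriction filters, and the graded-vs-binned reward AIC
  comparison;
* fit five candidate models to trial-level choice data by MAP estimation
  with random restarts, compute Laplace approximations to each subject's
  model evidence, and compare models at the group level with protected
  exceedance probabilities (random-effects Bayesian model selection).

## The models in brief

An agent in state *s* values action *a* by a convex mixture
*Q*(s,a) = ω·*Q*<sub>MB</sub>(s,a) + (1−ω)·*Q*<sub>MF</sub>(s,a).
Model-based values come from the Bellman recursion over the (instructed)
transition probabilities and a delta-rule reward model; model-free values
from Q-learning with an eligibility trace (decay λ) passing the Stage-2
prediction error back to the Stage-1 action. Choices are softmax with
inverse temperatures β₁, β₂ and a stay bonus ν for repeating the previous
Stage-1 action. Sequence models add four chunked options (L1-L2, L1-R2,
R1-L2, R1-R2) to the Stage-1 choice set; a chosen chunk executes its
Stage-2 action open-loop. The five candidate models cross sequence use with
MB-vs-mixture control of single actions and of sequences
(`list_models()`).

The scientific crux: with *reward-based* terminal states (binary task) a
purely model-based sequence agent reproduces the MF reward main effect —
after autopilot it knows only that its chunk paid off — while with
*path-based* terminal states (graded task) the terminal state reveals the
path, the planner credits the right channel, and the mimicry disappears.
The red-state design then separates MF from MB control *of the sequences
themselves*.

## Worked example

```r
library(twostep)

task <- make_task("graded_expt1")
cohort <- simulate_cohort(
  model_spec("Mixture-actions/Mixture-sequences"),
  task, n_agents = 300, seed = 1
)

stay1_signature(cohort)
#> <twostep_signature> stay1 ~ prev_reward * prev_transition ( two_stage backend, 247 of 300 subjects, 37200 trials )
#>                        term estimate std.error statistic  df  p.value
#> 1               (Intercept)    2.392    0.1324     18.07 246 5.24e-47
#> 2               prev_common    0.303    0.1139      2.67 246 8.20e-03
#> 3             prev_reward_c    0.364    0.0268     13.58 246 1.04e-31
#> 4 prev_reward_c:prev_common    0.556    0.0431     12.90 246 1.95e-29

cohort |>
  filter_sequence_trials("common") |>
  stage2_choice_signature()
#> <twostep_signature> stay2 ~ stay1 * prev_reward ( cluster backend, 300 of 300 subjects, 9023 trials )
#>                    term estimate std.error df statistic  p.value
#> 1           (Intercept)   0.5417    0.0383 NA     14.13 2.50e-45
#> 2               stay1_c   0.4616    0.0610 NA      7.57 3.65e-14
#> 3         prev_reward_c   0.0754    0.0107 NA      7.05 1.85e-12
#> 4 stay1_c:prev_reward_c   0.1318    0.0196 NA      6.71 1.93e-11
```

Reading the output: in the first table, the positive `prev_reward_c` row is
the model-free signature (agents repeat Stage-1 choices that just paid off,
regardless of transition type; log-odds per reward point) and the positive
interaction is the model-based signature. In the second table — restricted
to trials following a common transition whose Stage-2 state differs from
the previous trial's — the positive `stay1_c:prev_reward_c` interaction is
the action-sequence signature: Stage-1 and Stage-2 repetition are more
correlated after reward, exactly what open-loop re-execution of a
just-rewarded chunk produces. These agents mix both controllers, so all
three effects are present.

`tidy()` and `glance()` return the same results as tibbles;
`autoplot()`, `plot_stay_probability()` and `plot_stay_by_reward()` draw
the standard figures. `generate_dataset()` adds reaction times for the RT
signature; `fit_map()` / `fit_cohort()` / `bms_pxp()` /
`model_recovery()` cover the fitting side; `read_trials()` /
`write_trials()` define the CSV interchange (long format, one row per
trial: `subject, trial, s1_choice, transition, s2_state, s2_choice,
reward[, rt1, rt2][, option_latent]`).

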