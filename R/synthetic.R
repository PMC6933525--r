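# Human-like synthetic datasets: simulated choices plus generated reaction
# times, so the full analysis pipeline (including the RT signatures) can be
# exercised without any external data.

#' Specify the additive reaction-time model
#'
#' The agent models produce choices, not latencies; reaction times are
#' generated by a minimal additive model grounded in the open-loop logic:
#' executing a chunked sequence skips the Stage-2 decision and is therefore
#' faster. `rt2 = base2 - seq_speedup * chunked + switch_cost * switched +
#' noise`, truncated to stay positive; `rt1 = base1 + noise`.
#'
#' @param base1,base2 Baseline Stage-1 / Stage-2 latencies (ms).
#' @param seq_speedup Latency saved when the Stage-2 action was executed
#'   open-loop (ms).
#' @param switch_cost Latency added when the Stage-2 action differs from the
#'   previous trial's (ms).
#' @param noise_sd Gaussian noise SD (ms).
#' @return A list of class `twostep_rt_model`.
#' @export
rt_model <- function(base1 = 800, base2 = 700, seq_speedup = 150,
                     switch_cost = 100, noise_sd = 200) {
  stopifnot(base1 > 0, base2 > 0, noise_sd >= 0)
  structure(
    list(
      base1 = base1, base2 = base2, seq_speedup = seq_speedup,
      switch_cost = switch_cost, noise_sd = noise_sd
    ),
    class = "twostep_rt_model"
  )
}

#' Generate a complete human-like dataset
#'
#' Simulates per-subject sessions from an agent model on the graded
#' (experiment 1) or red-state (experiment 2) task and attaches generated
#' Stage-1 and Stage-2 reaction times via [rt_model()]. Two views are
#' returned: `observed` mimics what a human study records (no latent
#' sequence-use column), and `hidden` retains the ground-truth
#' `option_latent` flag for validation.
#'
#' @param experiment `1` (graded task) or `2` (red-state task).
#' @param model A [model_spec()] object (default: the full
#'   mixture-actions/mixture-sequences model).
#' @param n_subjects Number of subjects (default 96, an experiment-1-sized
#'   cohort).
#' @param n_trials Trials per subject (default 125).
#' @param rt A [rt_model()] object.
#' @param seed Integer seed.
#' @return List with tibbles `observed` and `hidden`, plus `params` (the
#'   generating parameter draws).
#' @export
generate_dataset <- function(experiment = 1,
                             model = model_spec("Mixture-actions/Mixture-sequences"),
                             n_subjects = 96, n_trials = 125,
                             rt = rt_model(), seed = 1) {
  stopifnot(experiment %in% c(1, 2))
  task <- make_task(if (experiment == 1) "graded_expt1" else "redstate_expt2")
  sim <- simulate_cohort(model, task,
    n_agents = n_subjects, n_trials = n_trials,
    seed = seed
  )
  set.seed(derive_seed(seed, 999983L))
  switched <- sim |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(sw = .data$s2_choice != dplyr::lag(.data$s2_choice)) |>
    dplyr::pull(.data$sw)
  switched[is.na(switched)] <- FALSE
  n <- nrow(sim)
  sim$rt1 <- pmax(1, rt$base1 + stats::rnorm(n, 0, rt$noise_sd))
  sim$rt2 <- pmax(
    1,
    rt$base2 - rt$seq_speedup * sim$option_latent +
      rt$switch_cost * switched + stats::rnorm(n, 0, rt$noise_sd)
  )
  list(
    observed = dplyr::select(sim, -"option_latent"),
    hidden = sim,
    params = attr(sim, "params")
  )
}
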