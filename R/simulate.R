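# Cohort simulation: parameter priors and session generation.

# Deterministic per-agent substream seeds derived from a cohort seed by an
# integer mixing map (kept < 2^31; distinct across agents for any cohort of
# realistic size).
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483629 * 7919 + i * 104729) %% 2147483629)
}

#' Draw agent parameters from the simulation priors
#'
#' Samples parameter points from the priors used for both simulation and
#' fitting: `alpha ~ Beta(1.1, 1.1)`, `beta1, beta2 ~ Gamma(shape 1.2,
#' scale 5)` (independently), `nu ~ Normal(0, 1)`, and `omega, lam ~
#' Uniform(0, 1)` where the model uses them. For purely model-based
#' controllers `omega` is fixed at 1; `lam` is fixed at 0 when the model has
#' no single-step model-free values for the eligibility trace to act on.
#'
#' @param model A [model_spec()] object.
#' @param n Number of parameter points to draw.
#' @return A tibble with `n` rows and columns `alpha`, `beta1`, `beta2`,
#'   `nu`, `omega`, `lam`.
#' @examples
#' set.seed(1)
#' sample_params(model_spec("Pure MB"), n = 3)
#' @export
sample_params <- function(model, n = 1) {
  uses <- model_uses_param(model)
  tibble::tibble(
    alpha = stats::rbeta(n, 1.1, 1.1),
    beta1 = stats::rgamma(n, shape = 1.2, scale = 5),
    beta2 = stats::rgamma(n, shape = 1.2, scale = 5),
    nu = stats::rnorm(n, 0, 1),
    omega = if (uses[["omega"]]) stats::runif(n) else rep(1, n),
    lam = if (uses[["lam"]]) stats::runif(n) else rep(0, n)
  )
}

# One agent's session as a list of plain vectors (fast path for cohorts).
agent_session <- function(model, params, task, n_trials) {
  store <- init_store(task, model)
  walk <- init_walk(task)
  a1 <- integer(n_trials)
  s2 <- integer(n_trials)
  a2 <- integer(n_trials)
  rew <- numeric(n_trials)
  trans <- character(n_trials)
  chunked <- logical(n_trials)
  for (t in seq_len(n_trials)) {
    step <- run_trial(model, params, store, task, walk)
    store <- step$store
    walk <- step$walk
    rec <- step$record
    a1[t] <- rec$a1
    s2[t] <- rec$s2
    a2[t] <- rec$a2
    rew[t] <- rec$reward
    trans[t] <- rec$transition
    chunked[t] <- rec$chunked
  }
  list(a1 = a1, s2 = s2, a2 = a2, reward = rew, transition = trans, chunked = chunked)
}

#' Simulate a cohort of agents on a task
#'
#' Draws independent parameter points from the priors for `n_agents` agents
#' and simulates each for `n_trials` trials, with an independent reward walk
#' per agent. Each agent runs on its own seed substream derived from `seed`,
#' so the cohort is bit-reproducible regardless of evaluation order.
#'
#' @param model A [model_spec()] object.
#' @param task A [make_task()] object.
#' @param n_agents Number of agents (cohort default 1000).
#' @param n_trials Trials per agent (default: the task's session length).
#' @param seed Integer seed for the whole cohort.
#' @param params Optional tibble of fixed parameter values (recycled to
#'   `n_agents` rows if it has one row); by default parameters are drawn from
#'   the priors.
#' @return A tibble (one row per trial) with columns `subject`, `trial`,
#'   `s1_choice`, `transition`, `s2_state`, `s2_choice`, `reward`, and the
#'   latent (unobservable in human data) sequence-execution flag
#'   `option_latent`. The generating parameters are attached as the
#'   `"params"` attribute.
#' @examples
#' task <- make_task("graded_expt1")
#' sim <- simulate_cohort(model_spec("No sequences"), task, n_agents = 2, seed = 1)
#' @export
simulate_cohort <- function(model, task, n_agents = 1000, n_trials = task$n_trials,
                            seed = 1, params = NULL) {
  stopifnot(n_agents >= 1, n_trials >= 1)
  if (is.null(params)) {
    set.seed(derive_seed(seed, 0L))
    params <- sample_params(model, n_agents)
  } else {
    params <- tibble::as_tibble(params)
    if (nrow(params) == 1) params <- params[rep(1, n_agents), ]
    stopifnot(nrow(params) == n_agents)
  }
  sessions <- lapply(seq_len(n_agents), function(i) {
    set.seed(derive_seed(seed, i))
    p <- agent_params(
      alpha = params$alpha[i], beta1 = params$beta1[i], beta2 = params$beta2[i],
      nu = params$nu[i], omega = params$omega[i], lam = params$lam[i]
    )
    agent_session(model, p, task, n_trials)
  })
  out <- tibble::tibble(
    subject = rep(seq_len(n_agents), each = n_trials),
    trial = rep(seq_len(n_trials), times = n_agents),
    s1_choice = STAGE1_ACTIONS[unlist(lapply(sessions, `[[`, "a1"))],
    transition = unlist(lapply(sessions, `[[`, "transition")),
    s2_state = STAGE2_STATES[unlist(lapply(sessions, `[[`, "s2"))],
    s2_choice = STAGE2_ACTIONS[unlist(lapply(sessions, `[[`, "a2"))],
    reward = unlist(lapply(sessions, `[[`, "reward")),
    option_latent = unlist(lapply(sessions, `[[`, "chunked"))
  )
  attr(out, "params") <- tibble::tibble(subject = seq_len(n_agents), params)
  attr(out, "model") <- model$name
  attr(out, "task") <- task$variant
  out
}
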