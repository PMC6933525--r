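# Agent machinery: value stores, model-based planning, Q-learning updates,
# the softmax choice rule with stay bonus, and one full task trial.
#
# Sequences are indexed 1..4 in the order L1-L2, L1-R2, R1-L2, R1-R2:
# sequence k has first action ((k - 1) %/% 2) + 1 and second ((k - 1) %% 2) + 1.

seq_first <- function(k) ((k - 1L) %/% 2L) + 1L
seq_second <- function(k) ((k - 1L) %% 2L) + 1L

# The state reached by the rare branch of stage-1 action a1.
rare_state <- function(task, a1) {
  if (task$variant == "redstate_expt2") 3L else 3L - a1
}

#' Initialize an agent's value store
#'
#' The store holds the agent's cached model-free Q-values (`qmf1`, `qmf2`,
#' and, for sequence models, per-sequence caches `qmf_seq`), the learned
#' reward model `rprime` (one entry per terminal channel; in the reward-based
#' representation these are per-pair reward probabilities), the learned
#' per-sequence reward probabilities `pseq` (reward-based representation
#' only), and the previous trial's choices (`prev_a1`, `prev_a2`; 0 = none).
#' The transition model is not stored: agents are instructed on (and use) the
#' true transition probabilities, so planning reads them from the task.
#'
#' @param task A [make_task()] object.
#' @param model A [model_spec()] object.
#' @return A list value store.
#' @export
init_store <- function(task, model) {
  reward_based <- task$representation == "reward_based"
  list(
    qmf1 = c(0, 0),
    qmf2 = matrix(0, nrow = 3, ncol = 2),
    rprime = rep(if (reward_based) 0.5 else 0, task$n_channels),
    pseq = if (reward_based) rep(0.5, 4) else NULL,
    qmf_seq = rep(0, 4),
    prev_a1 = 0L,
    prev_a2 = 0L
  )
}

#' Model-based values for every option
#'
#' Computes the model-based value of each Stage-2 action in each state, each
#' Stage-1 single-step action, and (for sequence models) each of the four
#' action sequences.
#'
#' Stage-2 pairs are valued at the learned expected reward of their terminal
#' channel. Stage-1 single actions are valued by the Bellman recursion: the
#' transition-probability-weighted expectation, over reachable Stage-2
#' states, of the best Stage-2 value there. A sequence is valued as the
#' expectation over its open-loop outcome distribution: in the path-based
#' representation, the transition-weighted learned reward of the terminal
#' channel its fixed Stage-2 action would reach; in the reward-based
#' representation, its learned reward probability.
#'
#' @param store A value store (see [init_store()]).
#' @inheritParams init_store
#' @return List with `q2` (3 x 2 matrix of Stage-2 values by state), `q1`
#'   (length-2 vector for L1/R1), and `q_seq` (length-4 vector, or `NULL`
#'   for models without sequences).
#' @export
mb_values <- function(store, task, model) {
  cp <- task$common_prob
  rp <- task$rare_prob
  q2 <- matrix(store$rprime[channel_index(rep(1:3, 2), rep(1:2, each = 3))],
    nrow = 3, ncol = 2
  )
  if (task$n_channels < 5L) q2[3, ] <- 0 # no red state in this task
  q1 <- vapply(1:2, function(a1) {
    cp * max(q2[a1, ]) + rp * max(q2[rare_state(task, a1), ])
  }, numeric(1))
  q_seq <- NULL
  if (model$uses_sequences) {
    if (task$representation == "reward_based") {
      q_seq <- store$pseq
    } else {
      q_seq <- vapply(1:4, function(k) {
        a1 <- seq_first(k)
        a2 <- seq_second(k)
        cp * q2[a1, a2] + rp * q2[rare_state(task, a1), a2]
      }, numeric(1))
    }
  }
  list(q2 = q2, q1 = q1, q_seq = q_seq)
}

#' Convex combination of model-based and model-free values
#'
#' `Q_combined = omega * Q_MB + (1 - omega) * Q_MF`, elementwise. The two
#' inputs must describe the same option set.
#'
#' @param q_mb,q_mf Numeric vectors (or matrices) of equal shape; if both are
#'   named, the names must agree.
#' @param omega Mixture weight in \[0, 1\].
#' @return The combined values, same shape as the inputs.
#' @examples
#' combine_q(c(a = 2, b = 0), c(a = 0, b = 1), omega = 0.5)
#' @export
combine_q <- function(q_mb, q_mf, omega) {
  if (length(q_mb) != length(q_mf)) {
    stop("q_mb and q_mf must describe the same option set.", call. = FALSE)
  }
  if (!is.null(names(q_mb)) && !is.null(names(q_mf)) &&
    !identical(names(q_mb), names(q_mf))) {
    stop("q_mb and q_mf have mismatched option names.", call. = FALSE)
  }
  stopifnot(omega >= 0, omega <= 1)
  omega * q_mb + (1 - omega) * q_mf
}

#' Softmax choice probabilities with a stay bonus
#'
#' `P(a) = exp(beta * Q(a) + nu * stay(a)) / sum(...)`, evaluated with
#' max-subtraction so large `beta * Q` cannot overflow. The stay bonus `nu`
#' is added to the logit of every option flagged in `stay` (those sharing the
#' previous trial's first-stage action, in Stage-1 use).
#'
#' @param q Numeric vector of option values.
#' @param beta Inverse temperature, >= 0.
#' @param nu Stay bonus (log-odds units).
#' @param stay Logical vector marking which options receive the bonus
#'   (default: none).
#' @return Probability vector summing to 1.
#' @examples
#' choice_probs(c(1, 0), beta = 1)
#' @export
choice_probs <- function(q, beta, nu = 0, stay = NULL) {
  if (length(q) == 0) stop("Empty option set.", call. = FALSE)
  stopifnot(all(is.finite(q)), beta >= 0)
  z <- beta * q
  if (!is.null(stay)) {
    stopifnot(length(stay) == length(q))
    z <- z + nu * as.numeric(stay)
  }
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Model-free Q-learning update for one trial
#'
#' Applies the within-trial Q-learning updates to the store's cached
#' model-free values, given the trial's transition record:
#'
#' * Stage-1: `Q(s1, a1) += alpha * (max_a' Q(s2, a') - Q(s1, a1))`,
#'   evaluated at transition time (before the Stage-2 value is revised).
#' * Stage-2: `Q(s2, a2) += alpha * delta2` with `delta2 = r - Q(s2, a2)`.
#' * Eligibility trace: `Q(s1, a1) += alpha * lam * delta2`, passing the
#'   Stage-2 reward prediction error back to the Stage-1 action.
#' * Sequence cache (models with model-free sequence control): the matching
#'   sequence's cached value moves toward the terminal reward with rate
#'   `alpha` (one prediction error for one temporally extended action; the
#'   eligibility trace does not apply).
#'
#' @param store A value store.
#' @param params An [agent_params()] vector.
#' @param model A [model_spec()] object.
#' @param a1,s2,a2 Integer codes of the trial's Stage-1 action, Stage-2
#'   state, Stage-2 action.
#' @param r Scalar reward.
#' @param update_components Update the single-step values (set `FALSE` when a
#'   chunked trial in the reward-based representation leaves the Stage-2
#'   state unobserved).
#' @param update_sequence Update the model-free sequence cache.
#' @return The updated store.
#' @export
mf_update <- function(store, params, model, a1, s2, a2, r,
                      update_components = TRUE, update_sequence = TRUE) {
  alpha <- params[["alpha"]]
  if (update_components) {
    d1 <- max(store$qmf2[s2, ]) - store$qmf1[a1]
    store$qmf1[a1] <- store$qmf1[a1] + alpha * d1
    d2 <- r - store$qmf2[s2, a2]
    store$qmf2[s2, a2] <- store$qmf2[s2, a2] + alpha * d2
    store$qmf1[a1] <- store$qmf1[a1] + alpha * params[["lam"]] * d2
  }
  if (update_sequence && model$sequence_control == "mixture") {
    k <- (a1 - 1L) * 2L + a2
    store$qmf_seq[k] <- store$qmf_seq[k] + alpha * (r - store$qmf_seq[k])
  }
  store
}

# Model-based reward-model update (delta rule with the shared learning rate).
# In the path-based representation the terminal state always reveals the
# channel; in the reward-based representation a chunked trial updates only the
# sequence's reward probability.
mb_update <- function(store, task, model, params, a1, s2, a2, r, chunked) {
  alpha <- params[["alpha"]]
  reward_based <- task$representation == "reward_based"
  if (!reward_based || !chunked) {
    ch <- channel_index(s2, a2)
    store$rprime[ch] <- store$rprime[ch] + alpha * (r - store$rprime[ch])
  }
  if (reward_based && model$uses_sequences &&
    (chunked || model$update_sequences_from_components)) {
    k <- (a1 - 1L) * 2L + a2
    store$pseq[k] <- store$pseq[k] + alpha * (r - store$pseq[k])
  }
  store
}

# Combined stage-1 option values and choice probabilities.
stage1_choice_probs <- function(store, task, model, params) {
  mb <- mb_values(store, task, model)
  omega <- params[["omega"]]
  w_single <- if (model$single_step_control == "mixture") omega else 1
  q_single <- w_single * mb$q1 + (1 - w_single) * store$qmf1
  if (model$uses_sequences) {
    w_seq <- if (model$sequence_control == "mixture") omega else 1
    q_seq <- w_seq * mb$q_seq + (1 - w_seq) * store$qmf_seq
    q <- c(q_single, q_seq)
    first <- c(1L, 2L, seq_first(1:4))
  } else {
    q <- q_single
    first <- c(1L, 2L)
  }
  stay <- if (store$prev_a1 > 0L) first == store$prev_a1 else rep(FALSE, length(q))
  list(
    probs = choice_probs(q, params[["beta1"]], params[["nu"]], stay),
    mb = mb, first = first
  )
}

# Stage-2 choice probabilities in realized state s2 (single-step control).
stage2_choice_probs <- function(store, task, model, params, s2, q2_mb) {
  omega <- params[["omega"]]
  w <- if (model$single_step_control == "mixture") omega else 1
  q <- w * q2_mb[s2, ] + (1 - w) * store$qmf2[s2, ]
  stay <- if (model$stay_bonus_stage2 && store$prev_a2 > 0L) {
    c(1L, 2L) == store$prev_a2
  } else {
    c(FALSE, FALSE)
  }
  choice_probs(q, params[["beta2"]], params[["nu"]], stay)
}

#' Run one full task trial for an agent
#'
#' Draws the Stage-1 option (the two single-step actions plus, for sequence
#' models, the four action sequences) from the Stage-1 softmax; executes the
#' Stage-2 action open-loop if a sequence was chosen (ignoring the realized
#' Stage-2 state) or draws it from the Stage-2 softmax otherwise; samples the
#' transition and reward from the task; applies all model-free and
#' model-based learning updates; and advances the reward walk one step.
#'
#' @inheritParams mf_update
#' @param task A [make_task()] object.
#' @param walk Current reward-walk values.
#' @return List with `record` (a one-trial list: `a1`, `s2`, `a2`, `reward`,
#'   `transition`, `chunked`), the updated `store`, and the advanced `walk`.
#' @export
run_trial <- function(model, params, store, task, walk) {
  s1p <- stage1_choice_probs(store, task, model, params)
  opt <- sample.int(length(s1p$probs), 1L, prob = s1p$probs)
  chunked <- opt > 2L
  a1 <- if (chunked) seq_first(opt - 2L) else opt
  tr <- sample_transition(task, a1)
  s2 <- tr$s2
  a2 <- if (chunked) {
    seq_second(opt - 2L) # open-loop: ignores the realized state
  } else {
    p2 <- stage2_choice_probs(store, task, model, params, s2, s1p$mb$q2)
    sample.int(2L, 1L, prob = p2)
  }
  r <- emit_reward(task, walk, s2, a2)

  components_visible <- !(chunked && task$representation == "reward_based")
  store <- mf_update(store, params, model, a1, s2, a2, r,
    update_components = components_visible,
    update_sequence = chunked ||
      (model$update_sequences_from_components && components_visible)
  )
  store <- mb_update(store, task, model, params, a1, s2, a2, r, chunked)
  store$prev_a1 <- a1
  store$prev_a2 <- a2

  list(
    record = list(
      a1 = a1, s2 = s2, a2 = a2, reward = r,
      transition = tr$transition, chunked = chunked
    ),
    store = store,
    walk = advance_walk(walk, task)
  )
}
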