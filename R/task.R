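# Task variants, transition dynamics, and drifting reward walks.
#
# Internal integer codings used throughout the package:
#   stage-1 actions: 1 = "L1", 2 = "R1"
#   stage-2 states : 1 = "green", 2 = "yellow", 3 = "red" (red-state variant only)
#   stage-2 actions: 1 = "L2", 2 = "R2"
# Terminal reward channels (path-based representation):
#   1 = green-L2, 2 = green-R2, 3 = yellow-L2, 4 = yellow-R2, 5 = red (shared).

STAGE1_ACTIONS <- c("L1", "R1")
STAGE2_ACTIONS <- c("L2", "R2")
STAGE2_STATES <- c("green", "yellow", "red")

#' Define a two-step task variant
#'
#' Constructs the full specification of one of the three task variants:
#'
#' * `"original_binary"`: binary rewards (0/1); each Stage-2 state-action pair
#'   has a reward probability that drifts across trials by a reflecting
#'   Gaussian walk.
#' * `"graded_expt1"`: graded rewards; each Stage-2 state-action pair is worth
#'   a drifting point value on `[-5, 5]` (reflecting Gaussian walk,
#'   `sigma = 1.75`).
#' * `"redstate_expt2"`: as `"graded_expt1"`, except rare transitions from
#'   *both* Stage-1 actions lead (with probability 0.2 each) to a shared red
#'   state whose two actions yield one common drifting outcome value.
#'
#' In every variant a Stage-1 action reaches its designated Stage-2 state
#' (L1 to green, R1 to yellow) with probability 0.8.
#'
#' The `representation` controls how agents encode trial outcomes:
#' `"path_based"` terminal states are identified by the Stage-2 state-action
#' path taken, so a reward is always credited to the channel actually visited;
#' `"reward_based"` terminal states are identified by reward alone, so an
#' agent that executed a chunked action sequence credits the reward to the
#' sequence without registering which Stage-2 state it passed through. The
#' reward-based representation is only plausible for the binary task (a graded
#' task would need one terminal state per point value), so requesting it with
#' a graded variant is an error.
#'
#' @param variant One of `"original_binary"`, `"graded_expt1"`,
#'   `"redstate_expt2"`.
#' @param representation One of `"path_based"`, `"reward_based"`.
#' @param common_prob Probability of the designated (common) transition.
#' @param walk_sigma Standard deviation of the reflecting Gaussian reward walk.
#'   Defaults to 1.75 reward units for graded variants and 0.025 probability
#'   units for the binary variant.
#' @param walk_bounds Length-2 reflection bounds of the walk. Defaults to
#'   `c(-5, 5)` points (graded) or `c(0.25, 0.75)` probability (binary).
#' @param n_trials Session length (default 125 trials).
#'
#' @return An object of class `twostep_task`: a list with elements `variant`,
#'   `representation`, `stage1_actions`, `stage2_states`, `stage2_actions`,
#'   `common_prob`, `rare_prob`, `walk_sigma`, `walk_bounds`, `n_channels`,
#'   and `n_trials`.
#' @examples
#' make_task("graded_expt1")
#' make_task("original_binary", representation = "reward_based")
#' @export
make_task <- function(variant = c("graded_expt1", "original_binary", "redstate_expt2"),
                      representation = c("path_based", "reward_based"),
                      common_prob = 0.8,
                      walk_sigma = NULL,
                      walk_bounds = NULL,
                      n_trials = 125L) {
  variant <- match.arg(variant)
  representation <- match.arg(representation)
  if (representation == "reward_based" && variant != "original_binary") {
    stop(
      "The reward-based terminal-state representation is only supported for ",
      "the 'original_binary' variant: a graded task would require one ",
      "terminal state per point value (eleven states, forty-four transition ",
      "probabilities), which is not a plausible representation.",
      call. = FALSE
    )
  }
  binary <- variant == "original_binary"
  if (is.null(walk_sigma)) walk_sigma <- if (binary) 0.025 else 1.75
  if (is.null(walk_bounds)) walk_bounds <- if (binary) c(0.25, 0.75) else c(-5, 5)
  stopifnot(
    length(walk_bounds) == 2, walk_bounds[1] < walk_bounds[2],
    walk_sigma >= 0, common_prob > 0, common_prob < 1, n_trials >= 1
  )
  has_red <- variant == "redstate_expt2"
  structure(
    list(
      variant = variant,
      representation = representation,
      stage1_actions = STAGE1_ACTIONS,
      stage2_states = if (has_red) STAGE2_STATES else STAGE2_STATES[1:2],
      stage2_actions = STAGE2_ACTIONS,
      common_prob = common_prob,
      rare_prob = 1 - common_prob,
      walk_sigma = walk_sigma,
      walk_bounds = walk_bounds,
      n_channels = if (has_red) 5L else 4L,
      n_trials = as.integer(n_trials)
    ),
    class = "twostep_task"
  )
}

#' @export
print.twostep_task <- function(x, ...) {
  cat("<twostep_task>\n")
  cat("  variant        :", x$variant, "\n")
  cat("  representation :", x$representation, "\n")
  cat(
    "  transitions    : common", x$common_prob, "/ rare", x$rare_prob,
    if (x$variant == "redstate_expt2") "(rare -> shared red state)" else "", "\n"
  )
  cat(
    "  reward walk    : sigma", x$walk_sigma, "on [",
    x$walk_bounds[1], ",", x$walk_bounds[2], "],",
    x$n_channels, "channels\n"
  )
  cat("  session length :", x$n_trials, "trials\n")
  invisible(x)
}

#' Initialize the drifting reward walk
#'
#' Draws the starting value of every terminal reward channel independently and
#' uniformly over the walk bounds. For the binary variant the channels hold
#' per-pair reward *probabilities*; for graded variants they hold point
#' values, with channel 5 the shared red-state outcome in the red-state
#' variant.
#'
#' @param task A [make_task()] object.
#' @return Numeric vector of length `task$n_channels`.
#' @export
init_walk <- function(task) {
  stats::runif(task$n_channels, task$walk_bounds[1], task$walk_bounds[2])
}

# Reflect values into [lo, hi]; total reflection (handles steps larger than
# the interval width).
reflect_bounds <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Advance the reward walk by one step
#'
#' Perturbs every channel by an independent Gaussian step (mean 0,
#' `task$walk_sigma`) and reflects the result at the walk bounds, so the
#' output always lies inside them. One step is taken between consecutive
#' trials.
#'
#' @param walk Numeric vector of current channel values (see [init_walk()]).
#' @inheritParams init_walk
#' @return Numeric vector of the same length, inside the bounds.
#' @export
advance_walk <- function(walk, task) {
  stopifnot(length(walk) == task$n_channels)
  if (task$walk_sigma == 0) {
    return(walk)
  }
  reflect_bounds(
    walk + stats::rnorm(length(walk), 0, task$walk_sigma),
    task$walk_bounds[1], task$walk_bounds[2]
  )
}

#' Sample a Stage-1 transition
#'
#' With probability `common_prob` the designated state is reached (L1 to
#' green, R1 to yellow); otherwise the rare branch fires: the other
#' green/yellow state in the standard variants, the shared red state in the
#' red-state variant.
#'
#' @inheritParams init_walk
#' @param a1 Integer Stage-1 action (1 = L1, 2 = R1).
#' @return List with integer `s2` (1 = green, 2 = yellow, 3 = red) and
#'   `transition` (`"common"` or `"rare"`).
#' @export
sample_transition <- function(task, a1) {
  stopifnot(a1 %in% c(1L, 2L))
  common <- stats::runif(1) < task$common_prob
  s2 <- if (common) {
    a1 # designated: L1 -> green(1), R1 -> yellow(2)
  } else if (task$variant == "redstate_expt2") {
    3L
  } else {
    3L - a1
  }
  list(s2 = as.integer(s2), transition = if (common) "common" else "rare")
}

# Terminal channel index for a realized (s2, a2) path. Red state (s2 = 3)
# maps to the single shared channel regardless of a2.
channel_index <- function(s2, a2) {
  ifelse(s2 == 3L, 5L, (s2 - 1L) * 2L + a2)
}

#' Emit a trial reward
#'
#' Binary variant: a Bernoulli draw with the current reward probability of the
#' realized (Stage-2 state, action) pair. Graded variants: the current point
#' value of the realized channel; in the red state both actions yield the
#' shared red-channel value.
#'
#' @inheritParams init_walk
#' @param walk Current walk values.
#' @param s2 Integer Stage-2 state.
#' @param a2 Integer Stage-2 action.
#' @return Scalar reward.
#' @export
emit_reward <- function(task, walk, s2, a2) {
  ch <- channel_index(s2, a2)
  stopifnot(ch <= task$n_channels)
  if (task$variant == "original_binary") {
    as.numeric(stats::runif(1) < walk[ch])
  } else {
    walk[ch]
  }
}
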