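# The five candidate models: identity and parameter handling.

MODEL_NAMES <- c(
  "No sequences",
  "Pure MB",
  "Mixture-actions/MB-sequences",
  "MB-actions/Mixture-sequences",
  "Mixture-actions/Mixture-sequences"
)

#' Specify one of the five candidate models
#'
#' The candidate space crosses (a) whether the agent can select chunked
#' action sequences at Stage 1 and (b) whether single-step actions and
#' sequences are valued purely model-based or by a convex model-based /
#' model-free mixture:
#'
#' | name | sequences | single-step control | sequence control |
#' |---|---|---|---|
#' | `"No sequences"` | no | mixture | -- |
#' | `"Pure MB"` | yes | MB | MB |
#' | `"Mixture-actions/MB-sequences"` | yes | mixture | MB |
#' | `"MB-actions/Mixture-sequences"` | yes | MB | mixture |
#' | `"Mixture-actions/Mixture-sequences"` | yes | mixture | mixture |
#'
#' A single mixture weight `omega` is shared by every controller the model
#' mixes (`omega = 1` is pure model-based). By default sequence value caches
#' are also updated when the agent happens to choose the sequence's component
#' actions one at a time (`update_sequences_from_components`); set it to
#' `FALSE` to update sequences only after chunked execution.
#'
#' @param name A model name (see table); partial matching is not performed.
#' @param update_sequences_from_components Update sequence-level values from
#'   component single-step choices (default `TRUE`).
#' @param stay_bonus_stage2 Also apply the stay bonus to Stage-2 choices
#'   (keyed on the previous trial's Stage-2 action). Default `FALSE`: the
#'   bonus acts only on the Stage-1 option set, the standard perseveration
#'   convention. A shared Stage-2 bonus couples Stage-1 and Stage-2
#'   repetition through one parameter and thereby imitates a weak
#'   sequence-like correlation even in models without sequences.
#' @return An object of class `twostep_model`.
#' @examples
#' model_spec("Pure MB")
#' @export
model_spec <- function(name, update_sequences_from_components = TRUE,
                       stay_bonus_stage2 = FALSE) {
  if (!name %in% MODEL_NAMES) {
    stop(
      "Unknown model '", name, "'. Available models: ",
      paste0("'", MODEL_NAMES, "'", collapse = ", "),
      call. = FALSE
    )
  }
  uses_sequences <- name != "No sequences"
  single_step_control <- if (name %in% c("Pure MB", "MB-actions/Mixture-sequences")) "MB" else "mixture"
  sequence_control <- if (!uses_sequences) {
    "none"
  } else if (name %in% c("Pure MB", "Mixture-actions/MB-sequences")) {
    "MB"
  } else {
    "mixture"
  }
  structure(
    list(
      name = name,
      uses_sequences = uses_sequences,
      single_step_control = single_step_control,
      sequence_control = sequence_control,
      update_sequences_from_components = isTRUE(update_sequences_from_components),
      stay_bonus_stage2 = isTRUE(stay_bonus_stage2)
    ),
    class = "twostep_model"
  )
}

#' @export
print.twostep_model <- function(x, ...) {
  cat("<twostep_model>", x$name, "\n")
  cat("  uses sequences      :", x$uses_sequences, "\n")
  cat("  single-step control :", x$single_step_control, "\n")
  cat("  sequence control    :", x$sequence_control, "\n")
  cat("  seq update from components:", x$update_sequences_from_components, "\n")
  invisible(x)
}

#' List the five candidate model names
#'
#' @return Character vector of the model names accepted by [model_spec()].
#' @export
list_models <- function() MODEL_NAMES

# Does the model make any use of a given parameter?
PARAM_NAMES <- c("alpha", "beta1", "beta2", "nu", "omega", "lam")

model_uses_param <- function(model) {
  mixes <- model$single_step_control == "mixture" ||
    model$sequence_control == "mixture"
  c(
    alpha = TRUE, beta1 = TRUE, beta2 = TRUE, nu = TRUE,
    omega = mixes,
    # the eligibility trace only exists for single-step MF values
    lam = model$single_step_control == "mixture"
  )
}

#' Assemble and validate an agent parameter point
#'
#' @param alpha Learning rate, in (0, 1).
#' @param beta1,beta2 Stage-1 / Stage-2 softmax inverse temperatures, >= 0.
#' @param nu Stay bonus (log-odds units; any real number).
#' @param omega Model-based mixture weight in \[0, 1\] (1 = pure MB).
#' @param lam Eligibility-trace decay in \[0, 1\].
#' @return A named numeric vector of class `twostep_params`.
#' @examples
#' agent_params(alpha = 0.4, beta1 = 5, beta2 = 5, nu = 0.2, omega = 0.6, lam = 0.5)
#' @export
agent_params <- function(alpha, beta1, beta2, nu, omega = 1, lam = 0) {
  p <- c(
    alpha = alpha, beta1 = beta1, beta2 = beta2, nu = nu,
    omega = omega, lam = lam
  )
  if (any(!is.finite(p))) stop("All parameters must be finite.", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1).", call. = FALSE)
  if (beta1 < 0 || beta2 < 0) stop("Inverse temperatures must be >= 0.", call. = FALSE)
  if (omega < 0 || omega > 1) stop("omega must lie in [0, 1].", call. = FALSE)
  if (lam < 0 || lam > 1) stop("lam must lie in [0, 1].", call. = FALSE)
  structure(p, class = "twostep_params")
}
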