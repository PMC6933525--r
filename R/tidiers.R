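# broom-style tidiers and ggplot2 methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a signature regression
#'
#' @param x A `twostep_signature` object.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @method tidy twostep_signature
#' @export
tidy.twostep_signature <- function(x, ...) x$terms

#' @rdname tidy.twostep_signature
#' @method glance twostep_signature
#' @export
glance.twostep_signature <- function(x, ...) {
  tibble::tibble(
    analysis = x$analysis, backend = x$backend,
    n_subjects = x$n_subjects, n_subjects_total = x$n_subjects_total,
    n_obs = x$n_obs
  )
}

#' Tidy a subject-level MAP fit
#'
#' @param x A `twostep_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per parameter: `term`, `estimate`, `free`.
#' @method tidy twostep_fit
#' @export
tidy.twostep_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$params_map),
    estimate = as.numeric(x$params_map),
    free = names(x$params_map) %in% x$free
  )
}

#' @rdname tidy.twostep_fit
#' @method glance twostep_fit
#' @export
glance.twostep_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model$name,
    log_likelihood = x$log_likelihood,
    log_posterior = x$log_posterior,
    log_evidence = as.numeric(laplace_evidence(x)),
    n_trials = x$n_trials,
    n_free = length(x$free),
    converged = x$converged
  )
}

#' Tidy a model-selection result
#'
#' @param x A `twostep_bms` object.
#' @param ... Unused.
#' @return Tibble with `model`, `frequency`, `ep`, `pxp`.
#' @method tidy twostep_bms
#' @export
tidy.twostep_bms <- function(x, ...) {
  tibble::tibble(
    model = x$models, frequency = x$frequency, ep = x$ep, pxp = x$pxp
  )
}

#' @rdname tidy.twostep_bms
#' @method glance twostep_bms
#' @export
glance.twostep_bms <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects, bor = x$bor)
}

#' Coefficient plot for a signature regression
#'
#' Forest plot of the fixed-effect estimates with 95% Wald intervals.
#'
#' @param object A `twostep_signature` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot twostep_signature
#' @export
autoplot.twostep_signature <- function(object, ...) {
  d <- dplyr::filter(object$terms, .data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$estimate, y = .data$term,
    xmin = .data$estimate - 1.96 * .data$std.error,
    xmax = .data$estimate + 1.96 * .data$std.error
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange() +
    ggplot2::labs(
      title = object$analysis,
      x = "coefficient (95% CI)", y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Model-frequency plot for a model-selection result
#'
#' @param object A `twostep_bms` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot twostep_bms
#' @export
autoplot.twostep_bms <- function(object, ...) {
  d <- tidy(object) |>
    tidyr::pivot_longer(c("frequency", "pxp"), names_to = "quantity")
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$model, y = .data$value, fill = .data$quantity
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Stay-probability summary plot
#'
#' Stage-1 stay probability by previous reward (sign-binned for display) and
#' previous transition type, averaged within subject then across subjects --
#' the classic two-step bar plot.
#'
#' @param data A trial table.
#' @return A ggplot object.
#' @export
plot_stay_probability <- function(data) {
  d <- derive_lagged(data) |>
    dplyr::filter(!is.na(.data$prev_reward)) |>
    dplyr::mutate(prev_reward_bin = bin_reward(.data$prev_reward)) |>
    dplyr::group_by(.data$subject, .data$prev_reward_bin, .data$prev_transition) |>
    dplyr::summarise(stay = mean(.data$stay1), .groups = "drop") |>
    dplyr::group_by(.data$prev_reward_bin, .data$prev_transition) |>
    dplyr::summarise(
      p_stay = mean(.data$stay),
      sem = stats::sd(.data$stay) / sqrt(dplyr::n()), .groups = "drop"
    )
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$prev_reward_bin, y = .data$p_stay, fill = .data$prev_transition
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$p_stay - .data$sem,
        ymax = .data$p_stay + .data$sem
      ),
      position = ggplot2::position_dodge(0.9), width = 0.2
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "previous reward", y = "P(repeat Stage-1 choice)",
      fill = "previous transition"
    ) +
    ggplot2::theme_minimal()
}

#' Stay probability as a function of graded reward
#'
#' Stage-1 stay probability for each previous-reward value (rounded to the
#' nearest point), on trials following common transitions -- the diagnostic
#' that subjects track the full reward scale.
#'
#' @param data A trial table (graded task).
#' @return A ggplot object.
#' @export
plot_stay_by_reward <- function(data) {
  d <- derive_lagged(data) |>
    dplyr::filter(!is.na(.data$prev_reward), .data$prev_transition == "common") |>
    dplyr::mutate(reward_bin = round(.data$prev_reward)) |>
    dplyr::group_by(.data$subject, .data$reward_bin) |>
    dplyr::summarise(stay = mean(.data$stay1), .groups = "drop") |>
    dplyr::group_by(.data$reward_bin) |>
    dplyr::summarise(
      p_stay = mean(.data$stay),
      sem = stats::sd(.data$stay) / sqrt(dplyr::n()), .groups = "drop"
    )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$reward_bin, y = .data$p_stay)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$p_stay - .data$sem,
      ymax = .data$p_stay + .data$sem
    )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "previous reward (points)", y = "P(repeat Stage-1 choice)") +
    ggplot2::theme_minimal()
}
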