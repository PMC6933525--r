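# One-trial-back behavioral signature analyses.
#
# All regressions use centered predictors: continuous previous reward is
# mean-centered over the analyzed table, and binary predictors are coded
# +/- 0.5 (common = +0.5, rare = -0.5; repeat = +0.5, switch = -0.5), so main
# effects are evaluated at the average of the other factors. Reward always
# enters inference as its raw (unbinned) value; sign-binning exists only for
# display and the graded-vs-binned comparison.

#' Add one-trial-back lag columns
#'
#' For each subject (trials sorted and consecutive), adds the previous
#' trial's reward, transition, Stage-1 choice, Stage-2 state and choice, plus
#' the repetition indicators `stay1` (Stage-1 choice repeated) and `stay2`
#' (Stage-2 action label repeated). The first trial of each subject has
#' missing lags and is excluded by the downstream analyses.
#'
#' @param data A trial table (see [simulate_cohort()]): columns `subject`,
#'   `trial`, `s1_choice`, `transition`, `s2_state`, `s2_choice`, `reward`.
#' @return The table with lag columns added.
#' @export
derive_lagged <- function(data) {
  if (anyDuplicated(data[c("subject", "trial")])) {
    stop("Duplicate (subject, trial) keys in trial table.", call. = FALSE)
  }
  data |>
    dplyr::arrange(.data$subject, .data$trial) |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(
      prev_reward = dplyr::lag(.data$reward),
      prev_transition = dplyr::lag(.data$transition),
      prev_s1_choice = dplyr::lag(.data$s1_choice),
      prev_s2_state = dplyr::lag(.data$s2_state),
      prev_s2_choice = dplyr::lag(.data$s2_choice),
      stay1 = as.numeric(.data$s1_choice == .data$prev_s1_choice),
      stay2 = as.numeric(.data$s2_choice == .data$prev_s2_choice)
    ) |>
    dplyr::ungroup()
}

has_lags <- function(data) all(c("prev_reward", "stay1") %in% names(data))

#' Sign-bin a graded reward
#'
#' Display/comparison binning of graded rewards into positive and negative
#' categories. Zero is assigned to `"negative"` (a fixed convention; zero
#' rewards occur with probability zero under the continuous walk). Inference
#' always uses the unbinned reward.
#'
#' @param reward Numeric vector of rewards.
#' @return Factor with levels `"negative"`, `"positive"`.
#' @examples
#' bin_reward(c(3.2, -0.5, 0))
#' @export
bin_reward <- function(reward) {
  factor(ifelse(reward > 0, "positive", "negative"),
    levels = c("negative", "positive")
  )
}

#' Restrict to the sequence-diagnostic trials
#'
#' Keeps trials where (i) the previous trial's transition matched
#' `prev_transition` (default `"common"`) and (ii) the current Stage-2 state
#' differs from the previous trial's Stage-2 state. The state-change
#' restriction removes the attention/arousal confound for the Stage-2
#' signatures: an agent choosing single-step actions cannot carry a learned
#' Stage-2 preference into a different Stage-2 state, while an agent on
#' open-loop autopilot is unaffected by the state change. Use
#' `prev_transition = "rare"` for the red-state design's post-rare analyses
#' and `"any"` when previous transition type enters the regression itself.
#'
#' @param data A trial table; lag columns are added if absent.
#' @param prev_transition `"common"`, `"rare"`, or `"any"`.
#' @return The filtered, lagged table (possibly empty).
#' @export
filter_sequence_trials <- function(data, prev_transition = c("common", "rare", "any")) {
  prev_transition <- match.arg(prev_transition)
  if (!has_lags(data)) data <- derive_lagged(data)
  out <- data |>
    dplyr::filter(
      !is.na(.data$prev_transition),
      .data$s2_state != .data$prev_s2_state
    )
  if (prev_transition != "any") {
    out <- dplyr::filter(out, .data$prev_transition == .env$prev_transition)
  }
  out
}

# ---- regression backends -----------------------------------------------
#
# Three estimators:
#  * two_stage_fit: per-subject GLM/LM fits, group-level one-sample t-test on
#    the per-subject coefficients (random-effects summary-statistics). Used
#    for the Stage-1 stay analyses, where every subject supplies ~124 trials.
#  * cluster_fit: pooled GLM/LM with CR0 cluster-robust (by subject)
#    standard errors -- a GEE-style population-averaged estimator. Used for
#    the Stage-2 analyses, whose trial-restriction filters leave too few
#    trials per subject for stable subject-level fits.
#  * mixed_fit: lme4 random-slopes mixed model (optional backend).

two_stage_fit <- function(data, formula, family, se_max = 25) {
  terms_obj <- stats::terms(formula)
  n_par <- length(attr(terms_obj, "term.labels")) + attr(terms_obj, "intercept")
  outcome <- all.vars(formula)[1]
  fits <- data |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_map(function(d, key) {
      if (nrow(d) < n_par + 3) {
        return(NULL)
      }
      if (stats::var(d[[outcome]]) == 0) {
        return(NULL)
      }
      fit <- tryCatch(
        suppressWarnings(
          if (identical(family, "gaussian")) {
            stats::lm(formula, data = d)
          } else {
            stats::glm(formula, data = d, family = stats::binomial())
          }
        ),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        return(NULL)
      }
      sm <- summary(fit)$coefficients
      if (nrow(sm) < n_par) {
        return(NULL)
      }
      tibble::tibble(
        subject = key$subject, term = rownames(sm),
        estimate = sm[, 1], se = sm[, 2]
      )
    }) |>
    dplyr::bind_rows()
  if (nrow(fits) == 0) {
    stop("No subject-level fits could be estimated (degenerate input).", call. = FALSE)
  }
  usable <- fits |>
    dplyr::group_by(.data$subject) |>
    dplyr::filter(all(is.finite(.data$estimate) & is.finite(.data$se) & .data$se < se_max)) |>
    dplyr::ungroup()
  n_used <- dplyr::n_distinct(usable$subject)
  if (n_used < 2) {
    stop("Fewer than 2 usable subjects for the group-level test.", call. = FALSE)
  }
  # Random-effects group test: each subject contributes one coefficient per
  # term; the group mean is tested against zero with a one-sample t-test.
  # (Between-subject slope heterogeneity is real in these cohorts, so a
  # fixed-effect precision-weighted mean would be anti-conservative.)
  terms_tbl <- usable |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      std.error = stats::sd(.data$estimate) / sqrt(dplyr::n()),
      estimate = mean(.data$estimate),
      df = dplyr::n() - 1,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      statistic = .data$estimate / .data$std.error,
      p.value = 2 * stats::pt(-abs(.data$statistic), df = .data$df)
    ) |>
    dplyr::select("term", "estimate", "std.error", "statistic", "df", "p.value")
  list(
    terms = terms_tbl,
    n_subjects = n_used,
    n_subjects_total = dplyr::n_distinct(data$subject),
    n_obs = nrow(data),
    subject_fits = usable
  )
}

cluster_fit <- function(data, formula, family) {
  fit <- if (identical(family, "gaussian")) {
    stats::lm(formula, data = data)
  } else {
    stats::glm(formula, data = data, family = stats::binomial())
  }
  X <- stats::model.matrix(fit)
  res <- stats::residuals(fit, type = "response")
  w <- if (identical(family, "gaussian")) {
    rep(1, nrow(X))
  } else {
    mu <- stats::fitted(fit)
    mu * (1 - mu)
  }
  bread <- solve(crossprod(X * sqrt(w)))
  scores <- rowsum(X * res, data$subject)
  V <- bread %*% crossprod(as.matrix(scores)) %*% bread
  b <- stats::coef(fit)
  se <- sqrt(diag(V))
  terms_tbl <- tibble::tibble(
    term = names(b), estimate = as.numeric(b), std.error = se,
    df = NA_integer_,
    statistic = as.numeric(b) / se,
    p.value = 2 * stats::pnorm(-abs(as.numeric(b) / se))
  )
  list(
    terms = terms_tbl,
    n_subjects = dplyr::n_distinct(data$subject),
    n_subjects_total = dplyr::n_distinct(data$subject),
    n_obs = nrow(data),
    subject_fits = NULL
  )
}

mixed_fit <- function(data, formula, family, drop_re_correlations = FALSE) {
  if (!requireNamespace("lme4", quietly = TRUE)) {
    stop("The mixed-model backend requires the 'lme4' package.", call. = FALSE)
  }
  preds <- attr(stats::terms(formula), "term.labels")
  preds <- preds[!grepl(":", preds)]
  bar <- if (drop_re_correlations) "||" else "|"
  re <- paste0("(1 + ", paste(preds, collapse = " + "), " ", bar, " subject)")
  f <- stats::update(formula, paste(". ~ . +", re))
  fit <- if (identical(family, "gaussian")) {
    lme4::lmer(f, data = data, REML = FALSE)
  } else {
    lme4::glmer(f, data = data, family = stats::binomial())
  }
  sm <- summary(fit)$coefficients
  terms_tbl <- tibble::tibble(
    term = rownames(sm), estimate = unname(sm[, 1]), std.error = unname(sm[, 2]),
    df = NA_integer_,
    statistic = unname(sm[, 1] / sm[, 2]),
    p.value = unname(2 * stats::pnorm(-abs(sm[, 1] / sm[, 2])))
  )
  list(
    terms = terms_tbl, n_subjects = dplyr::n_distinct(data$subject),
    n_subjects_total = dplyr::n_distinct(data$subject),
    n_obs = nrow(data), subject_fits = NULL
  )
}

run_signature <- function(data, formula, family, backend, analysis,
                          drop_re_correlations = FALSE) {
  res <- switch(backend,
    two_stage = two_stage_fit(data, formula, family),
    cluster = cluster_fit(data, formula, family),
    mixed = mixed_fit(data, formula, family, drop_re_correlations)
  )
  structure(
    c(res, list(
      analysis = analysis, formula = formula, backend = backend,
      family = family
    )),
    class = "twostep_signature"
  )
}

#' @export
print.twostep_signature <- function(x, ...) {
  cat(
    "<twostep_signature>", x$analysis, "(", x$backend, "backend,",
    x$n_subjects, "of", x$n_subjects_total, "subjects,", x$n_obs, "trials )\n"
  )
  print(as.data.frame(x$terms), digits = 3)
  invisible(x)
}

# Common preparation: lag, drop missing lags, add centered regressors.
prepare_lagged <- function(data, need_rt = FALSE) {
  if (need_rt && !("rt2" %in% names(data))) {
    stop("This analysis needs a Stage-2 reaction-time column 'rt2'.", call. = FALSE)
  }
  if (!has_lags(data)) data <- derive_lagged(data)
  data <- dplyr::filter(data, !is.na(.data$prev_reward))
  if (nrow(data) < 2 || stats::var(data$prev_reward) == 0) {
    stop("Previous reward is constant: degenerate predictor.", call. = FALSE)
  }
  dplyr::mutate(data,
    prev_reward_c = .data$prev_reward - mean(.data$prev_reward),
    prev_common = ifelse(.data$prev_transition == "common", 0.5, -0.5),
    stay1_c = .data$stay1 - 0.5,
    stay2_c = .data$stay2 - 0.5,
    switch2_c = 0.5 - .data$stay2 # +0.5 when the Stage-2 action changed
  )
}

#' Stage-1 stay regression (model-free signature)
#'
#' Regresses the Stage-1 repetition indicator on the previous trial's reward,
#' the previous transition type, and their interaction. A positive main
#' effect of previous reward is the classic signature of model-free control;
#' a positive reward-by-transition interaction is the signature of
#' model-based control.
#'
#' @param data A trial table (lag columns added if absent).
#' @param backend `"two_stage"` (per-subject fits + across-subject t-test;
#'   default for the Stage-1 analyses), `"cluster"` (pooled fit with
#'   by-subject cluster-robust standard errors; default for the filtered
#'   Stage-2 analyses), or `"mixed"` (lme4 random-slopes model with Wald
#'   z-tests).
#' @return A `twostep_signature` object; see [tidy.twostep_signature()].
#' @export
stay1_signature <- function(data, backend = c("two_stage", "cluster", "mixed")) {
  backend <- match.arg(backend)
  data <- prepare_lagged(data)
  run_signature(data, stay1 ~ prev_reward_c * prev_common, "binomial",
    backend,
    analysis = "stay1 ~ prev_reward * prev_transition"
  )
}

#' Stage-1 stay after rare transitions (red-state design)
#'
#' Restricts to trials whose previous transition was rare (i.e., passed
#' through the shared red state in the red-state variant) and regresses the
#' Stage-1 repetition indicator on the previous reward. Because both Stage-1
#' actions reach the red state with equal probability, a model-based
#' controller is unaffected by red-state outcomes; a positive reward effect
#' here is therefore an unconfounded model-free signature.
#'
#' @inheritParams stay1_signature
#' @return A `twostep_signature` object.
#' @export
expt2_stay1_after_rare <- function(data, backend = c("two_stage", "cluster", "mixed")) {
  backend <- match.arg(backend)
  data <- prepare_lagged(data) |>
    dplyr::filter(.data$prev_transition == "rare")
  if (nrow(data) == 0) stop("No post-rare trials to analyze.", call. = FALSE)
  run_signature(data, stay1 ~ prev_reward_c, "binomial",
    backend,
    analysis = "stay1 ~ prev_reward | previous transition rare"
  )
}

#' Stage-2 choice signature of action sequences
#'
#' On the sequence-diagnostic trials (see [filter_sequence_trials()]),
#' regresses the Stage-2 repetition indicator on the Stage-1 repetition
#' indicator, the previous reward, and their interaction. A positive
#' `stay1 x previous reward` interaction -- Stage-1 and Stage-2 repetition
#' more correlated after reward -- is the signature of chunked action
#' sequences. With `split_by_prev_transition = TRUE`, previous transition
#' type enters the regression and the three-way interaction tests whether
#' the sequence signature is stronger after common than after rare
#' transitions (the model-based sequence-control prediction in the red-state
#' design).
#'
#' @param data A trial table already passed through
#'   [filter_sequence_trials()] (it is filtered with `prev_transition =
#'   "any"` automatically when `split_by_prev_transition = TRUE`, `"common"`
#'   otherwise, if the filter has not been applied).
#' @param split_by_prev_transition Include previous transition type and its
#'   interactions.
#' @inheritParams stay1_signature
#' @return A `twostep_signature` object.
#' @export
stage2_choice_signature <- function(data, split_by_prev_transition = FALSE,
                                    backend = c("cluster", "two_stage", "mixed")) {
  backend <- match.arg(backend)
  if (!has_lags(data)) {
    data <- filter_sequence_trials(
      data,
      if (split_by_prev_transition) "any" else "common"
    )
  }
  data <- prepare_lagged(data)
  f <- if (split_by_prev_transition) {
    stay2 ~ stay1_c * prev_reward_c * prev_common
  } else {
    stay2 ~ stay1_c * prev_reward_c
  }
  run_signature(data, f, "binomial", backend,
    analysis = paste0(
      "stay2 ~ stay1 * prev_reward",
      if (split_by_prev_transition) " * prev_transition" else ""
    ),
    drop_re_correlations = split_by_prev_transition
  )
}

#' Stage-2 reaction-time signature of action sequences
#'
#' On the sequence-diagnostic trials, models the Stage-2 reaction time as a
#' function of Stage-2 switching (`switch2`, +0.5 when the Stage-2 action
#' label changed), Stage-1 repetition, and previous reward. The diagnostic
#' contrast is the `switch2 x stay1 x previous reward` interaction: the speed
#' gain from repeating (equivalently, the time cost of switching) the
#' Stage-2 action should be largest when the Stage-1 action was repeated
#' after a reward, because open-loop re-execution of a just-rewarded
#' sequence skips the Stage-2 decision. A positive interaction coefficient
#' is therefore the sequence-consistent direction. `formulation =
#' "factorial"` (default) fits the full factorial linear model;
#' `"difference"` models only the `switch2` speed terms.
#'
#' @inheritParams stage2_choice_signature
#' @param formulation `"factorial"` or `"difference"`.
#' @return A `twostep_signature` object (t statistics from the linear model).
#' @export
stage2_rt_signature <- function(data, split_by_prev_transition = FALSE,
                                formulation = c("factorial", "difference"),
                                backend = c("cluster", "two_stage", "mixed")) {
  backend <- match.arg(backend)
  formulation <- match.arg(formulation)
  if (!has_lags(data)) {
    data <- filter_sequence_trials(
      data,
      if (split_by_prev_transition) "any" else "common"
    )
  }
  data <- prepare_lagged(data, need_rt = TRUE)
  if (stats::var(data$rt2) == 0) {
    stop("Stage-2 reaction times are constant: degenerate outcome.", call. = FALSE)
  }
  f <- if (formulation == "factorial") {
    if (split_by_prev_transition) {
      rt2 ~ switch2_c * stay1_c * prev_reward_c * prev_common
    } else {
      rt2 ~ switch2_c * stay1_c * prev_reward_c
    }
  } else {
    if (split_by_prev_transition) {
      rt2 ~ switch2_c + switch2_c:stay1_c + switch2_c:prev_reward_c + switch2_c:prev_common +
        switch2_c:stay1_c:prev_reward_c + switch2_c:stay1_c:prev_common +
        switch2_c:prev_reward_c:prev_common + switch2_c:stay1_c:prev_reward_c:prev_common
    } else {
      rt2 ~ switch2_c + switch2_c:stay1_c + switch2_c:prev_reward_c +
        switch2_c:stay1_c:prev_reward_c
    }
  }
  run_signature(data, f, "gaussian", backend,
    analysis = paste0(
      "rt2 ~ switch2 * stay1 * prev_reward",
      if (split_by_prev_transition) " * prev_transition" else "",
      " (", formulation, ")"
    ),
    drop_re_correlations = TRUE
  )
}

#' Graded versus binned reward representation comparison
#'
#' On trials following a common transition, fits two Stage-1 stay models per
#' subject: one predicting repetition from the previous trial's graded
#' (continuous) reward, one from its sign-binned version, and compares summed
#' AIC. A positive `delta = aic_binned - aic_graded` favors the graded
#' representation (people track the full reward scale rather than a
#' positive/negative category).
#'
#' @inheritParams stay1_signature
#' @return A one-row tibble with `aic_graded`, `aic_binned`, `delta`,
#'   `n_subjects`, and `flagged` (`TRUE` when the rewards are already binary,
#'   making the two models reparameterizations of each other).
#' @export
graded_vs_binned <- function(data) {
  data <- prepare_lagged(data) |>
    dplyr::filter(.data$prev_transition == "common") |>
    dplyr::mutate(prev_bin = ifelse(bin_reward(.data$prev_reward) == "positive", 0.5, -0.5))
  flagged <- length(unique(data$prev_reward)) <= 2
  aics <- data |>
    dplyr::group_by(.data$subject) |>
    dplyr::group_map(function(d, key) {
      if (nrow(d) < 8 || stats::var(d$stay1) == 0 || stats::var(d$prev_bin) == 0) {
        return(NULL)
      }
      f1 <- tryCatch(
        suppressWarnings(stats::glm(stay1 ~ prev_reward_c, binomial(), data = d)),
        error = function(e) NULL
      )
      f2 <- tryCatch(
        suppressWarnings(stats::glm(stay1 ~ prev_bin, binomial(), data = d)),
        error = function(e) NULL
      )
      if (is.null(f1) || is.null(f2)) {
        return(NULL)
      }
      tibble::tibble(aic_graded = stats::AIC(f1), aic_binned = stats::AIC(f2))
    }) |>
    dplyr::bind_rows()
  if (nrow(aics) == 0) stop("No usable subjects for the AIC comparison.", call. = FALSE)
  tibble::tibble(
    aic_graded = sum(aics$aic_graded),
    aic_binned = sum(aics$aic_binned),
    delta = sum(aics$aic_binned) - sum(aics$aic_graded),
    n_subjects = nrow(aics),
    flagged = flagged
  )
}
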