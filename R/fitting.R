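# Trial-level likelihoods, MAP estimation, and Laplace model evidence.
#
# Optimization runs in an unconstrained transformed space (logit for alpha,
# omega, lam; log for beta1, beta2; identity for nu), with the prior densities
# mapped by change of variables. This keeps the Hessian used by the Laplace
# approximation away from boundary pathologies.

# Convert a trial table's label columns to the internal integer codes.
encode_trials <- function(data) {
  list(
    a1 = match(data$s1_choice, STAGE1_ACTIONS),
    s2 = match(data$s2_state, STAGE2_STATES),
    a2 = match(data$s2_choice, STAGE2_ACTIONS),
    reward = as.numeric(data$reward)
  )
}

#' Trial-level log-likelihood of one subject's choices
#'
#' Evaluates the sequential log-likelihood of a subject's observed Stage-1
#' and Stage-2 choices under a model and parameter point, updating values
#' trial by trial exactly as the simulated agents do. For sequence models the
#' unobservable chunked/single execution of each trial is marginalized:
#' `P(a1, a2) = P(sequence a1-a2) + P(single a1) * P(a2 | s2)`. Learning
#' updates treat the Stage-2 path as visible (path-based terminal states
#' reveal it even after open-loop execution), which is the configuration
#' under which the graded tasks are fit.
#'
#' @param data One subject's trial table (single `subject` value), sorted by
#'   trial.
#' @param model A [model_spec()] object.
#' @param task A [make_task()] object.
#' @param params An [agent_params()] vector (or named numeric vector with
#'   elements `alpha`, `beta1`, `beta2`, `nu`, `omega`, `lam`).
#' @return Scalar log-likelihood (<= 0).
#' @export
trial_loglik <- function(data, model, task, params) {
  if (dplyr::n_distinct(data$subject) > 1) {
    stop("trial_loglik evaluates a single subject; got several.", call. = FALSE)
  }
  enc <- encode_trials(data)
  loglik_session_cpp(
    enc$a1, enc$s2, enc$a2, enc$reward,
    as.numeric(params[PARAM_NAMES]),
    model$uses_sequences,
    model$single_step_control == "mixture",
    switch(model$sequence_control, none = 0L, MB = 1L, mixture = 2L),
    task$variant == "redstate_expt2",
    task$representation == "reward_based",
    task$common_prob,
    model$stay_bonus_stage2
  )
}

# Plain-R reference implementation of the same likelihood (used as an
# independent cross-check of the compiled version).
trial_loglik_r <- function(data, model, task, params) {
  enc <- encode_trials(data)
  store <- init_store(task, model)
  ll <- 0
  for (t in seq_along(enc$a1)) {
    a1 <- enc$a1[t]
    s2 <- enc$s2[t]
    a2 <- enc$a2[t]
    s1p <- stage1_choice_probs(store, task, model, params)
    p2 <- stage2_choice_probs(store, task, model, params, s2, s1p$mb$q2)
    p <- s1p$probs[a1] * p2[a2]
    if (model$uses_sequences) {
      k <- (a1 - 1L) * 2L + a2
      p <- p + s1p$probs[2L + k]
    }
    ll <- ll + log(p)
    store <- mf_update(store, params, model, a1, s2, a2, enc$reward[t],
      update_components = TRUE, update_sequence = TRUE
    )
    store <- mb_update(store, task, model, params, a1, s2, a2, enc$reward[t],
      chunked = FALSE
    )
    store$prev_a1 <- a1
    store$prev_a2 <- a2
  }
  ll
}

# ---- parameter transforms and priors -----------------------------------

# natural -> unconstrained
to_unconstrained <- function(p) {
  c(
    alpha = stats::qlogis(p[["alpha"]]),
    beta1 = log(p[["beta1"]]),
    beta2 = log(p[["beta2"]]),
    nu = p[["nu"]],
    omega = stats::qlogis(p[["omega"]]),
    lam = stats::qlogis(p[["lam"]])
  )
}

# unconstrained -> natural
to_natural <- function(x) {
  c(
    alpha = stats::plogis(x[["alpha"]]),
    beta1 = exp(x[["beta1"]]),
    beta2 = exp(x[["beta2"]]),
    nu = x[["nu"]],
    omega = stats::plogis(x[["omega"]]),
    lam = stats::plogis(x[["lam"]])
  )
}

# Log prior density in the transformed space (includes the Jacobian of the
# change of variables). Priors match the simulation priors.
log_prior_unconstrained <- function(x_free, free) {
  lp <- 0
  for (nm in free) {
    x <- x_free[[nm]]
    lp <- lp + switch(nm,
      alpha = {
        p <- stats::plogis(x)
        stats::dbeta(p, 1.1, 1.1, log = TRUE) + log(p) + log1p(-p)
      },
      beta1 = ,
      beta2 = stats::dgamma(exp(x), shape = 1.2, scale = 5, log = TRUE) + x,
      nu = stats::dnorm(x, 0, 1, log = TRUE),
      omega = ,
      lam = {
        p <- stats::plogis(x)
        log(p) + log1p(-p) # Uniform(0,1) prior, Jacobian only
      }
    )
  }
  lp
}

# Draw a start point in the transformed space from the priors.
draw_start <- function(free) {
  full <- c(
    alpha = stats::rbeta(1, 1.1, 1.1),
    beta1 = stats::rgamma(1, 1.2, scale = 5),
    beta2 = stats::rgamma(1, 1.2, scale = 5),
    nu = stats::rnorm(1),
    omega = stats::runif(1),
    lam = stats::runif(1)
  )
  to_unconstrained(full)[free]
}

# Central finite-difference Hessian (step h in transformed units).
fd_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        ej <- replace(numeric(d), j, h)
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) / (4 * h^2)
      }
    }
  }
  H
}

#' Fit a model to one subject by MAP estimation
#'
#' Maximizes log-likelihood plus log prior (the same priors used for
#' simulation) over the model's free parameters in the unconstrained
#' transformed space, restarting the optimizer from `n_restarts` random
#' prior-drawn start points and keeping the best. The curvature (Hessian of
#' the negative log posterior, central finite differences) at the optimum is
#' retained for the Laplace evidence.
#'
#' @inheritParams trial_loglik
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Integer seed controlling the restart draws.
#' @param fixed Optional named list of parameters to hold fixed at given
#'   values (removed from the free set). Parameters the model does not use
#'   are fixed automatically (`omega = 1`, `lam = 0`).
#' @return An object of class `twostep_fit` with elements `params_map`
#'   (natural scale), `x_map` (transformed), `free`, `log_posterior`,
#'   `log_likelihood`, `hessian`, `n_trials`, `converged`,
#'   `n_restarts_used`, and `model`.
#' @export
fit_map <- function(data, model, task, n_restarts = 10, seed = 1, fixed = NULL) {
  if (nrow(data) < 20) {
    stop("Need at least 20 trials for a meaningful fit.", call. = FALSE)
  }
  uses <- model_uses_param(model)
  fixed_full <- c(
    as.list(fixed),
    if (!uses[["omega"]] && is.null(fixed$omega)) list(omega = 1),
    if (!uses[["lam"]] && is.null(fixed$lam)) list(lam = 0)
  )
  free <- setdiff(PARAM_NAMES, names(fixed_full))
  enc <- encode_trials(data)
  mflags <- list(
    uses_seq = model$uses_sequences,
    single_mix = model$single_step_control == "mixture",
    seq_ctrl = switch(model$sequence_control, none = 0L, MB = 1L, mixture = 2L),
    expt2 = task$variant == "redstate_expt2",
    reward_based = task$representation == "reward_based",
    cp = task$common_prob,
    stay2 = model$stay_bonus_stage2
  )
  base <- c(alpha = 0.5, beta1 = 1, beta2 = 1, nu = 0, omega = 1, lam = 0)
  for (nm in names(fixed_full)) base[[nm]] <- fixed_full[[nm]]

  ll_at <- function(x_free) {
    p <- base
    nat <- to_natural(replace(to_unconstrained(base), match(free, PARAM_NAMES), x_free))
    p[free] <- nat[free]
    loglik_session_cpp(
      enc$a1, enc$s2, enc$a2, enc$reward, as.numeric(p[PARAM_NAMES]),
      mflags$uses_seq, mflags$single_mix, mflags$seq_ctrl,
      mflags$expt2, mflags$reward_based, mflags$cp, mflags$stay2
    )
  }
  neg_log_post <- function(x_free) {
    names(x_free) <- free
    ll <- tryCatch(ll_at(x_free), error = function(e) -Inf)
    v <- -(ll + log_prior_unconstrained(x_free, free))
    if (!is.finite(v)) 1e10 else v
  }

  set.seed(derive_seed(seed, 0L))
  best <- NULL
  n_used <- 0L
  for (r in seq_len(n_restarts)) {
    x0 <- draw_start(free)
    res <- tryCatch(
      stats::optim(x0, neg_log_post, method = "BFGS", control = list(maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    n_used <- n_used + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("All optimizer restarts failed.", call. = FALSE)
  }
  x_map <- best$par
  names(x_map) <- free
  params_map <- base
  params_map[free] <- to_natural(
    replace(to_unconstrained(base), match(free, PARAM_NAMES), x_map)
  )[free]
  H <- fd_hessian(neg_log_post, x_map)
  structure(
    list(
      model = model,
      task = task,
      free = free,
      x_map = x_map,
      params_map = params_map,
      log_posterior = -best$value,
      log_likelihood = ll_at(x_map),
      hessian = H,
      n_trials = nrow(data),
      converged = best$convergence == 0 && n_used > 0,
      n_restarts_used = n_used
    ),
    class = "twostep_fit"
  )
}

#' @export
print.twostep_fit <- function(x, ...) {
  cat("<twostep_fit>", x$model$name, "\n")
  cat(
    "  MAP params :",
    paste(names(x$params_map), signif(x$params_map, 3), sep = "=", collapse = " "), "\n"
  )
  cat(
    "  logLik", signif(x$log_likelihood, 6),
    " logPost", signif(x$log_posterior, 6),
    " trials", x$n_trials,
    " converged", x$converged, "\n"
  )
  invisible(x)
}

# Core Laplace formula, shared with tests that build toy posteriors:
# log evidence ~ log_post_at_mode + (d/2) log(2 pi) - 1/2 log det(H),
# H the Hessian of the negative log posterior at the mode.
laplace_log_evidence <- function(log_post_at_mode, hessian) {
  d <- nrow(hessian)
  ridge <- 0
  ch <- tryCatch(chol(hessian), error = function(e) NULL)
  while (is.null(ch) && ridge < 1e-1) {
    ridge <- if (ridge == 0) 1e-6 else ridge * 10
    ch <- tryCatch(chol(hessian + diag(ridge, d)), error = function(e) NULL)
  }
  if (is.null(ch)) stop("Hessian could not be regularized to positive definite.", call. = FALSE)
  le <- log_post_at_mode + d / 2 * log(2 * pi) - sum(log(diag(ch)))
  attr(le, "ridge") <- ridge
  le
}

#' Laplace approximation to a subject's log marginal likelihood
#'
#' `log p(D | m) ~ log p(D, theta_MAP) + (d/2) log(2 pi) - (1/2) log det H`,
#' with `H` the curvature of the negative log posterior at the MAP in the
#' transformed parameter space (the change-of-variables Jacobian is part of
#' the transformed-space prior, so no further correction is needed). A
#' non-positive-definite Hessian is ridge-regularized, with the ridge
#' reported in the `"ridge"` attribute.
#'
#' @param fit A [fit_map()] result.
#' @return Scalar log marginal likelihood (with attribute `"ridge"`).
#' @export
laplace_evidence <- function(fit) {
  stopifnot(inherits(fit, "twostep_fit"))
  laplace_log_evidence(fit$log_posterior, fit$hessian)
}

#' Fit several models to every subject of a cohort
#'
#' Runs [fit_map()] and [laplace_evidence()] for each subject under each
#' candidate model, assembling the subjects-by-models matrix of log marginal
#' likelihoods consumed by [bms_pxp()].
#'
#' @param data A multi-subject trial table.
#' @param models A list of [model_spec()] objects (named list or models named
#'   by their `name` field).
#' @param task A [make_task()] object.
#' @inheritParams fit_map
#' @return List with `evidence` (numeric matrix, one row per subject, one
#'   column per model) and `fits` (tibble of per-subject MAP summaries).
#' @export
fit_cohort <- function(data, models, task, n_restarts = 10, seed = 1) {
  if (inherits(models, "twostep_model")) models <- list(models)
  model_names <- vapply(models, `[[`, character(1), "name")
  subjects <- unique(data$subject)
  evidence <- matrix(NA_real_,
    nrow = length(subjects), ncol = length(models),
    dimnames = list(as.character(subjects), model_names)
  )
  rows <- vector("list", length(subjects) * length(models))
  idx <- 1L
  for (si in seq_along(subjects)) {
    d <- data[data$subject == subjects[si], ]
    for (mi in seq_along(models)) {
      fit <- fit_map(d, models[[mi]], task,
        n_restarts = n_restarts,
        seed = derive_seed(seed, si * 1000L + mi)
      )
      evidence[si, mi] <- as.numeric(laplace_evidence(fit))
      rows[[idx]] <- tibble::tibble(
        subject = subjects[si], model = model_names[mi],
        log_evidence = evidence[si, mi],
        log_likelihood = fit$log_likelihood,
        converged = fit$converged,
        tibble::as_tibble(as.list(fit$params_map))
      )
      idx <- idx + 1L
    }
  }
  list(evidence = evidence, fits = dplyr::bind_rows(rows))
}
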