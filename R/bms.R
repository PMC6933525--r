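# Random-effects Bayesian model selection: variational Dirichlet hierarchy,
# exceedance probabilities, Bayes omnibus risk, protected exceedance
# probabilities; plus the BIC approximation to Bayes factors.

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# Variational update for the hierarchical Dirichlet-multinomial model over
# subject-level model attributions (alpha0 = 1 prior).
bms_variational <- function(evidence, alpha0 = 1, tol = 1e-8, max_iter = 1000) {
  n <- nrow(evidence)
  k <- ncol(evidence)
  a0 <- rep(alpha0, k)
  a <- a0 + n / k
  for (it in seq_len(max_iter)) {
    lw <- sweep(evidence, 2, digamma(a) - digamma(sum(a)), `+`)
    u <- exp(lw - apply(lw, 1, logsumexp))
    a_new <- a0 + colSums(u)
    if (max(abs(a_new - a)) < tol) {
      a <- a_new
      break
    }
    a <- a_new
  }
  lw <- sweep(evidence, 2, digamma(a) - digamma(sum(a)), `+`)
  u <- exp(lw - apply(lw, 1, logsumexp))
  # variational free energy of the random-effects model
  e_lnr <- digamma(a) - digamma(sum(a))
  f1 <- sum(u * sweep(evidence, 2, e_lnr, `+`)) -
    sum(u[u > 0] * log(u[u > 0])) +
    lgamma(sum(a0)) - sum(lgamma(a0)) - lgamma(sum(a)) + sum(lgamma(a)) +
    sum((a0 - a) * e_lnr)
  list(alpha = a, u = u, free_energy = f1)
}

#' Random-effects model selection with protected exceedance probabilities
#'
#' Fits the hierarchical Dirichlet-multinomial model of model frequencies to
#' a subjects-by-models matrix of log marginal likelihoods (variational
#' update of the Dirichlet concentration), estimates each model's exceedance
#' probability (EP; probability its population frequency is the largest) by
#' Monte-Carlo sampling of the posterior Dirichlet, computes the Bayes
#' omnibus risk (BOR; posterior probability of the equal-frequency null
#' model, from the free-energy comparison of the random-effects model
#' against the null), and reports protected exceedance probabilities
#' `PXP = EP * (1 - BOR) + BOR / K`.
#'
#' @param evidence Numeric matrix of log marginal likelihoods, one row per
#'   subject, one column per model (at least 2 of each). Column names label
#'   the models.
#' @param n_samples Dirichlet Monte-Carlo draws for the EP (default 1e6).
#' @param seed Integer seed for the Monte-Carlo draws.
#' @return An object of class `twostep_bms`: list with `frequency` (expected
#'   model frequencies), `ep`, `bor`, `pxp`, and `alpha` (posterior Dirichlet
#'   parameters).
#' @export
bms_pxp <- function(evidence, n_samples = 1e6, seed = 1) {
  evidence <- as.matrix(evidence)
  if (any(!is.finite(evidence))) {
    stop("Evidence matrix contains non-finite entries.", call. = FALSE)
  }
  if (nrow(evidence) < 2 || ncol(evidence) < 2) {
    stop("Need at least 2 subjects and 2 models.", call. = FALSE)
  }
  k <- ncol(evidence)
  vb <- bms_variational(evidence)
  # null model: every subject's data explained by equal frequencies 1/K
  f0 <- sum(apply(evidence, 1, logsumexp) - log(k))
  bor <- 1 / (1 + exp(vb$free_energy - f0))
  # exceedance probabilities by Dirichlet Monte Carlo (chunked draws)
  set.seed(derive_seed(seed, 0L))
  wins <- numeric(k)
  left <- n_samples
  while (left > 0) {
    m <- min(left, 1e5)
    g <- matrix(stats::rgamma(m * k, shape = rep(vb$alpha, each = m)), nrow = m)
    wins <- wins + tabulate(max.col(g), nbins = k)
    left <- left - m
  }
  ep <- wins / n_samples
  pxp <- ep * (1 - bor) + bor / k
  structure(
    list(
      models = colnames(evidence) %||% paste0("model", seq_len(k)),
      frequency = as.numeric(vb$alpha / sum(vb$alpha)),
      ep = as.numeric(ep),
      bor = bor,
      pxp = as.numeric(pxp),
      alpha = as.numeric(vb$alpha),
      n_subjects = nrow(evidence)
    ),
    class = "twostep_bms"
  )
}

#' @export
print.twostep_bms <- function(x, ...) {
  cat("<twostep_bms> random-effects model selection,", x$n_subjects, "subjects\n")
  print(data.frame(
    model = x$models, frequency = round(x$frequency, 3),
    ep = round(x$ep, 3), pxp = round(x$pxp, 3)
  ))
  cat("  Bayes omnibus risk:", signif(x$bor, 3), "\n")
  invisible(x)
}

#' BIC approximation to a Bayes factor in favor of the null
#'
#' `BIC_m = k_m log(n) - 2 ll_m`; the Bayes factor for the null over the
#' alternative is `exp((BIC_alt - BIC_null) / 2)`.
#'
#' @param ll_null,ll_alt Maximized log-likelihoods of the null and
#'   alternative models.
#' @param k_null,k_alt Their parameter counts.
#' @param n_obs Number of observations (trials).
#' @return Scalar Bayes factor in favor of the null.
#' @examples
#' bic_bayes_factor(ll_null = -100, k_null = 1, ll_alt = -99, k_alt = 2, n_obs = 125)
#' @export
bic_bayes_factor <- function(ll_null, k_null, ll_alt, k_alt, n_obs) {
  stopifnot(n_obs >= 1)
  bic_null <- k_null * log(n_obs) - 2 * ll_null
  bic_alt <- k_alt * log(n_obs) - 2 * ll_alt
  exp((bic_alt - bic_null) / 2)
}

#' Generating-model recovery study
#'
#' Simulates a cohort from each generating model, fits every candidate model
#' to every simulated subject, and runs the random-effects model selection
#' per generating cohort. The result summarizes whether the selection
#' procedure recovers the model that generated the data.
#'
#' @param models List of candidate [model_spec()] objects (fit to every
#'   cohort).
#' @param task A [make_task()] object.
#' @param generating List of generating [model_spec()] objects (default: the
#'   candidates themselves).
#' @param n_subjects Subjects per generating cohort.
#' @param n_trials Trials per subject.
#' @param n_restarts Optimizer restarts per fit.
#' @param seed Integer seed.
#' @return A tibble with one row per generating cohort: `generating`,
#'   `selected` (highest-PXP candidate), and one `pxp_*` column per
#'   candidate.
#' @export
model_recovery <- function(models, task, generating = models,
                           n_subjects = 20, n_trials = 250,
                           n_restarts = 10, seed = 1) {
  candidate_names <- vapply(models, `[[`, character(1), "name")
  rows <- vector("list", length(generating))
  for (gi in seq_along(generating)) {
    sim <- simulate_cohort(generating[[gi]], task,
      n_agents = n_subjects,
      n_trials = n_trials, seed = derive_seed(seed, gi)
    )
    fits <- fit_cohort(sim, models, task,
      n_restarts = n_restarts,
      seed = derive_seed(seed, 100L + gi)
    )
    bms <- bms_pxp(fits$evidence, seed = derive_seed(seed, 200L + gi))
    pxp <- stats::setNames(bms$pxp, paste0("pxp_", seq_along(candidate_names)))
    rows[[gi]] <- tibble::tibble(
      cohort = gi,
      generating = generating[[gi]]$name,
      selected = candidate_names[which.max(bms$pxp)],
      !!!pxp
    )
  }
  dplyr::bind_rows(rows)
}
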