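# Trial-level likelihoods, MAP estimation, Laplace evidence.

test_that("indifferent agents have the closed-form likelihood in all model classes", {
  task <- make_task("graded_expt1")
  sim <- simulate_cohort(model_spec("Mixture-actions/Mixture-sequences"), task,
    n_agents = 1, n_trials = 125, seed = 40
  )
  p0 <- agent_params(alpha = 0.5, beta1 = 0, beta2 = 0, nu = 0, omega = 0.5, lam = 0.5)
  target <- 250 * log(0.5)
  for (m in list_models()) {
    expect_equal(trial_loglik(sim, model_spec(m), task, p0), target, tolerance = 1e-10)
  }
  # alpha is irrelevant when values never reach the choice rule
  p0b <- agent_params(alpha = 0.91, beta1 = 0, beta2 = 0, nu = 0, omega = 0.5, lam = 0.5)
  expect_equal(
    trial_loglik(sim, model_spec("Pure MB"), task, p0b),
    trial_loglik(sim, model_spec("Pure MB"), task, p0)
  )
})

test_that("compiled likelihood agrees with the plain-R reference on every model and task", {
  set.seed(41)
  for (variant in c("graded_expt1", "redstate_expt2")) {
    task <- make_task(variant)
    sim <- simulate_cohort(model_spec("Mixture-actions/Mixture-sequences"), task,
      n_agents = 1, n_trials = 80, seed = 42 + (variant == "redstate_expt2")
    )
    for (m in list_models()) {
      model <- model_spec(m)
      p <- agent_params(
        alpha = runif(1, 0.1, 0.9), beta1 = runif(1, 0, 8), beta2 = runif(1, 0, 8),
        nu = rnorm(1), omega = runif(1), lam = runif(1)
      )
      expect_equal(
        trial_loglik(sim, model, task, p),
        twostep:::trial_loglik_r(sim, model, task, p),
        tolerance = 1e-10,
        label = paste(variant, m)
      )
    }
  }
})

test_that("log-likelihood is non-positive and decreases as trials accumulate", {
  task <- make_task("graded_expt1")
  model <- model_spec("Mixture-actions/MB-sequences")
  sim <- simulate_cohort(model, task, n_agents = 1, n_trials = 100, seed = 43)
  p <- agent_params(0.4, 3, 3, 0.3, 0.7, 0.2)
  lls <- vapply(
    seq(10, 100, by = 10),
    function(n) trial_loglik(sim[1:n, ], model, task, p), numeric(1)
  )
  expect_true(all(lls < 0))
  expect_true(all(diff(lls) < 0))
})

test_that("MAP optimization matches a dense grid-search oracle on a 2-parameter toy", {
  task <- make_task("graded_expt1")
  model <- model_spec("No sequences")
  sim <- simulate_cohort(model, task,
    n_agents = 1, n_trials = 200, seed = 44,
    params = tibble::tibble(
      alpha = 0.5, beta1 = 4, beta2 = 4, nu = 0, omega = 0.5, lam = 0.5
    )
  )
  fixed <- list(beta2 = 4, nu = 0, omega = 0.5, lam = 0.5)
  fit <- fit_map(sim, model, task, n_restarts = 4, seed = 1, fixed = fixed)
  expect_setequal(fit$free, c("alpha", "beta1"))

  # oracle: evaluate the identical objective over a 200 x 200 transformed grid
  xg <- seq(-5, 5, length.out = 200) # logit alpha
  yg <- seq(-3, 3, length.out = 200) # log beta1
  obj <- function(xa, xb) {
    p <- agent_params(
      alpha = stats::plogis(xa), beta1 = exp(xb), beta2 = 4, nu = 0,
      omega = 0.5, lam = 0.5
    )
    lp <- stats::dbeta(stats::plogis(xa), 1.1, 1.1, log = TRUE) +
      log(stats::plogis(xa)) + log(1 - stats::plogis(xa)) +
      stats::dgamma(exp(xb), 1.2, scale = 5, log = TRUE) + xb
    trial_loglik(sim, model, task, p) + lp
  }
  vals <- outer(xg, yg, Vectorize(obj))
  best <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  cell <- c(diff(xg)[1], diff(yg)[1])
  expect_lt(abs(fit$x_map[["alpha"]] - xg[best[1]]), cell[1] * 1.5)
  expect_lt(abs(fit$x_map[["beta1"]] - yg[best[2]]), cell[2] * 1.5)
  expect_gt(fit$log_posterior - max(vals), -0.02) # no better optimum than the grid's

  # determinism
  fit2 <- fit_map(sim, model, task, n_restarts = 4, seed = 1, fixed = fixed)
  expect_identical(fit$params_map, fit2$params_map)
})

test_that("Laplace evidence matches the exact conjugate Beta-Bernoulli marginal", {
  set.seed(45)
  n <- 100
  k <- 63
  a <- 1.1
  b <- 1.1
  exact <- lbeta(a + k, b + n - k) - lbeta(a, b)
  # same machinery the subject fits use: logit-space MAP + FD Hessian
  nlp <- function(x) {
    p <- stats::plogis(x)
    -(k * log(p) + (n - k) * log(1 - p) +
      stats::dbeta(p, a, b, log = TRUE) + log(p) + log(1 - p))
  }
  opt <- stats::optim(0, nlp, method = "BFGS")
  H <- twostep:::fd_hessian(nlp, opt$par)
  lap <- twostep:::laplace_log_evidence(-opt$value, H)
  expect_lt(abs(as.numeric(lap) - exact), 0.1)

  # Laplace is exact for a Gaussian posterior
  prior_sd <- 1
  obs <- 0.7
  obs_sd <- 0.5
  nlp_g <- function(th) {
    -(stats::dnorm(obs, th, obs_sd, log = TRUE) + stats::dnorm(th, 0, prior_sd, log = TRUE))
  }
  opt_g <- stats::optim(0, nlp_g, method = "BFGS")
  H_g <- twostep:::fd_hessian(nlp_g, opt_g$par)
  exact_g <- stats::dnorm(obs, 0, sqrt(prior_sd^2 + obs_sd^2), log = TRUE)
  expect_lt(abs(as.numeric(twostep:::laplace_log_evidence(-opt_g$value, H_g)) - exact_g), 1e-5)
})

test_that("Laplace evidence is transform-insensitive and matches quadrature on a 2-d toy", {
  set.seed(46)
  n <- 100
  k <- 63
  a <- 1.1
  b <- 1.1
  exact <- lbeta(a + k, b + n - k) - lbeta(a, b)
  # natural-space Laplace (no transform, prior without Jacobian)
  nlp_nat <- function(p) {
    if (p <= 0 || p >= 1) {
      return(1e10)
    }
    -(k * log(p) + (n - k) * log(1 - p) + stats::dbeta(p, a, b, log = TRUE))
  }
  opt_nat <- stats::optimize(nlp_nat, c(0.01, 0.99))
  H_nat <- twostep:::fd_hessian(nlp_nat, opt_nat$minimum)
  lap_nat <- twostep:::laplace_log_evidence(-opt_nat$objective, H_nat)
  nlp_logit <- function(x) {
    p <- stats::plogis(x)
    -(k * log(p) + (n - k) * log(1 - p) +
      stats::dbeta(p, a, b, log = TRUE) + log(p) + log(1 - p))
  }
  opt_l <- stats::optim(0, nlp_logit, method = "BFGS")
  lap_logit <- twostep:::laplace_log_evidence(
    -opt_l$value,
    twostep:::fd_hessian(nlp_logit, opt_l$par)
  )
  expect_lt(abs(as.numeric(lap_nat) - as.numeric(lap_logit)), 0.05)
  expect_lt(abs(as.numeric(lap_logit) - exact), 0.1)

  # 2-d toy: product of two independent Beta-Bernoulli problems, quadrature oracle
  k2 <- 40
  nlp2 <- function(x) nlp_logit(x[1]) + {
    p <- stats::plogis(x[2])
    -(k2 * log(p) + (n - k2) * log(1 - p) +
      stats::dbeta(p, a, b, log = TRUE) + log(p) + log(1 - p))
  }
  opt2 <- stats::optim(c(0, 0), nlp2, method = "BFGS")
  lap2 <- twostep:::laplace_log_evidence(-opt2$value, twostep:::fd_hessian(nlp2, opt2$par))
  grid <- seq(-6, 6, length.out = 400)
  h <- diff(grid)[1]
  quad <- function(nlp1d) {
    v <- vapply(grid, nlp1d, numeric(1))
    m <- max(-v)
    m + log(sum(exp(-v - m))) + log(h)
  }
  quad2 <- quad(nlp_logit) + quad(function(x) nlp2(c(0, x)) - nlp_logit(0))
  expect_lt(abs(as.numeric(lap2) - quad2), 0.2)
})

test_that("parameters of a strongly identified subject are recovered within posterior error", {
  task <- make_task("graded_expt1")
  model <- model_spec("No sequences")
  true <- tibble::tibble(
    alpha = 0.6, beta1 = 8, beta2 = 8, nu = 0.3, omega = 0.35, lam = 0.5
  )
  sim <- simulate_cohort(model, task, n_agents = 1, n_trials = 1000, seed = 47, params = true)
  fit <- fit_map(sim, model, task, n_restarts = 4, seed = 2)
  sds <- sqrt(diag(solve(fit$hessian)))
  names(sds) <- fit$free
  x_true <- twostep:::to_unconstrained(unlist(true))
  for (nm in c("alpha", "omega")) {
    expect_lt(abs(fit$x_map[[nm]] - x_true[[nm]]), 3 * sds[[nm]] + 0.05)
  }
})

test_that("fits refuse vacuous sessions", {
  task <- make_task("graded_expt1")
  sim <- simulate_cohort(model_spec("No sequences"), task,
    n_agents = 1,
    n_trials = 10, seed = 48
  )
  expect_error(fit_map(sim, model_spec("No sequences"), task), "20 trials")
})
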