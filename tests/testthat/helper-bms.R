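# Independent brute-force sampler of the same hierarchy: r ~ Dirichlet(1),
# weight by the marginal likelihood of the attributions, estimate exceedance
# probabilities and the random-effects marginal by importance sampling.
brute_force_bms <- function(evidence, n_draws = 2e5, seed = 99) {
  set.seed(seed)
  n <- nrow(evidence)
  k <- ncol(evidence)
  shift <- apply(evidence, 1, max)
  lik <- exp(evidence - shift) # n x k, row-scaled
  g <- matrix(stats::rgamma(n_draws * k, 1), ncol = k)
  r <- g / rowSums(g)
  logw <- apply(r, 1, function(ri) sum(log(lik %*% ri)))
  w <- exp(logw - max(logw))
  ep <- vapply(seq_len(k), function(j) {
    sum(w * (max.col(r) == j)) / sum(w)
  }, numeric(1))
  # marginal likelihood of the RE model (up to the common shift) vs null
  log_p_re <- max(logw) + log(mean(exp(logw - max(logw))))
  log_p_null <- sum(log(rowMeans(lik)))
  bor <- 1 / (1 + exp(log_p_re - log_p_null))
  list(ep = ep, bor = bor, pxp = ep * (1 - bor) + bor / k)
}
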