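# Shared simulated cohorts, built once per test run and memoized, so the
# signature and acceptance tests can reuse them.

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, builder(), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

# The study-condition cohorts: 1000 agents x 125 trials, priors as stated.
cohort_mf_binary <- function() {
  cached("mf_binary", function() {
    simulate_cohort(
      model_spec("No sequences"),
      make_task("original_binary", representation = "reward_based"),
      n_agents = 1000, seed = 101
    )
  })
}

cohort_mbas_binary <- function() {
  cached("mbas_binary", function() {
    simulate_cohort(
      model_spec("Pure MB"),
      make_task("original_binary", representation = "reward_based"),
      n_agents = 1000, seed = 102
    )
  })
}

cohort_mf_graded <- function() {
  cached("mf_graded", function() {
    simulate_cohort(
      model_spec("No sequences"), make_task("graded_expt1"),
      n_agents = 1000, seed = 103
    )
  })
}

cohort_mbas_graded <- function() {
  cached("mbas_graded", function() {
    simulate_cohort(
      model_spec("Pure MB"), make_task("graded_expt1"),
      n_agents = 1000, seed = 104
    )
  })
}

# Red-state task cohorts for the four sequence-controller configurations.
cohort_expt2 <- function(which) {
  key <- paste0("expt2_", which)
  cached(key, function() {
    task <- make_task("redstate_expt2")
    switch(which,
      mf_seq = {
        # pure model-free sequence control: mixture model with omega forced to 0
        m <- model_spec("Mixture-actions/Mixture-sequences")
        set.seed(derive_seed_test(105))
        pr <- sample_params(m, 1000)
        pr$omega <- 0
        simulate_cohort(m, task, n_agents = 1000, seed = 105, params = pr)
      },
      mixture_seq = simulate_cohort(
        model_spec("Mixture-actions/Mixture-sequences"), task,
        n_agents = 1000, seed = 106
      ),
      mb_seq = simulate_cohort(
        model_spec("Mixture-actions/MB-sequences"), task,
        n_agents = 1000, seed = 107
      ),
      no_seq = simulate_cohort(
        model_spec("No sequences"), task,
        n_agents = 1000, seed = 108
      )
    )
  })
}

derive_seed_test <- function(seed) (seed * 7919L) %% 2147483629L

# Extract one term's row from a tidied signature result.
sig_term <- function(sig, term) {
  row <- dplyr::filter(generics::tidy(sig), .data$term == .env$term)
  stopifnot(nrow(row) == 1)
  row
}
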