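# Shared fixtures for the suite. Small configs keep unit tests fast; the
# acceptance tests use the full study conditions (n = 20000, 10 replicates).

fast_config <- function(seed = 1L) {
  sim_config(n = 5000L, seed = seed, replicates = 4L)
}

study_config <- function(seed = 1L) {
  sim_config(n = 20000L, seed = seed, replicates = 10L)
}

# random positive scores for property tests
random_positive <- function(n, seed) {
  set.seed(seed)
  exp(stats::runif(n, log(0.05), log(20)))
}
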