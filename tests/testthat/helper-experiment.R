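# The end-to-end synthetic experiment is expensive (several minutes), so it
# is computed once per test run and shared between the tests that inspect it.

experiment_cache <- new.env(parent = emptyenv())

cached_experiment <- function(seed = 42L) {
  key <- paste0("seed_", seed)
  if (is.null(experiment_cache[[key]])) {
    experiment_cache[[key]] <- run_phantom_experiment(seed = seed)
  }
  experiment_cache[[key]]
}
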