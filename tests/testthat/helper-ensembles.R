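# Shared, lazily computed simulation fixtures for the transition-scale tests.
# The heavy ensembles are computed once per test run and reused across
# test_that() blocks.

.sim_cache <- new.env(parent = emptyenv())

transition_config <- function(...) {
  run_config(n_agents = 200, equilibration_steps = 200, forcing_steps = 1000,
             ensemble_size = 20, base_seed = 2026, ...)
}

# 20-run coupled ensemble over the full protocol
coupled_transition_ensemble <- function() {
  if (is.null(.sim_cache$coupled))
    .sim_cache$coupled <- run_ensemble(transition_config(), ci = FALSE)
  .sim_cache$coupled
}

# 8-run-per-variant comparison of all four model variants, shared structure
variant_transition_comparison <- function() {
  if (is.null(.sim_cache$cmp))
    .sim_cache$cmp <- compare_variants(transition_config(), n_runs = 8)
  .sim_cache$cmp
}
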