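# Shared fixtures: a small fast parameter set and tiny lattices, all built
# in code.

# Parameter set with mixed Hill exponents (exercises both the n == 2 fast
# path and the general pow path in the compiled engine).
test_params <- function(...) {
  sc_params(...)
}

# A small toroidal lattice seeded with a handful of stem cells at fixed
# positions (deterministic, no RNG).
small_lattice <- function(n_cols = 10, n_rows = 6, sites = c(1, 2, 25, 40),
                          params = test_params()) {
  seed_stem(hex_lattice(n_cols, n_rows), sites, params)
}

# Config for fast whole-pipeline runs on the small lattice; any argument
# of experiment_config() can be overridden.
small_config <- function(...) {
  defaults <- list(n_replicates = 2, doses = c(0, 5),
                   treatment_duration = 48, post_treatment_duration = 152,
                   measurement_window = 48, initial_sc_count = 4,
                   n_cols = 10, n_rows = 6)
  do.call(experiment_config, utils::modifyList(defaults, list(...)))
}

# Memoised store for expensive acceptance fixtures shared across test files.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_fixture <- function(name, build) {
  if (!exists(name, envir = .acceptance_cache)) {
    assign(name, build(), envir = .acceptance_cache)
  }
  get(name, envir = .acceptance_cache)
}
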