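# Expensive shared simulations, computed once per test run.
.run_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) {
    assign(key, force(expr), envir = .run_cache)
  }
  get(key, envir = .run_cache)
}

# the reference multi-trial experiment: 60 cells, 200 trials, trial-wise
# conductance noise (the default statistics condition)
default_trials <- function() {
  cached("default_trials", {
    run_trials(network_config(n_cells = 60), noise_config(),
               n_trials = 200, base_seed = 1000)
  })
}

fig2_default <- function() {
  cached("fig2_default", run_fig2_single_cell())
}
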