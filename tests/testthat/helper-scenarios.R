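# Shared small-scale scenarios and cached simulations for the test suite.
# Sizes are chosen so the whole suite runs in minutes while keeping enough
# events for the stochastic checks.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

test_config <- function(...) {
  args <- list(...)
  if (is.null(args$founders)) args$founders <- 60
  do.call(gc_config, args)
}

# one default-scenario run reused across module tests
default_sim <- function() cached("default_sim", {
  simulate_gc(gc_config(founders = 80), model_zero(), seed = 1,
              replicates = 2, days = 7, keep_state = TRUE)
})

default_cells <- function() dplyr::bind_rows(attr(default_sim(), "cells"))

# build a tiny gc_state with chosen subpopulations, for census fixtures
state_with_subpops <- function(subpops) {
  cfg <- gc_config(founders = length(subpops))
  st <- seed_gc(cfg, seed = 1)
  st$sub <- unname(gcmyc:::SUBPOPS[subpops])
  st$sub_t <- rep(0, length(subpops))
  st
}
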