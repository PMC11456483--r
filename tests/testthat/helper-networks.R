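# Shared fixtures. Expensive simulations are cached per test run so several
# test files can reuse them.

`%||%` <- function(a, b) if (is.null(a)) b else a

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

reference_network <- function() cached("net_ref", build_network(0.3, 0.02))

# Six-condition trace sets at the ordered-pattern reference point, at the
# full 10 s protocol (shared with the regime helpers' cache).
reference_traces <- function() regime_traces(0.3, 0.02)

# A short, cheap simulation for structural tests.
short_trace <- function(condition = "none") {
  cached(paste0("short_", condition),
         suppressWarnings(simulate_columns(reference_network(), condition,
                                           t_total = 1500, t_onset = 1000)))
}
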