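# Cached full-protocol (10 s / onset 5 s / dt 0.01 ms) six-condition runs and
# their regime labels, shared across test files.

regime_traces <- function(de, di, perturbation = "none") {
  key <- sprintf("traces_%g_%g_%s", de, di, perturbation)
  cached(key, {
    net <- build_network(de, di, perturbation = perturbation)
    suppressWarnings(simulate_conditions(net))
  })
}

regime_at <- function(de, di, perturbation = "none", ...) {
  key <- sprintf("label_%g_%g_%s", de, di, perturbation)
  cached(key, classify_regime(regime_traces(de, di, perturbation), ...))
}

# The package's own marker points (chosen from its parameter-plane sweeps):
# a concurrent pair, and the point where blocking L6E->L4E keeps concurrency.
concurrent_points <- list(c(0.14, 0.010), c(0.20, 0.012))
blockL4E_concurrent_point <- c(0.18, 0.012)
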