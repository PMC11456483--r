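# Class-aggregated synaptic weight matrices W[target, source] = gbar * P * N_Y.
# One matrix per source class; multiplying by the rate vector gives the drive
# term of the aggregated conductance ODE.
weight_matrices <- function(network) {
  pops <- network$populations
  labels <- pops$name
  n <- length(labels)
  WE <- WI <- matrix(0, n, n, dimnames = list(labels, labels))
  pw <- network$pathways |>
    mutate(N_src = pops$N[match(.data$source, pops$name)],
           w = .data$g_peak * .data$P * .data$N_src,
           exc = pops$cell_class[match(.data$source, pops$name)] == "E")
  for (i in seq_len(nrow(pw))) {
    ti <- match(pw$target[i], labels)
    si <- match(pw$source[i], labels)
    if (pw$exc[i]) WE[ti, si] <- WE[ti, si] + pw$w[i]
    else WI[ti, si] <- WI[ti, si] + pw$w[i]
  }
  list(WE = WE, WI = WI)
}

#' Mean-field right-hand side of the population equations
#'
#' Evaluates, for every population X, the Lorentzian-ansatz reduction of the
#' heterogeneous QIF network:
#' \deqn{\dot r_X = 2\zeta_X r_X v_X + \eta_X r_X - \frac{r_X}{C}\sum_Y g_{YX}
#'       + \frac{\zeta_X}{\pi}\Delta_{back,X}}
#' \deqn{\dot v_X = \zeta_X v_X^2 + \eta_X v_X + \kappa_X - (\pi^2/\zeta_X) r_X^2
#'       + \frac{1}{C}\Big(\sum_Y g_{YX} V_{syn,Y} - v_X \sum_Y g_{YX}\Big)
#'       + \bar I_{back,X} + I_{sens,X} + I_{attn,X}}
#' \deqn{\dot g_{YX} = -g_{YX}/\tau_{d,Y} + \bar g_{YX} P_{YX} N_Y r_Y}
#' with afferent conductances aggregated by source class into `g_exc_in` and
#' `g_inh_in` (exactly equivalent because the decay time depends only on the
#' source class). The rate-feedback coefficient \eqn{\pi^2/\zeta_X} and the
#' heterogeneity source \eqn{\zeta_X \Delta / \pi} follow from reducing the
#' dimensional QIF equation: \eqn{u = \zeta V + \eta/2} maps it to the
#' canonical form and the physical rate is the voltage-density flux
#' \eqn{r = \zeta x / \pi} at \eqn{V \to \infty}. A pure function of its
#' arguments; the compiled integrator steps the same equations.
#'
#' @param state List with numeric vectors `r` (ms^-1), `v` (mV), `g_exc_in`,
#'   `g_inh_in` (mS/cm^2), each of length 16 in [population_labels()] order.
#' @param network A `column_network`.
#' @param inputs Tibble from [condition_currents()] (or `NULL` for zero
#'   external input).
#'
#' @return List of the four derivative vectors, same shapes and units per ms.
#' @export
mean_field_rhs <- function(state, network, inputs = NULL) {
  pops <- network$populations
  r <- state$r; v <- state$v
  ge <- state$g_exc_in; gi <- state$g_inh_in
  if (any(!is.finite(c(r, v, ge, gi)))) {
    bad <- pops$name[!is.finite(r) | !is.finite(v)][1]
    abort(paste0("Non-finite state encountered (population ",
                 bad %||% "unknown", ")."),
          class = "columnet_numeric_error")
  }
  W <- weight_matrices(network)
  iext <- if (is.null(inputs)) numeric(nrow(pops)) else {
    stopifnot(identical(inputs$name, pops$name))
    inputs$I_sens + inputs$I_attn
  }
  sum_g <- ge + gi
  vsyn <- .default_biophys$V_syn
  list(
    r = 2 * pops$zeta * r * v + pops$eta * r - (r / pops$C) * sum_g +
      (pops$zeta / pi) * pops$I_back_width,
    v = pops$zeta * v^2 + pops$eta * v + pops$kappa - (pi^2 / pops$zeta) * r^2 +
      (ge * vsyn[["E"]] + gi * vsyn[["I"]] - v * sum_g) / pops$C +
      pops$I_back_center + iext,
    g_exc_in = -ge / .default_biophys$tau_d[["E"]] + drop(W$WE %*% r),
    g_inh_in = -gi / .default_biophys$tau_d[["I"]] + drop(W$WI %*% r)
  )
}

#' Simulate the two-column mean-field model
#'
#' Integrates all 64 state variables (rate, mean voltage and two aggregated
#' conductances per population) with fixed-step forward Euler. External
#' sensory/attention currents are zero before `t_onset` and constant
#' afterwards. The run is deterministic: identical inputs give identical
#' traces.
#'
#' @param network A `column_network`.
#' @param condition One of [stimulus_conditions()].
#' @param dt Euler time step, ms.
#' @param t_total Total simulated time, ms.
#' @param t_onset Stimulus onset, ms (must be < `t_total`).
#' @param record_stride Record every `record_stride`-th step.
#' @param r_ceiling Sanity ceiling on any population rate, ms^-1 (spiky
#'   low-heterogeneity regimes legitimately reach ~20 ms^-1); exceeding
#'   it aborts with a diagnostic naming population and time.
#' @param init Optional list with `r`, `v`, `g_exc_in`, `g_inh_in` start
#'   vectors (ms^-1, mV, mS/cm^2). Default: `r = 1e-4` ms^-1, `v = V_R`,
#'   conductances 0; the pre-onset window washes out this transient.
#' @inheritParams condition_currents
#'
#' @return A `trace_set`: list with `time` (ms), matrices `rates` (Hz) and
#'   `voltages` (mV) with one column per population, the condition and
#'   simulation settings, and a fingerprint of the network. Use
#'   [tidy.trace_set()] for a long tibble.
#' @export
#' @examples
#' net <- build_network(0.3, 0.02)
#' tr <- simulate_columns(net, "S1", t_total = 500, t_onset = 250)
#' dplyr::filter(tidy(tr), population == "1L5E") |> head()
simulate_columns <- function(network, condition = "none",
                             dt = 0.01, t_total = 10000, t_onset = 5000,
                             record_stride = 10, r_ceiling = 50,
                             sensory_base = .default_drive$sensory_base,
                             attention_base = .default_drive$attention_base,
                             preferred_ratio = .default_drive$preferred_ratio,
                             init = NULL) {
  stopifnot(inherits(network, "column_network"))
  if (dt <= 0 || t_total <= 0 || t_onset < 0 || t_onset >= t_total) {
    abort("Require dt > 0 and 0 <= t_onset < t_total.",
          class = "columnet_config_error")
  }
  record_stride <- as.integer(record_stride)
  stopifnot(record_stride >= 1)
  pops <- network$populations
  n <- nrow(pops)
  cur <- condition_currents(network, condition, sensory_base,
                            attention_base, preferred_ratio)
  W <- weight_matrices(network)
  if (is.null(init)) {
    init <- list(r = rep(1e-4, n), v = pops$V_R, g_exc_in = rep(0, n),
                 g_inh_in = rep(0, n))
  }

  out <- euler_meanfield_cpp(
    pops$zeta, pops$eta, pops$kappa, pops$I_back_center, pops$I_back_width,
    pops$C, cur$I_sens, cur$I_attn, W$WE, W$WI,
    .default_biophys$tau_d[["E"]], .default_biophys$tau_d[["I"]],
    .default_biophys$V_syn[["E"]], .default_biophys$V_syn[["I"]],
    dt, t_total, t_onset, record_stride,
    init$r, init$v, init$g_exc_in, init$g_inh_in, r_ceiling
  )
  if (isTRUE(out$error)) {
    abort(sprintf(
      "Numerical blow-up in population %s at t = %.2f ms (non-finite state or rate above %g ms^-1).",
      pops$name[out$bad_population], out$bad_time, r_ceiling),
      class = "columnet_numeric_error")
  }
  if (isTRUE(out$step_warning)) {
    warn("Relative state change above 0.5 in a single Euler step; `dt` may be too large.")
  }
  rates <- out$r * 1000 # ms^-1 -> Hz
  voltages <- out$v
  colnames(rates) <- colnames(voltages) <- pops$name
  structure(
    list(
      time = as.numeric(out$time),
      rates = rates,
      voltages = voltages,
      condition = condition,
      dt = dt, t_total = t_total, t_onset = t_onset,
      record_stride = record_stride,
      network = network,
      fingerprint = rlang::hash(network)
    ),
    class = "trace_set"
  )
}

#' Simulate a set of stimulus conditions
#'
#' Convenience wrapper running [simulate_columns()] once per condition.
#'
#' @param conditions Character vector of condition names.
#' @inheritParams simulate_columns
#' @param ... Passed on to [simulate_columns()].
#' @return Named list of `trace_set` objects.
#' @export
simulate_conditions <- function(network,
                                conditions = c("none", "S1", "S2", "S1S2",
                                               "S1S2_A1", "S1S2_A2"),
                                ...) {
  setNames(lapply(conditions, function(cc) simulate_columns(network, cc, ...)),
           conditions)
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set> condition ", x$condition, ", ",
      length(x$time), " samples x ", ncol(x$rates), " populations, t = [",
      min(x$time), ", ", max(x$time), "] ms (onset ", x$t_onset, " ms)\n",
      sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trace set into a long tibble
#'
#' @param x A `trace_set`.
#' @param voltages Include the mean-voltage column.
#' @param ... Unused.
#' @return Tibble with `time_ms`, `population`, `rate_hz` (and `v_mv`),
#'   plus the condition.
#' @export
tidy.trace_set <- function(x, voltages = FALSE, ...) {
  out <- as_tibble(x$rates) |>
    mutate(time_ms = x$time) |>
    tidyr::pivot_longer(-"time_ms", names_to = "population",
                        values_to = "rate_hz")
  if (voltages) {
    vl <- as_tibble(x$voltages) |>
      mutate(time_ms = x$time) |>
      tidyr::pivot_longer(-"time_ms", names_to = "population",
                          values_to = "v_mv")
    out <- left_join(out, vl, by = c("time_ms", "population"))
  }
  mutate(out, condition = x$condition)
}

#' One-row-per-population summary of a trace set
#'
#' Mean rate and oscillation-cycle amplitude over the final-second window.
#'
#' @param x A `trace_set`.
#' @param window Length of the trailing analysis window, ms.
#' @param ... Unused.
#' @return Tibble with `population`, `mean_rate_hz`, `amplitude_hz`.
#' @export
glance.trace_set <- function(x, window = 1000, ...) {
  w <- c(max(x$time) - window, max(x$time))
  purrr::map_dfr(colnames(x$rates), function(p) {
    tibble(population = p,
           mean_rate_hz = mean(window_trace(x, p, w)$value),
           amplitude_hz = oscillation_amplitude(x, p, w))
  }) |> mutate(condition = x$condition)
}
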