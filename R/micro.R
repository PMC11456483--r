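#' Settings of the microscopic (finite-N) QIF network
#'
#' The spiking network integrates every neuron's quadratic voltage equation,
#' with background currents drawn once per neuron from the population's
#' Lorentzian distribution and connectivity realized as independent
#' Bernoulli draws per pathway. It serves as a brute-force check of the
#' mean-field reduction on small instances.
#'
#' @param scale Fraction of the nominal population sizes to instantiate.
#' @param v_peak Spike cutoff, mV (the reduction assumes it far above
#'   threshold; the default sits ~260 mV above the `(V_R+V_T)/2` midpoint).
#' @param v_reset Reset potential, mV (symmetric far below rest).
#' @param dt Euler step, ms.
#' @param clip_quantiles Lorentzian draws are clipped to this quantile range
#'   to avoid pathological outlier currents in tiny populations; use
#'   `c(0, 1)` to disable.
#' @param connectivity `"shared"` (default): one conductance per pathway,
#'   incremented by `g_peak * P / scale` for every presynaptic spike and
#'   seen identically by all target neurons — the coupling the exact
#'   reduction describes. `"bernoulli"`: connectivity realized as
#'   independent Bernoulli(P) draws with per-neuron conductances (jump
#'   `g_peak / scale` per synapse), which adds quenched in-degree disorder
#'   on top of the mean-field picture.
#' @return A list of class `micro_config`.
#' @export
micro_config <- function(scale = 0.1, v_peak = 200, v_reset = -320,
                         dt = 0.01, clip_quantiles = c(0.001, 0.999),
                         connectivity = c("shared", "bernoulli")) {
  stopifnot(scale > 0, scale <= 1, v_peak > -55, v_reset < -62, dt > 0)
  structure(list(scale = scale, v_peak = v_peak, v_reset = v_reset,
                 dt = dt, clip_quantiles = clip_quantiles,
                 connectivity = match.arg(connectivity)),
            class = "micro_config")
}

#' Draw Lorentzian background currents
#'
#' Inverse-CDF sampling of the Cauchy-Lorentzian background-current
#' distribution with optional quantile clipping.
#'
#' @param n Number of draws.
#' @param center,width Center and half-width of the distribution, mA/cm^2.
#' @param clip Quantile range to clip to.
#' @return Numeric vector of currents.
#' @export
rlorentzian <- function(n, center, width, clip = c(0.001, 0.999)) {
  u <- stats::runif(n, clip[1], clip[2])
  center + width * tan(pi * (u - 0.5))
}

#' Simulate the microscopic spiking QIF network
#'
#' Integrates every neuron of a (down-scaled) realization of `network` with
#' forward Euler. Synaptic coupling follows `micro$connectivity`: either the
#' shared per-pathway conductance of the population equations (default) or
#' Bernoulli-realized connections with per-neuron conductances; in both
#' cases jumps are scaled by `1/scale` so the expected synaptic drive
#' matches the full-size mean-field limit. Randomness (background currents,
#' and connectivity in the Bernoulli mode) uses R's RNG: call `set.seed()`
#' for reproducible rasters.
#'
#' @param network A `column_network` (the full model or a small fixture such
#'   as [ei_network()]).
#' @param condition Stimulus condition.
#' @param micro A [micro_config()].
#' @param t_total Simulated time, ms.
#' @param t_onset Stimulus onset, ms; defaults to `t_total` (never on).
#' @param bin Width of the rate bins, ms.
#' @return A list of class `micro_result`: `spikes` tibble
#'   (`time_ms`, `neuron`, `population`), `rates` tibble of binned
#'   population rates (`time_ms`, `population`, `rate_hz`), and the
#'   realized per-population neuron counts.
#' @export
simulate_micro <- function(network, condition = "none",
                           micro = micro_config(), t_total = 2000,
                           t_onset = t_total, bin = 5) {
  stopifnot(inherits(network, "column_network"),
            inherits(micro, "micro_config"))
  pops <- network$populations
  n_scaled <- pmax(0L, as.integer(round(pops$N * micro$scale)))
  if (any(n_scaled < 10)) {
    abort(paste0("Scale ", micro$scale, " leaves population(s) ",
                 paste(pops$name[n_scaled < 10], collapse = ", "),
                 " with fewer than 10 neurons."),
          class = "columnet_config_error")
  }
  N <- sum(n_scaled)
  offset <- c(0L, cumsum(n_scaled))
  pop_of <- rep(seq_len(nrow(pops)), n_scaled)

  # per-neuron constants
  zeta_n <- pops$zeta[pop_of]
  eta_n <- pops$eta[pop_of]
  kappa_n <- pops$kappa[pop_of]
  iback_n <- unlist(lapply(seq_len(nrow(pops)), function(p)
    rlorentzian(n_scaled[p], pops$I_back_center[p], pops$I_back_width[p],
                micro$clip_quantiles)))
  cur <- condition_currents(network, condition)
  isens_n <- cur$I_sens[pop_of]
  iattn_n <- cur$I_attn[pop_of]
  src_is_exc <- as.integer(pops$cell_class[pop_of] == "E")

  pw <- filter(network$pathways, .data$P > 0)
  tau <- .default_biophys$tau_d
  vsyn <- .default_biophys$V_syn
  if (micro$connectivity == "shared") {
    # one conductance per pathway; each spike in Y jumps it by
    # g_peak * P / scale, so the expected drive matches g_peak * P * N * r
    out <- micro_qif_shared_cpp(
      zeta_n, eta_n, kappa_n, iback_n, isens_n, iattn_n, pops$C[1],
      pop_of - 1L,
      match(pw$source, pops$name) - 1L, match(pw$target, pops$name) - 1L,
      pw$g_peak * pw$P / micro$scale,
      as.integer(pops$cell_class[match(pw$source, pops$name)] == "E"),
      tau[["E"]], tau[["I"]], vsyn[["E"]], vsyn[["I"]],
      micro$dt, t_total, t_onset, micro$v_peak, micro$v_reset, pops$V_R[1]
    )
  } else {
    # Bernoulli connectivity; per-synapse jumps scaled by 1/scale
    edges_src <- integer(0); edges_tgt <- integer(0); edges_w <- numeric(0)
    for (i in seq_len(nrow(pw))) {
      sp <- match(pw$source[i], pops$name)
      tp <- match(pw$target[i], pops$name)
      ns <- n_scaled[sp]; nt <- n_scaled[tp]
      hit <- which(stats::runif(ns * nt) < pw$P[i])
      if (!length(hit)) next
      s_idx <- ((hit - 1L) %% ns) + 1L
      t_idx <- ((hit - 1L) %/% ns) + 1L
      edges_src <- c(edges_src, offset[sp] + s_idx)
      edges_tgt <- c(edges_tgt, offset[tp] + t_idx)
      edges_w <- c(edges_w, rep(pw$g_peak[i] / micro$scale, length(hit)))
    }
    ord <- order(edges_src)
    edges_src <- edges_src[ord]; edges_tgt <- edges_tgt[ord]
    edges_w <- edges_w[ord]
    adj_ptr <- c(0L, cumsum(tabulate(edges_src, nbins = N)))

    out <- micro_qif_cpp(
      zeta_n, eta_n, kappa_n, iback_n, isens_n, iattn_n, pops$C[1],
      adj_ptr, edges_tgt - 1L, edges_w, src_is_exc,
      tau[["E"]], tau[["I"]], vsyn[["E"]], vsyn[["I"]],
      micro$dt, t_total, t_onset, micro$v_peak, micro$v_reset, pops$V_R[1]
    )
  }

  spikes <- tibble(time_ms = out$spike_time, neuron = out$spike_neuron,
                   population = pops$name[pop_of[out$spike_neuron]])
  breaks <- seq(0, t_total, by = bin)
  centers <- breaks[-1] - bin / 2
  rates <- purrr::map_dfr(seq_len(nrow(pops)), function(p) {
    st <- spikes$time_ms[pop_of[spikes$neuron] == p]
    counts <- if (length(st)) tabulate(findInterval(st, breaks,
                                                    rightmost.closed = TRUE),
                                       nbins = length(centers)) else
      integer(length(centers))
    tibble(time_ms = centers, population = pops$name[p],
           rate_hz = 1000 * counts / (n_scaled[p] * bin))
  })
  structure(list(spikes = spikes, rates = rates,
                 counts = setNames(n_scaled, pops$name),
                 condition = condition, micro = micro, t_total = t_total),
            class = "micro_result")
}

#' @export
print.micro_result <- function(x, ...) {
  cat("<micro_result> ", sum(x$counts), " neurons, ",
      nrow(x$spikes), " spikes over ", x$t_total, " ms\n", sep = "")
  invisible(x)
}

#' Minimal excitatory-inhibitory network fixture
#'
#' A two-population E-I network with the layer-5 connectivity motif
#' (recurrent excitation, strong reciprocal inhibition) used to
#' cross-validate the mean-field reduction against the spiking network and
#' to test closed-form limits. Populations are labeled `1L5E`/`1L5I` so the
#' standard stimulus machinery applies.
#'
#' @inheritParams build_network
#' @param n_e,n_i Nominal population sizes.
#' @param p Named connection probabilities `ee`, `ei` (E to I), `ie`
#'   (I to E), `ii`.
#' @return A `column_network` with two populations.
#' @export
ei_network <- function(delta_e = 0.3, delta_i = 0.02,
                       n_e = 2425, n_i = 532,
                       p = c(ee = 0.0758, ei = 0.0566,
                             ie = 0.3765, ii = 0.3158),
                       i_back_e = .default_drive$i_back_E) {
  bio <- .default_biophys
  pops <- tibble(
    name = c("1L5E", "1L5I"),
    column = 1L,
    layer = "L5",
    cell_class = c("E", "I"),
    N = c(n_e, n_i),
    C = bio$C,
    g_L = unname(bio$g_L),
    V_R = bio$V_R, V_T = bio$V_T,
    V_syn_out = unname(bio$V_syn),
    tau_d = unname(bio$tau_d),
    I_back_center = c(i_back_e, .default_drive$i_back_I_ratio * i_back_e),
    I_back_width = c(delta_e, delta_i)
  )
  pops <- bind_cols(pops, qif_constants(pops$g_L, pops$C, pops$V_R, pops$V_T))
  g <- .default_g_peak
  paths <- tibble(
    source = c("1L5E", "1L5E", "1L5I", "1L5I"),
    target = c("1L5E", "1L5I", "1L5E", "1L5I"),
    P = unname(p[c("ee", "ei", "ie", "ii")]),
    g_peak = unname(g[c("E->E", "E->I", "I->E", "I->I")])
  )
  structure(list(populations = pops, pathways = paths,
                 perturbation = "none", delta_e = delta_e, delta_i = delta_i,
                 p_inter = 0, i_back_e = i_back_e),
            class = "column_network")
}
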