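# --- windowing and extrema helpers -----------------------------------------

window_trace <- function(trace, population, window) {
  stopifnot(inherits(trace, "trace_set"))
  if (!population %in% colnames(trace$rates)) {
    abort(paste0("Unknown population `", population, "`."),
          class = "columnet_config_error")
  }
  if (window[1] < min(trace$time) - 1e-9 || window[2] > max(trace$time) + 1e-9) {
    abort("Analysis window exceeds the recorded trace.",
          class = "columnet_config_error")
  }
  keep <- trace$time >= window[1] & trace$time <= window[2]
  tibble(time_ms = trace$time[keep], value = trace$rates[keep, population])
}

# Indices of strict local maxima / minima (plateau-tolerant on the left).
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(), min = integer()))
  d <- diff(x)
  s <- sign(d)
  # carry the sign of the previous nonzero slope through plateaus
  for (i in seq_along(s)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  turn <- diff(s)
  list(max = which(turn < 0) + 1L, min = which(turn > 0) + 1L)
}

rolling_mean <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2 == 0) k <- k + 1L
  sm <- stats::filter(x, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)
  # extend with edge values where the centered window is incomplete
  half <- (k - 1L) / 2L
  if (half > 0 && length(x) > k) {
    sm[seq_len(half)] <- sm[half + 1L]
    sm[(length(x) - half + 1L):length(x)] <- sm[length(x) - half]
  } else if (anyNA(sm)) sm <- x
  sm
}

# --- envelopes --------------------------------------------------------------

#' Oscillation envelopes of a population trace
#'
#' Upper and lower envelopes from per-cycle local extrema with interpolation
#' between them. A trace without at least two full cycles in the window (or
#' with negligible peak-to-trough range) is treated as non-oscillating: both
#' envelopes equal its slow trend (a 40 ms rolling mean).
#'
#' @param trace A `trace_set`.
#' @param population Population label.
#' @param window Length-2 numeric, ms, within the trace; default the final
#'   second.
#' @return Tibble with `time_ms`, `value`, `upper`, `lower`.
#' @export
envelope <- function(trace, population, window = NULL) {
  if (is.null(window)) window <- c(max(trace$time) - 1000, max(trace$time))
  if (diff(window) < 80) {
    abort("Envelope window must cover at least 80 ms (two cycles at 25 Hz).",
          class = "columnet_config_error")
  }
  tr <- window_trace(trace, population, window)
  ex <- local_extrema(tr$value)
  rng <- diff(range(tr$value))
  flat <- rng <= 1e-9 * max(abs(tr$value), 1e-12)
  if (flat || length(ex$max) < 2 || length(ex$min) < 2) {
    dt_rec <- if (nrow(tr) > 1) tr$time_ms[2] - tr$time_ms[1] else 1
    trend <- rolling_mean(tr$value, round(40 / dt_rec))
    return(mutate(tr, upper = trend, lower = trend))
  }
  up <- approx(tr$time_ms[ex$max], tr$value[ex$max], xout = tr$time_ms,
               rule = 2)$y
  lo <- approx(tr$time_ms[ex$min], tr$value[ex$min], xout = tr$time_ms,
               rule = 2)$y
  mutate(tr, upper = up, lower = lo)
}

#' Oscillation-cycle amplitude of a population trace
#'
#' The scalar amplitude estimator used for regime classification: the mean of
#' `(upper - lower) / 2` over the window (default the final second). Zero for
#' non-oscillating traces.
#'
#' @inheritParams envelope
#' @return Amplitude in Hz.
#' @export
oscillation_amplitude <- function(trace, population, window = NULL) {
  env <- envelope(trace, population, window)
  mean((env$upper - env$lower) / 2)
}

# --- spectra ----------------------------------------------------------------

spectral_prominence <- function(amp, peaks) {
  vapply(peaks, function(i) {
    lmin <- rmin <- min(amp)
    j <- i
    while (j > 1 && amp[j] <= amp[i]) j <- j - 1
    lmin <- if (amp[j] > amp[i]) min(amp[j:i]) else min(amp[1:i])
    j <- i
    n <- length(amp)
    while (j < n && amp[j] <= amp[i]) j <- j + 1
    rmin <- if (amp[j] > amp[i]) min(amp[i:j]) else min(amp[i:n])
    amp[i] - max(lmin, rmin)
  }, numeric(1))
}

#' Amplitude spectrum of a population trace
#'
#' Magnitude spectrum of the mean-subtracted rate in the analysis window
#' (default the final second, giving 1 Hz resolution), without tapering.
#' Spectral peaks are local maxima with prominence at least `prominence_frac`
#' of the global spectral maximum. Band amplitudes are the maximum amplitude
#' in the beta band `[12.5, 25)` Hz and gamma band `[25, 100]` Hz (the bands
#' meet at 25 Hz).
#'
#' @inheritParams envelope
#' @param max_freq Truncate the reported spectrum above this frequency, Hz.
#' @param prominence_frac Peak-prominence threshold as a fraction of the
#'   spectral maximum.
#' @param taper Apply a Hann taper before the transform (off by default).
#' @return A `spectral_summary`: list with tibble `spectrum`
#'   (`freq_hz`, `amplitude`), tibble `peaks` (with prominences, sorted by
#'   frequency), `peak_freq` (dominant peak, Hz), `gamma_amp`, `beta_amp`.
#' @export
amplitude_spectrum <- function(trace, population, window = NULL,
                               max_freq = 200, prominence_frac = 0.05,
                               taper = FALSE) {
  if (is.null(window)) window <- c(max(trace$time) - 1000, max(trace$time))
  tr <- window_trace(trace, population, window)
  x <- tr$value - mean(tr$value)
  n <- length(x)
  if (n < 16) abort("Spectrum window too short.", class = "columnet_config_error")
  if (taper) x <- x * (0.5 - 0.5 * cos(2 * pi * seq0(n) / (n - 1)))
  dt_s <- (tr$time_ms[2] - tr$time_ms[1]) / 1000
  nf <- floor(n / 2)
  amp <- 2 * Mod(fft(x))[seq_len(nf)] / n
  freq <- (seq_len(nf) - 1) / (n * dt_s)
  keep <- freq <= max_freq
  amp <- amp[keep]; freq <- freq[keep]

  ex <- local_extrema(amp)
  prom <- spectral_prominence(amp, ex$max)
  sel <- prom >= prominence_frac * max(amp)
  peaks <- tibble(freq_hz = freq[ex$max][sel], amplitude = amp[ex$max][sel],
                  prominence = prom[sel]) |>
    arrange(.data$freq_hz)

  in_gamma <- freq >= 25 & freq <= 100
  in_beta <- freq >= 12.5 & freq < 25
  structure(
    list(
      spectrum = tibble(freq_hz = freq, amplitude = amp),
      peaks = peaks,
      peak_freq = freq[which.max(amp)],
      gamma_amp = if (any(in_gamma)) max(amp[in_gamma]) else 0,
      beta_amp = if (any(in_beta)) max(amp[in_beta]) else 0,
      population = population,
      condition = trace$condition,
      window = window
    ),
    class = "spectral_summary"
  )
}

seq0 <- function(n) seq_len(n) - 1

#' @export
print.spectral_summary <- function(x, ...) {
  cat("<spectral_summary> ", x$population, " under ", x$condition,
      ": dominant peak ", round(x$peak_freq, 2), " Hz; gamma ",
      signif(x$gamma_amp, 3), ", beta ", signif(x$beta_amp, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname amplitude_spectrum
#' @param x A `spectral_summary`.
#' @param ... Unused.
#' @export
tidy.spectral_summary <- function(x, ...) x$spectrum

# --- settling ---------------------------------------------------------------

#' Time to reach the new steady oscillation amplitude after stimulus onset
#'
#' Tracks the cycle amplitude `(upper - lower)/2` from onset onwards and
#' returns the first time after which it stays within a relative tolerance
#' band of its final-second mean for the remainder of the trace; `Inf` if the
#' band is never held (e.g. slow drift or aperiodic fluctuations).
#'
#' @inheritParams envelope
#' @param tol Relative tolerance band around the final-second mean amplitude.
#' @param final_window Length of the trailing reference window, ms.
#' @return Settle time in ms past onset (0 if already settled at onset).
#' @export
settle_time <- function(trace, population, tol = 0.05, final_window = 1000) {
  t_end <- max(trace$time)
  onset <- trace$t_onset
  if (t_end - onset < 3 * final_window) {
    abort("Trace must extend at least 3 s past onset to measure settling.",
          class = "columnet_config_error")
  }
  env <- envelope(trace, population, window = c(onset, t_end))
  amp <- (env$upper - env$lower) / 2
  final_mean <- mean(amp[env$time_ms >= t_end - final_window])
  floor_hz <- 1e-6
  ok <- abs(amp - final_mean) <= tol * max(final_mean, floor_hz)
  if (all(ok)) return(0)
  last_bad <- max(which(!ok))
  if (last_bad >= length(ok)) return(Inf)
  env$time_ms[last_bad + 1L] - onset
}

# --- regime classification --------------------------------------------------

#' Classify the dynamical regime at one parameter point
#'
#' From the six-condition trace set at one `(delta_e, delta_i)` point,
#' determines:
#' * `oscillating` — final-second cycle amplitude of `population_l5` under
#'   `S1S2_A1` exceeds `eps_osc` times its mean rate;
#' * `ordered_pattern` — the layer-5 amplitude ordering
#'   `{S1, S1S2_A1} > S1S2 > {S1S2_A2, S2}`, every inequality by relative
#'   margin `eps_ord`;
#' * `wta` — attended-versus-unattended comparison of the layer-2/3
#'   amplitude: `S1S2_A1` larger by the margin means winner-take-all,
#'   smaller means anti-winner-take-all, inside the margin `neither`;
#' * `concurrent` — ordered pattern together with anti-WTA;
#' * `bands` — spectral content of `S1S2_A1` (`gamma_only`,
#'   `beta_and_gamma`, or `aperiodic_mixed` when beta is present and the
#'   amplitude never settles);
#' * `region_color` — the parameter-plane palette: `blue` no oscillation,
#'   `green` oscillating without the ordered pattern, `red` ordered with pure
#'   gamma, `yellow` ordered with beta content.
#'
#' @param traces Named list of `trace_set` objects covering conditions
#'   `none`, `S1`, `S2`, `S1S2`, `S1S2_A1`, `S1S2_A2`.
#' @param population_l5,population_l23 Labels of the layer-5 and layer-2/3
#'   excitatory populations scored (column 1 by default).
#' @param eps_ord Relative margin of every amplitude inequality.
#' @param eps_osc Relative oscillation floor (amplitude / mean rate).
#' @param band_floor Beta amplitude below `band_floor * gamma_amp` counts as
#'   absent.
#' @return A one-row tibble of class `regime_label` with the flags above and
#'   the underlying per-condition amplitudes as an attribute `metrics`.
#' @export
classify_regime <- function(traces, population_l5 = "1L5E",
                            population_l23 = "1L2/3E",
                            eps_ord = 0.02, eps_osc = 1e-3,
                            band_floor = 0.05) {
  need <- c("none", "S1", "S2", "S1S2", "S1S2_A1", "S1S2_A2")
  missing_cond <- setdiff(need, names(traces))
  if (length(missing_cond)) {
    abort(paste0("Missing condition(s): ", paste(missing_cond, collapse = ", ")),
          class = "columnet_config_error")
  }
  amp5 <- vapply(need, function(cc)
    oscillation_amplitude(traces[[cc]], population_l5), numeric(1))
  amp23 <- vapply(c("S1S2_A1", "S1S2_A2"), function(cc)
    oscillation_amplitude(traces[[cc]], population_l23), numeric(1))
  ref <- traces$S1S2_A1
  w <- c(max(ref$time) - 1000, max(ref$time))
  mean5 <- mean(window_trace(ref, population_l5, w)$value)

  gt <- function(a, b) a > b * (1 + eps_ord) + 1e-12
  oscillating <- amp5[["S1S2_A1"]] > eps_osc * max(mean5, 1e-9)
  ordered <- oscillating &&
    gt(min(amp5[["S1"]], amp5[["S1S2_A1"]]), amp5[["S1S2"]]) &&
    gt(amp5[["S1S2"]], max(amp5[["S1S2_A2"]], amp5[["S2"]]))
  wta <- if (!oscillating) "neither"
    else if (gt(amp23[["S1S2_A1"]], amp23[["S1S2_A2"]])) "wta"
    else if (gt(amp23[["S1S2_A2"]], amp23[["S1S2_A1"]])) "anti_wta"
    else "neither"
  concurrent <- ordered && wta == "anti_wta"

  spx <- amplitude_spectrum(ref, population_l5)
  beta_present <- spx$beta_amp > band_floor * max(spx$gamma_amp, 1e-12)
  settled <- tryCatch(is.finite(settle_time(ref, population_l5)),
                      error = function(e) TRUE)
  bands <- if (!oscillating) NA_character_
    else if (beta_present && !settled) "aperiodic_mixed"
    else if (beta_present) "beta_and_gamma"
    else "gamma_only"

  region <- if (!oscillating) "blue"
    else if (!ordered) "green"
    else if (identical(bands, "gamma_only")) "red"
    else if (bands %in% c("beta_and_gamma", "aperiodic_mixed")) "yellow"
    else "other"

  out <- tibble(
    oscillating = oscillating, bands = bands, ordered_pattern = ordered,
    wta = wta, concurrent = concurrent, region_color = region
  )
  attr(out, "metrics") <- tibble(
    population = c(rep(population_l5, length(amp5)),
                   rep(population_l23, length(amp23))),
    condition = c(names(amp5), names(amp23)),
    amplitude_hz = c(amp5, amp23)
  )
  class(out) <- c("regime_label", class(out))
  out
}

# --- normalized rates -------------------------------------------------------

#' Min-max normalized steady firing rates across the six conditions
#'
#' For one population, takes the mean rate over the final-second window under
#' each of the six conditions (spontaneous baseline plus the five stimulus
#' conditions) and maps them through `(x - min) / (max - min)`, so the
#' largest response is 1 and the smallest 0.
#'
#' @inheritParams classify_regime
#' @param population Population label.
#' @param window Trailing window length, ms.
#' @return Tibble with `condition`, `mean_rate_hz`, `normalized`.
#' @export
normalized_rates <- function(traces, population, window = 1000) {
  need <- c("none", "S1", "S2", "S1S2", "S1S2_A1", "S1S2_A2")
  missing_cond <- setdiff(need, names(traces))
  if (length(missing_cond)) {
    abort(paste0("Missing condition(s): ", paste(missing_cond, collapse = ", ")),
          class = "columnet_config_error")
  }
  rates <- vapply(need, function(cc) {
    tr <- traces[[cc]]
    mean(window_trace(tr, population,
                      c(max(tr$time) - window, max(tr$time)))$value)
  }, numeric(1))
  rng <- range(rates)
  if (diff(rng) <= .Machine$double.eps * max(abs(rng), 1)) {
    warn("Degenerate flat response across conditions; normalized values set to 0.5.")
    norm <- rep(0.5, length(rates))
  } else {
    norm <- (rates - rng[1]) / diff(rng)
  }
  tibble(condition = need, mean_rate_hz = unname(rates),
         normalized = unname(norm))
}

# --- parameter-plane sweep --------------------------------------------------

#' Sweep the heterogeneity parameter plane
#'
#' Runs the full stimulus-condition set at every `(delta_e, delta_i)` grid
#' point, classifies each point with [classify_regime()], and returns the
#' labeled map. Grid points are independent; a simulation failure at one
#' point is recorded as a `failed` cell and never aborts the sweep.
#'
#' @param delta_e,delta_i Numeric vectors of heterogeneity half-widths
#'   spanning the grid.
#' @param perturbation Structural perturbation applied at every point.
#' @param t_total,t_onset Simulation horizon and onset, ms.
#' @param ... Further arguments to [classify_regime()].
#' @return A tibble of class `regime_map`: one row per grid point with the
#'   regime flags and a `failed` indicator.
#' @export
sweep_plane <- function(delta_e, delta_i, perturbation = "none",
                        t_total = 10000, t_onset = 5000, ...) {
  grid <- tidyr::expand_grid(delta_e = delta_e, delta_i = delta_i)
  rows <- purrr::pmap_dfr(grid, function(delta_e, delta_i) {
    res <- tryCatch({
      net <- build_network(delta_e, delta_i, perturbation = perturbation)
      traces <- simulate_conditions(net, t_total = t_total, t_onset = t_onset)
      lab <- classify_regime(traces, ...)
      mutate(as_tibble(lab), failed = FALSE, message = NA_character_)
    }, error = function(e) {
      tibble(oscillating = NA, bands = NA_character_, ordered_pattern = NA,
             wta = NA_character_, concurrent = NA, region_color = "failed",
             failed = TRUE, message = conditionMessage(e))
    })
    mutate(res, delta_e = delta_e, delta_i = delta_i, .before = 1)
  })
  structure(mutate(rows, perturbation = perturbation),
            class = c("regime_map", class(rows)))
}
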