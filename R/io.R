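# Configuration serialization (YAML), trace writers, run manifests and
# test fixtures.

#' Serialize a network to a configuration list / file
#'
#' The configuration has sections `heterogeneity` (delta_e, delta_i,
#' i_back_e), `perturbation`, `populations` (neuron counts) and `pathways`
#' (column-1 intra-column probabilities as `"<source>-><target>"` keys,
#' class-wise peak conductances, `p_inter`). [read_network_config()] rebuilds
#' an identical network.
#'
#' @param network A `column_network` (two-column form).
#' @param path Optional file path; when given the YAML text is written there.
#' @return The configuration list, invisibly when `path` is given.
#' @export
network_config <- function(network, path = NULL) {
  stopifnot(inherits(network, "column_network"))
  pops <- network$populations
  counts <- filter(pops, .data$column == 1)
  counts <- setNames(as.list(counts$N), sub("^1", "", counts$name))
  # column-1 pathway probabilities, keys without the column prefix.
  # For perturbed networks these are the *unperturbed* table values so the
  # config round-trips: perturbations are re-applied on rebuild.
  base <- build_network(network$delta_e, network$delta_i,
                        perturbation = "none", p_inter = network$p_inter,
                        i_back_e = network$i_back_e)
  pw <- filter(base$pathways, grepl("^1", .data$source), grepl("^1", .data$target))
  p_keys <- paste0(sub("^1", "", pw$source), "->", sub("^1", "", pw$target))
  g_peak <- .default_g_peak
  for (cls in names(g_peak)) {
    sc <- substr(cls, 1, 1); tc <- substr(cls, 4, 4)
    row <- filter(network$pathways,
                  grepl(paste0(sc, "$"), .data$source),
                  grepl(paste0(tc, "$"), .data$target))
    if (nrow(row)) g_peak[cls] <- row$g_peak[1]
  }
  cfg <- list(
    heterogeneity = list(delta_e = network$delta_e,
                         delta_i = network$delta_i,
                         i_back_e = network$i_back_e),
    perturbation = network$perturbation,
    populations = counts,
    pathways = list(p_intra = setNames(as.list(pw$P), p_keys),
                    g_peak = as.list(g_peak),
                    p_inter = network$p_inter)
  )
  if (!is.null(path)) {
    yaml::write_yaml(cfg, path, precision = 15)
    return(invisible(cfg))
  }
  cfg
}

#' Rebuild a network from a configuration list or YAML file
#'
#' @param config A list as produced by [network_config()], or a path to a
#'   YAML file of that shape.
#' @return A `column_network`.
#' @export
read_network_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  het <- config$heterogeneity
  if (is.null(het$delta_e) || is.null(het$delta_i)) {
    abort("Config field `heterogeneity$delta_e`/`delta_i` is missing.",
          class = "columnet_config_error")
  }
  overrides <- list()
  if (!is.null(config$populations)) {
    overrides$counts <- unlist(config$populations)
  }
  if (!is.null(config$pathways$p_intra)) {
    overrides$p_intra <- config$pathways$p_intra
  }
  if (!is.null(config$pathways$g_peak)) {
    overrides$g_peak <- unlist(config$pathways$g_peak)
  }
  build_network(
    delta_e = het$delta_e, delta_i = het$delta_i,
    perturbation = config$perturbation %||% "none",
    p_inter = config$pathways$p_inter %||% .default_p_inter,
    i_back_e = het$i_back_e %||% .default_drive$i_back_E,
    overrides = if (length(overrides)) overrides else NULL
  )
}

#' Write a trace set to CSV (with JSON sidecar)
#'
#' Columns: `time_ms`, then one rate column per population (Hz) and
#' optionally one voltage column per population (mV). A JSON sidecar
#' `<path>.json` records the condition, simulation settings and the network
#' fingerprint.
#'
#' @param trace A `trace_set`.
#' @param path Output CSV path.
#' @param voltages Include mean-voltage columns.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path, voltages = FALSE) {
  stopifnot(inherits(trace, "trace_set"))
  df <- data.frame(time_ms = trace$time, check.names = FALSE)
  rt <- as.data.frame(trace$rates)
  names(rt) <- paste0("r_", colnames(trace$rates))
  df <- cbind(df, rt)
  if (voltages) {
    vt <- as.data.frame(trace$voltages)
    names(vt) <- paste0("v_", colnames(trace$voltages))
    df <- cbind(df, vt)
  }
  utils::write.csv(df, path, row.names = FALSE)
  sidecar <- list(condition = trace$condition, dt = trace$dt,
                  t_total = trace$t_total, t_onset = trace$t_onset,
                  record_stride = trace$record_stride,
                  fingerprint = trace$fingerprint)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records what produced a set of artifacts: the command, a configuration
#' snapshot, the network fingerprint, package version, timestamp, seed and
#' output paths.
#'
#' @param path Manifest path (JSON).
#' @param command Character description of the invocation.
#' @param config Configuration list snapshot.
#' @param outputs Character vector of output file paths.
#' @param fingerprint Network fingerprint.
#' @param seed Seed recorded for the run (the mean-field is deterministic,
#'   but the field is always present).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, config, outputs,
                           fingerprint = NULL, seed = NA_integer_) {
  manifest <- list(
    command = command,
    config = config,
    fingerprint = fingerprint,
    package_version = as.character(utils::packageVersion("columnet")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    outputs = as.list(outputs)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Synthetic sinusoidal trace
#'
#' A `trace_set` holding `offset + amplitude * sin(2 pi f t)` for a single
#' synthetic population; used to test envelope extraction and spectra
#' against their analytic values.
#'
#' @param f_hz Frequency, Hz.
#' @param amplitude,offset Amplitude and offset, Hz.
#' @param t_total Duration, ms.
#' @param dt_rec Sampling interval, ms.
#' @param population Label of the synthetic population.
#' @return A `trace_set` with one population.
#' @export
synthetic_trace <- function(f_hz = 30, amplitude = 1, offset = 10,
                            t_total = 2000, dt_rec = 0.1,
                            population = "synthetic") {
  time <- seq(0, t_total, by = dt_rec)
  r <- offset + amplitude * sin(2 * pi * f_hz * time / 1000)
  rates <- matrix(r, ncol = 1, dimnames = list(NULL, population))
  structure(list(time = time, rates = rates,
                 voltages = matrix(NA_real_, nrow = length(time), ncol = 1,
                                   dimnames = list(NULL, population)),
                 condition = "synthetic", dt = dt_rec, t_total = t_total,
                 t_onset = 0, record_stride = 1L, network = NULL,
                 fingerprint = "synthetic"),
            class = "trace_set")
}

#' Bundled test fixtures
#'
#' * `"sinusoid"`: an analytic 30 Hz sinusoid trace plus its expected
#'   envelope and spectral peak;
#' * `"ei_pair"`: the two-population E-I fixture network plus the closed-form
#'   subthreshold voltage fixed point of the isolated excitatory population;
#' * `"table_network"`: the full two-column network at the reference
#'   heterogeneity point together with its configuration list.
#'
#' @param kind One of `"sinusoid"`, `"ei_pair"`, `"table_network"`.
#' @return A list bundling the object and its expected values.
#' @export
make_fixture <- function(kind = c("sinusoid", "ei_pair", "table_network")) {
  kind <- match.arg(kind)
  switch(kind,
    sinusoid = {
      tr <- synthetic_trace(f_hz = 30, amplitude = 1, offset = 10)
      list(trace = tr,
           expected = list(peak_freq = 30, upper = 11, lower = 9))
    },
    ei_pair = {
      net <- ei_network()
      pe <- filter(net$populations, .data$cell_class == "E")
      # smaller root of zeta v^2 + eta v + kappa + I/C = 0 (subthreshold drive)
      disc <- pe$eta^2 - 4 * pe$zeta * (pe$kappa + pe$I_back_center / pe$C)
      v_fp <- if (disc >= 0) (-pe$eta - sqrt(disc)) / (2 * pe$zeta) else NA_real_
      list(network = net, expected = list(v_fixed_point = v_fp))
    },
    table_network = {
      net <- build_network(0.3, 0.02)
      list(network = net, expected = list(config = network_config(net)))
    }
  )
}
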