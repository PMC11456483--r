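#' Build the two-column cortical network
#'
#' Assembles the sixteen-population (2 columns x 4 layers x E/I) network:
#' per-population biophysics and QIF constants, Lorentzian background-current
#' parameters, the full intra-column connection-probability matrix replicated
#' in both columns, the two inter-column pathways (L2/3E to the contralateral
#' L2/3I), and an optional structural perturbation.
#'
#' Background-current centers obey the fixed ratio
#' \eqn{\bar I_{back,E} : \bar I_{back,I} = 1 : 0.8}; the swept heterogeneity
#' parameters `delta_e` and `delta_i` are the half-widths of the Lorentzian
#' background-current distribution of excitatory and inhibitory populations.
#'
#' Perturbations never delete populations; they zero connection
#' probabilities, so the state-vector layout is identical across experiments:
#' * `"remove_layer6"`: every pathway with a layer-6 endpoint gets P = 0;
#' * `"block_L6E_to_L4I"`: P(L6E -> L4I) = 0 in both columns;
#' * `"block_L6E_to_L4E"`: P(L6E -> L4E) = 0 in both columns.
#'
#' @param delta_e,delta_i Half-width of the background-current distribution
#'   for excitatory / inhibitory populations, mA/cm^2.
#' @param perturbation One of `"none"`, `"remove_layer6"`,
#'   `"block_L6E_to_L4I"`, `"block_L6E_to_L4E"`.
#' @param p_inter Inter-column connection probability of the
#'   L2/3E -> contralateral L2/3I pathways.
#' @param i_back_e Center of the excitatory background current, mA/cm^2.
#'   The inhibitory center is `0.8 * i_back_e`.
#' @param overrides Optional named list of table overrides:
#'   `counts` (named vector, e.g. `c("L5E" = 1000)`),
#'   `p_intra` (named entries `"<source>-><target>" = P`, per-layer labels),
#'   `g_peak` (named vector over `"E->E"`, `"E->I"`, `"I->E"`, `"I->I"`).
#'
#' @return An object of class `column_network`: a list with tibbles
#'   `populations` (one row per population, with derived `zeta`, `eta`,
#'   `kappa`) and `pathways` (`source`, `target`, `P`, `g_peak`), plus the
#'   scalar settings.
#' @export
#' @examples
#' net <- build_network(delta_e = 0.3, delta_i = 0.02)
#' net$populations
#' dplyr::filter(net$pathways, target == "1L5E", source == "1L5I")
build_network <- function(delta_e, delta_i,
                          perturbation = c("none", "remove_layer6",
                                           "block_L6E_to_L4I",
                                           "block_L6E_to_L4E"),
                          p_inter = .default_p_inter,
                          i_back_e = .default_drive$i_back_E,
                          overrides = NULL) {
  perturbation <- match.arg(perturbation)
  if (!is.numeric(delta_e) || !is.numeric(delta_i) ||
      delta_e <= 0 || delta_i <= 0) {
    abort("`delta_e` and `delta_i` must be positive heterogeneity half-widths.",
          class = "columnet_config_error")
  }
  if (p_inter < 0 || p_inter > 1) {
    abort("`p_inter` must be a probability.", class = "columnet_config_error")
  }

  counts <- .default_counts
  p_intra <- .default_p_intra
  g_peak <- .default_g_peak
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), c("counts", "p_intra", "g_peak"))
    if (length(unknown)) {
      abort(paste0("Unknown override section(s): ",
                   paste(unknown, collapse = ", ")),
            class = "columnet_config_error")
    }
    if (!is.null(overrides$counts)) {
      bad <- setdiff(names(overrides$counts), names(counts))
      if (length(bad)) {
        abort(paste0("Unknown population label in counts override: ",
                     paste(bad, collapse = ", ")),
              class = "columnet_config_error")
      }
      counts[names(overrides$counts)] <- overrides$counts
    }
    if (!is.null(overrides$p_intra)) {
      for (key in names(overrides$p_intra)) {
        ends <- strsplit(key, "->", fixed = TRUE)[[1]]
        if (length(ends) != 2 || !all(ends %in% .pop_order_intra)) {
          abort(paste0("Unknown pathway override key: ", key),
                class = "columnet_config_error")
        }
        val <- overrides$p_intra[[key]]
        if (val < 0 || val > 1) {
          abort("Connection probabilities must lie in [0, 1].",
                class = "columnet_config_error")
        }
        p_intra[ends[2], ends[1]] <- val
      }
    }
    if (!is.null(overrides$g_peak)) {
      bad <- setdiff(names(overrides$g_peak), names(g_peak))
      if (length(bad)) {
        abort(paste0("Unknown conductance class: ", paste(bad, collapse = ", ")),
              class = "columnet_config_error")
      }
      if (any(overrides$g_peak <= 0)) {
        abort("Peak conductances must be positive.",
              class = "columnet_config_error")
      }
      g_peak[names(overrides$g_peak)] <- overrides$g_peak
    }
  }

  bio <- .default_biophys
  pops <- tidyr::expand_grid(column = 1:2, pop = .pop_order_intra) |>
    mutate(
      name = paste0(.data$column, .data$pop),
      layer = sub("[EI]$", "", .data$pop),
      cell_class = sub("^.*(E|I)$", "\\1", .data$pop),
      N = unname(counts[.data$pop]),
      C = bio$C,
      g_L = unname(bio$g_L[.data$cell_class]),
      V_R = bio$V_R,
      V_T = bio$V_T,
      V_syn_out = unname(bio$V_syn[.data$cell_class]),
      tau_d = unname(bio$tau_d[.data$cell_class]),
      I_back_center = ifelse(.data$cell_class == "E",
                             i_back_e, .default_drive$i_back_I_ratio * i_back_e),
      I_back_width = ifelse(.data$cell_class == "E", delta_e, delta_i)
    ) |>
    select(-"pop")
  pops <- bind_cols(pops, qif_constants(pops$g_L, pops$C, pops$V_R, pops$V_T)) |>
    relocate("name")

  # Intra-column pathways: every nonzero entry of the probability table,
  # replicated per column (the model is column-symmetric by construction).
  idx <- which(p_intra > 0, arr.ind = TRUE)
  intra <- purrr::map_dfr(1:2, function(col) {
    tibble(
      source = paste0(col, colnames(p_intra)[idx[, "col"]]),
      target = paste0(col, rownames(p_intra)[idx[, "row"]]),
      P = p_intra[idx]
    )
  })
  inter <- tibble(
    source = c("1L2/3E", "2L2/3E"),
    target = c("2L2/3I", "1L2/3I"),
    P = p_inter
  )
  paths <- bind_rows(intra, inter) |>
    mutate(
      source_class = ifelse(grepl("E$", .data$source), "E", "I"),
      target_class = ifelse(grepl("E$", .data$target), "E", "I"),
      g_peak = unname(g_peak[paste0(.data$source_class, "->",
                                    .data$target_class)])
    ) |>
    select("source", "target", "P", "g_peak")

  paths <- apply_perturbation(paths, perturbation)

  structure(
    list(
      populations = pops,
      pathways = paths,
      perturbation = perturbation,
      delta_e = delta_e,
      delta_i = delta_i,
      p_inter = p_inter,
      i_back_e = i_back_e
    ),
    class = "column_network"
  )
}

apply_perturbation <- function(paths, perturbation) {
  layer_of <- function(x) sub("^[12]", "", sub("[EI]$", "", x))
  switch(perturbation,
    none = paths,
    remove_layer6 = mutate(paths, P = ifelse(
      layer_of(.data$source) == "L6" | layer_of(.data$target) == "L6",
      0, .data$P)),
    block_L6E_to_L4I = mutate(paths, P = ifelse(
      grepl("L6E$", .data$source) & grepl("L4I$", .data$target), 0, .data$P)),
    block_L6E_to_L4E = mutate(paths, P = ifelse(
      grepl("L6E$", .data$source) & grepl("L4E$", .data$target), 0, .data$P))
  )
}

#' @export
print.column_network <- function(x, ...) {
  cat("<column_network> 16 populations, ", nrow(x$pathways), " pathways\n",
      "  delta_back(E, I) = (", x$delta_e, ", ", x$delta_i, ")",
      "  perturbation: ", x$perturbation, "\n", sep = "")
  invisible(x)
}

#' Neuron counts per population
#'
#' @param network A `column_network`.
#' @return Tibble with `name` and `N`.
#' @export
population_counts <- function(network) {
  stopifnot(inherits(network, "column_network"))
  select(network$populations, "name", "N")
}
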