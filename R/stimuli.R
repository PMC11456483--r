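.conditions <- c("none", "S1", "S2", "S1S2", "S1S2_A1", "S1S2_A2",
                 "A1_only", "A2_only")

#' Stimulus conditions
#'
#' The experiment mimics competing oriented-bar stimuli: column 1 prefers one
#' orientation, column 2 the orthogonal one. `S1`/`S2` present a single bar
#' (preferred by column 1 / column 2), `S1S2` presents both, and
#' `S1S2_A1`/`S1S2_A2` add top-down attention to the bar preferred by the
#' indicated column. `A1_only`/`A2_only` deliver attention without any
#' sensory input. `none` is the spontaneous baseline.
#'
#' @return Character vector of valid condition names.
#' @export
stimulus_conditions <- function() .conditions

#' Per-population external currents of a stimulus condition
#'
#' Maps a condition to the constant sensory and attention currents delivered
#' to each population once the stimulus is on (before onset all external
#' currents are zero; the onset itself is a property of the simulation).
#'
#' Sensory input reaches only layer 4 (E and I), scaled by the sensory
#' projection probabilities; the bar preferred by a column drives that column
#' with the full base amplitude and the other column with `1/preferred_ratio`
#' of it, and the two bars of `S1S2` add independently. Attention reaches
#' only layers 2/3 and 5 of the attended column, scaled by the attention
#' projection probabilities. Layer 6 receives no external drive under any
#' condition.
#'
#' The delivered current is `base * projection probability`; the default
#' base amplitudes are chosen so that the excitatory targets receive the
#' nominal stimulus currents (0.06 mA/cm^2 sensory onto L4E, 0.02 mA/cm^2
#' attention onto L2/3E and L5E), which keeps the delivered
#' sensory : attention : background ratio at 9 : 3 : 16.
#'
#' @param network A `column_network`.
#' @param condition One of [stimulus_conditions()].
#' @param sensory_base Sensory base amplitude, mA/cm^2 (delivered current is
#'   this times the layer-wise projection probability of the target).
#' @param attention_base Attention base amplitude, mA/cm^2.
#' @param preferred_ratio Preferred-to-unpreferred sensory input ratio.
#'
#' @return Tibble with one row per population: `name`, `I_sens`, `I_attn`
#'   (mA/cm^2).
#' @export
#' @examples
#' net <- build_network(0.3, 0.02)
#' condition_currents(net, "S1S2_A1")
condition_currents <- function(network, condition,
                               sensory_base = .default_drive$sensory_base,
                               attention_base = .default_drive$attention_base,
                               preferred_ratio = .default_drive$preferred_ratio) {
  stopifnot(inherits(network, "column_network"))
  if (!is.character(condition) || length(condition) != 1 ||
      !condition %in% .conditions) {
    abort(paste0("Unknown condition `", paste(condition, collapse = ","),
                 "`. Valid conditions: ",
                 paste(.conditions, collapse = ", ")),
          class = "columnet_config_error")
  }

  # Per-column multiplier of the sensory base for each presented bar.
  sens_factor <- c(0, 0)
  if (condition %in% c("S1", "S1S2", "S1S2_A1", "S1S2_A2")) {
    sens_factor <- sens_factor + c(1, 1 / preferred_ratio)
  }
  if (condition %in% c("S2", "S1S2", "S1S2_A1", "S1S2_A2")) {
    sens_factor <- sens_factor + c(1 / preferred_ratio, 1)
  }
  attn_col <- switch(condition,
                     S1S2_A1 = 1, A1_only = 1,
                     S1S2_A2 = 2, A2_only = 2,
                     0)

  proj <- .default_projection
  network$populations |>
    mutate(
      pop = sub("^[12]", "", .data$name),
      I_sens = sensory_base * sens_factor[.data$column] *
        proj$sensory[match(.data$pop, proj$pop)],
      I_attn = ifelse(.data$column == attn_col,
                      attention_base * proj$attention[match(.data$pop, proj$pop)],
                      0)
    ) |>
    select("name", "I_sens", "I_attn")
}
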