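# Default biophysical and structural constants of the two-column microcircuit.
# Units: mV, ms, uF/cm^2, mS/cm^2, mA/cm^2 throughout; firing rate is carried
# internally in ms^-1 and converted to Hz only when reported.

.layers <- c("L2/3", "L4", "L5", "L6")
.pop_types <- c("E", "I")

# Within-column population order; full order is column 1 then column 2.
.pop_order_intra <- as.vector(t(outer(.layers, .pop_types, paste0)))

#' Canonical population labels of the two-column network
#'
#' Sixteen labels in canonical order: column 1 then column 2, layers in
#' cortical depth order (L2/3, L4, L5, L6), excitatory before inhibitory
#' within a layer. Labels follow the `"<column><layer><E|I>"` convention,
#' e.g. `"1L5E"` is the excitatory population of layer 5 in column 1.
#'
#' @return Character vector of length 16.
#' @export
#' @examples
#' population_labels()
population_labels <- function() {
  as.vector(vapply(1:2, function(col) paste0(col, .pop_order_intra),
                   character(8)))
}

# Neuron counts per population (experimentally constrained microcircuit
# census for one column of early visual cortex).
.default_counts <- c(
  "L2/3E" = 10341, "L2/3I" = 2917,
  "L4E"   = 10957, "L4I"   = 2739,
  "L5E"   = 2425,  "L5I"   = 532,
  "L6E"   = 7197,  "L6I"   = 1474
)

# Intra-column connection probabilities P[target, source].
.default_p_intra <- matrix(c(
  # from:  L2/3E   L2/3I   L4E     L4I     L5E     L5I     L6E     L6I
  0.1184, 0.1552, 0.0846, 0.0629, 0.0323, 0.0,    0.0076, 0.0,    # to L2/3E
  0.1008, 0.1371, 0.0363, 0.0515, 0.0755, 0.0,    0.0042, 0.0,    # to L2/3I
  0.0077, 0.0059, 0.0519, 0.1453, 0.0067, 0.0003, 0.0453, 0.0,    # to L4E
  0.0691, 0.0029, 0.1093, 0.1597, 0.0033, 0.0,    0.1057, 0.0,    # to L4I
  0.1017, 0.0622, 0.0411, 0.0057, 0.0758, 0.3765, 0.0204, 0.0,    # to L5E
  0.0436, 0.0269, 0.0209, 0.0022, 0.0566, 0.3158, 0.0086, 0.0,    # to L5I
  0.0156, 0.0066, 0.0211, 0.0166, 0.0572, 0.0197, 0.0401, 0.2252, # to L6E
  0.0364, 0.0010, 0.0034, 0.0005, 0.0277, 0.0080, 0.0658, 0.1443  # to L6I
), nrow = 8, byrow = TRUE,
  dimnames = list(.pop_order_intra, .pop_order_intra))

# Peak synaptic conductances g-bar (mS/cm^2) by (source class -> target class).
.default_g_peak <- c(
  "E->E" = 4.069e-3, "I->E" = 2.672e-2,
  "E->I" = 3.276e-3, "I->I" = 2.138e-2
)

# Projection probabilities of the external drives onto each layer/class.
# Sensory input targets layer 4 only; attention targets layers 2/3 and 5.
.default_projection <- data.frame(
  pop      = .pop_order_intra,
  sensory  = c(0.0,   0.0,   0.0983, 0.0619, 0.0, 0.0,   0.0, 0.0),
  attention = c(0.1,  0.085, 0.0,    0.0,    0.1, 0.085, 0.0, 0.0)
)

# Membrane / synaptic constants by cell class.
.default_biophys <- list(
  C        = 1,      # uF/cm^2
  g_L      = c(E = 0.08, I = 0.1),   # mS/cm^2
  V_R      = -62,    # mV
  V_T      = -55,    # mV
  V_syn    = c(E = 0, I = -70),      # mV, reversal of outgoing synapses
  tau_d    = c(E = 2, I = 5)         # ms, decay of outgoing synapses
)

# External-drive amplitudes. The model fixes the attention current at
# 0.02 mA/cm^2 and the ratio I_sens : I_attn : I_back = 9 : 3 : 16; these
# are read as the currents DELIVERED to the excitatory target populations
# (the projection probabilities then set the E/I asymmetry), so the base
# amplitudes below are delivered value / excitatory projection probability:
# 0.06/0.0983 for sensory onto L4E, 0.02/0.1 for attention onto L2/3E & L5E.
# The excitatory background center is 0.02 * 16/3; background to inhibitory
# populations is scaled by 0.8.
.default_drive <- list(
  attention_base  = 0.02 / 0.1,    # delivers 0.02 mA/cm^2 to L2/3E, L5E
  sensory_base    = 0.06 / 0.0983, # delivers 0.06 mA/cm^2 to L4E
  i_back_E        = 0.02 * 16 / 3, # ~0.10667 mA/cm^2
  i_back_I_ratio  = 0.8,
  preferred_ratio = 10             # preferred : unpreferred sensory input
)

.default_p_inter <- 0.1

.perturbations <- c("none", "remove_layer6", "block_L6E_to_L4I",
                    "block_L6E_to_L4E")
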