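#' Derived constants of the quadratic integrate-and-fire voltage equation
#'
#' Rewrites the QIF subthreshold dynamics
#' \deqn{C \dot V = g_L (V - V_R)(V - V_T)/(V_T - V_R)}
#' in the monic quadratic form \eqn{\dot V = \zeta V^2 + \eta V + \kappa}
#' used by the mean-field reduction, with
#' \deqn{\zeta = \frac{g_L}{C (V_T - V_R)}, \quad
#'       \eta  = \frac{-g_L (V_T + V_R)}{C (V_T - V_R)}, \quad
#'       \kappa = \frac{g_L V_T V_R}{C (V_T - V_R)}.}
#' By construction \eqn{\zeta V^2 + \eta V + \kappa =
#' \zeta (V - V_R)(V - V_T)}, so the quadratic's roots are exactly the
#' resting potential and the firing threshold.
#'
#' @param g_L Leak conductance, mS/cm^2. May be a vector.
#' @param C Membrane capacitance, uF/cm^2.
#' @param V_R Resting potential, mV.
#' @param V_T Firing threshold, mV; must exceed `V_R`.
#'
#' @return A tibble with columns `zeta`, `eta`, `kappa` (one row per element
#'   of the recycled inputs).
#' @export
#' @examples
#' qif_constants(g_L = c(0.08, 0.1))
qif_constants <- function(g_L, C = 1, V_R = -62, V_T = -55) {
  if (any(!is.finite(g_L)) || any(g_L <= 0)) {
    abort("`g_L` must be positive and finite.", class = "columnet_config_error")
  }
  if (any(C <= 0)) {
    abort("`C` must be positive.", class = "columnet_config_error")
  }
  if (any(V_T <= V_R)) {
    abort("`V_T` must be strictly greater than `V_R`.",
          class = "columnet_config_error")
  }
  denom <- C * (V_T - V_R)
  tibble(
    zeta  = g_L / denom,
    eta   = -g_L * (V_T + V_R) / denom,
    kappa = g_L * V_T * V_R / denom
  )
}

#' Tonic firing rate of a single QIF neuron under constant drive
#'
#' For a suprathreshold constant current the QIF voltage traverses the real
#' line in finite time; the firing rate is the inverse of that passage time,
#' \eqn{r = \sqrt{4\zeta(\kappa + I) - \eta^2} / (2\pi)} (in ms^-1), and zero
#' for subthreshold drive. Used as the closed-form oracle for the microscopic
#' network.
#'
#' @param I Constant input current, mA/cm^2 (vectorised).
#' @inheritParams qif_constants
#' @return Firing rate in ms^-1 (multiply by 1000 for Hz).
#' @export
qif_tonic_rate <- function(I, g_L = 0.08, C = 1, V_R = -62, V_T = -55) {
  k <- qif_constants(g_L, C, V_R, V_T)
  disc <- 4 * k$zeta * (k$kappa + I / C) - k$eta^2
  ifelse(disc > 0, sqrt(pmax(disc, 0)) / (2 * pi), 0)
}
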