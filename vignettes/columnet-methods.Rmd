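---
title: "Mean-field dynamics of a two-column cortical microcircuit: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-field dynamics of a two-column cortical microcircuit: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`columnet` simulates top-down visual attention in a pair of interacting
cortical columns. Each column carries four layers (L2/3, L4, L5, L6), each
layer an excitatory (E) and an inhibitory (I) population of quadratic
integrate-and-fire (QIF) neurons — sixteen populations in all. The
microscopic voltage equation of neuron $i$ in population $X$ is

$$ C \dot V_i = \frac{g_L (V_i - V_R)(V_i - V_T)}{V_T - V_R}
   - \sum_Y g_{YX} (V_i - V_{syn,Y}) + I_i , $$

with $C = 1\,\mu F/cm^2$, $g_L = 0.08$ (E) or $0.1$ (I) $mS/cm^2$,
$V_R = -62$ mV, $V_T = -55$ mV, and synaptic reversal potentials
$V_{syn} = 0$ mV (excitatory synapses) and $-70$ mV (inhibitory). Each
neuron's background current is drawn once from a Cauchy–Lorentzian
distribution with center $\bar I_{back,X}$ and half-width
$\Delta_{back,X}$; this heterogeneity is the model's central control
parameter and the pair $(\Delta_{back,E}, \Delta_{back,I})$ spans the
parameter plane all regime analyses live on.

Because the heterogeneity is Lorentzian and the voltage equation is
quadratic, the population dynamics reduces *exactly* (in the infinite-size
limit) to three ODEs per population — firing rate $r_X$, mean membrane
voltage $v_X$, and synaptic conductance, the Lorentzian-ansatz reduction.
With $\zeta = g_L / (C (V_T - V_R))$, $\eta = -g_L (V_T+V_R)/(C(V_T-V_R))$,
$\kappa = g_L V_T V_R / (C (V_T - V_R))$ (so that
$\zeta v^2 + \eta v + \kappa = \zeta (v - V_R)(v - V_T)$):

$$ \dot r_X = 2 \zeta_X r_X v_X + \eta_X r_X
   - \frac{r_X}{C} \sum_Y g_{YX} + \frac{\zeta_X}{\pi} \Delta_{back,X} $$

$$ \dot v_X = \zeta_X v_X^2 + \eta_X v_X + \kappa_X
   - \frac{\pi^2}{\zeta_X} r_X^2
   + \frac{1}{C} \Big( \sum_Y g_{YX} V_{syn,Y} - v_X \sum_Y g_{YX} \Big)
   + \bar I_{back,X} + I_{sens,X} + I_{attn,X} $$

$$ \dot g_{YX} = -\frac{g_{YX}}{\tau_{d,Y}}
   + \bar g_{YX} \, P_{YX} \, N_Y \, r_Y $$

### A note on the rate-feedback coefficient

Published statements of this reduction differ in how the $r^2$ term of the
voltage equation is scaled, and transcription slips are common because the
reduction is usually quoted in dimensionless form. We therefore re-derive
it. Substituting $u = \zeta V + \eta/2$ maps the dimensional voltage
equation onto the canonical form $\dot u = u^2 + J$ with
$J = \zeta(\kappa + I) - \eta^2/4$, so a Lorentzian current of half-width
$\Delta$ becomes a canonical drive of half-width $\zeta \Delta$. The
physical firing rate is the probability flux at $V \to \infty$, which for a
Lorentzian voltage density of half-width $x$ equals $r = \zeta x / \pi$.
Carrying both scalings through gives the source term
$\zeta \Delta / \pi$ in $\dot r$ and the feedback term
$-(\pi^2/\zeta)\, r^2$ in $\dot v$ — the form `columnet` integrates
(`mean_field_rhs()` is the executable statement). With the feedback
mis-scaled by $\zeta^2$ the voltage is essentially never reset by
population firing and every oscillatory regime collapses into
near-singular relaxation spikes (peak rates of order $10^5$ Hz) that no
fixed-step integrator can traverse; the correct coefficient yields the
smooth ~30 Hz gamma oscillation the model is known for.

### Conductance aggregation

The pathway conductance ODE is linear and its decay time depends only on
the source class ($\tau_d = 2$ ms for excitatory, $5$ ms for inhibitory
sources). All excitatory afferents onto a target therefore fold into a
single state variable whose drive is $\sum_{Y \in E} \bar g_{YX} P_{YX}
N_Y r_Y$, and likewise for inhibitory afferents: four state variables per
population (64 in all) instead of up to eighteen. The equivalence is exact
up to floating point and is tested against a per-pathway reference
integration.

## Structure and stimuli

Neuron counts, intra-column connection probabilities and class-wise peak
conductances come from the experimentally constrained microcircuit
literature for early visual cortex and ship as the package defaults
(`build_network()`; the full table set round-trips through the YAML
configuration in `inst/extdata/default_config.yaml`). All nonzero table
entries are instantiated — not only the strong pathways usually drawn in
circuit diagrams. The two columns are wired identically; the only
cross-column coupling is L2/3E → contralateral L2/3I with probability 0.1,
which implements stimulus competition.

Sensory drive reaches layer 4 (E and I), attentional drive layers 2/3 and
5 of the attended column; layer 6 receives no external input. Each column
prefers one bar orientation: the preferred column receives ten times the
sensory current of the unpreferred one, and two simultaneously presented
bars add independently. The five stimulus conditions are S1, S2, S1S2,
S1S2+A1, S1S2+A2, plus the spontaneous baseline and two attention-only
conditions.

### Current amplitudes

The model pins the attention current at $0.02$ mA/cm², the current ratio
$I_{sens} : I_{attn} : \bar I_{back} = 9 : 3 : 16$, and
$\bar I_{back,E} : \bar I_{back,I} = 1 : 0.8$. Two readings are possible:
the printed amplitudes could be base values that the layer-wise projection
probabilities then scale down (delivered sensory current
$0.06 \times 0.0983 \approx 0.006$ mA/cm², about 6% of background), or the
currents *as delivered to the excitatory target populations*, with the
projection probabilities only setting the E/I asymmetry within a layer.
`columnet` adopts the delivered reading: base amplitudes $0.06/0.0983$
(sensory) and $0.02/0.1$ (attention), so L4E receives exactly 0.06 and
L2/3E, L5E exactly 0.02 mA/cm². This is the only reading under which both
printed constraints hold for the currents the populations actually see
*and* stimulus conditions separate: under the first reading the delivered
stimuli are a few percent of background, condition differences in L5E
amplitude are ~0.5%, and no amplitude ordering survives a 2% margin
anywhere in the plane. Both amplitudes remain user arguments of
`condition_currents()`/`simulate_columns()`.

## Integration

The reference integrator is fixed-step forward Euler at $dt = 0.01$ ms
(`simulate_columns()`, compiled), 10 s of activity with stimulus onset at
5 s; the 5 s pre-stimulus window washes out the initial transient. Initial
state: $r = 10^{-4}$ ms⁻¹, $v = V_R$, conductances zero. Rates are carried
in ms⁻¹ internally and reported in Hz. Traces are recorded every 10th step
(0.1 ms sampling, Nyquist 5 kHz, far above the gamma band).

Degenerate inputs are guarded: non-finite state or any rate above
`r_ceiling` aborts with the population and time. The ceiling defaults to
50 ms⁻¹ — the spikiest legitimate regimes we simulate (low inhibitory
heterogeneity, e.g. $\Delta_{back,I} \approx 0.01$) reach ~22 ms⁻¹
momentarily, while true divergence exceeds any ceiling within a
millisecond. A one-step relative state change above 0.5 raises a
"dt too large" warning. Halving $dt$ changes the settled cycle amplitude
by under 2% and the spectral peak not at all (first-order convergence,
tested down to $dt = 0.0025$ ms).

## Analysis conventions

* **Envelopes** (`envelope()`): per-cycle local extrema joined by linear
  interpolation; traces without at least two cycles in the window count as
  non-oscillating and both envelopes equal a 40 ms rolling-mean trend.
* **Cycle amplitude**: mean of $(upper - lower)/2$ over the final 1 s
  window — the scalar used for every amplitude comparison.
* **Spectra** (`amplitude_spectrum()`): magnitude FFT of the
  mean-subtracted final second (1 Hz resolution), no taper by default (a
  Hann taper is available); peaks must clear a prominence of 5% of the
  spectral maximum. Beta band $[12.5, 25)$ Hz, gamma $[25, 100]$ Hz; the
  bands meet at the conventional 25 Hz boundary.
* **Settling** (`settle_time()`): first time after stimulus onset at which
  the cycle amplitude enters and stays within 5% of its final-second mean;
  `Inf` if the band is never held.
* **Classification** (`classify_regime()`): oscillation requires a cycle
  amplitude above $10^{-3}$ of the mean rate; the ordered pattern requires
  the L5E amplitude ordering $\{S1, S1S2{+}A1\} > S1S2 > \{S1S2{+}A2,
  S2\}$ with every inequality by a 2% relative margin; winner-take-all
  (WTA) compares the attended column's L2/3E amplitude under S1S2+A1
  versus S1S2+A2 at the same margin, and the *concurrent case* is an
  ordered L5E together with anti-WTA L2/3. Margins make the classifier
  robust to numerical ties; enlarging the ordering margin can only demote
  an ordered point (tested as a monotonicity property).

## The spiking-network check

`simulate_micro()` integrates the finite-size spiking QIF network the
reduction is derived from: per-neuron voltages, background currents drawn
from the population's Lorentzian (inverse-CDF sampling, clipped by default
to the [0.001, 0.999] quantile range to keep tiny populations free of
pathological outliers), Bernoulli connectivity, and conductance jumps of
$\bar g / scale$ per spike so the expected drive matches the mean-field
limit at reduced size. Spike cutoff and reset default to $+200$ and
$-320$ mV — far outside $[V_R, V_T]$, so the finite-cutoff bias of the
inter-spike period is quadratically small; no refractory correction is
applied. The reduction is validated on a two-population E–I fixture
(`ei_network()`, the layer-5 connectivity motif): at 20% of nominal size
the binned spiking rate oscillates within ~15% of the mean-field spectral
peak, and the time-averaged distance to the mean-field trajectory shrinks
as the scale grows.

## What the simulations do and do not show

All experiments in this package are simulations of the mean-field model
itself; the synthetic stimuli are constant currents, not structured visual
input. Passing checks therefore demonstrate properties of the reduced
dynamical system — gamma oscillations, the ordered amplitude pattern,
WTA/anti-WTA competition, and the role of layer-6 pathways — not
predictions about biological tissue beyond what the underlying microcircuit
parameters already encode. Finite-size fluctuations, synaptic rise times,
transmission delays, interneuron subtypes and time-varying stimuli are out
of scope. Exact regime-region boundaries in the $(\Delta_{back,E},
\Delta_{back,I})$ plane are sensitive to the amplitude estimator, the
classification margins, the current calibration and the integrator step;
the package treats its own sweeps' geometry as the reference, and the
region *structure* is what the test suite pins down. In this
implementation the ordered+WTA band spans roughly
$\Delta_{back,E} \in [0.14, 0.5]$ with $\Delta_{back,I} \in [0.01,
0.035]$ (containing the reference point (0.3, 0.02)); anti-WTA bands lie
along the oscillation boundaries; and the concurrent case occupies a
narrow strip at low inhibitory heterogeneity — e.g. (0.14, 0.010) and
(0.20, 0.012), where attending the competing stimulus *raises* the L2/3E
amplitude by >30% while layer 5 keeps its ordered pattern. Removing layer
6 or blocking L6E→L4I eliminates every concurrent point we test while the
ordered pattern survives; blocking L6E→L4E leaves the concurrent case
intact (e.g. at (0.18, 0.012)). Published parameter-plane figures of this
model family place the concurrent markers at high heterogeneity instead
(around (0.42–0.46, 0.044–0.045)); at those exact coordinates our
realization shows small, co-directional attention effects in L5E and
L2/3E and no anti-WTA, which we attribute to the calibration choices
above shifting this admittedly small and sensitive region.

## Problem sizes used by the test suite

Unit tests run seconds-long simulations; the acceptance checks use the
full 10 s / 0.01 ms protocol at the reference heterogeneity point and
shorter 8 s runs for parameter-plane spot checks, with the spiking-network
comparison at scales 0.05–0.2 of the nominal E–I fixture size (up to
~600 neurons, 2 s). These sizes were chosen as the smallest that leave
every measured quantity (spectral peaks at 1 Hz resolution, amplitude
orderings at 2% margins, rate comparisons at 10–15% tolerance) clearly
resolved.
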