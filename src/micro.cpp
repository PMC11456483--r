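// Finite-N spiking QIF network used as a brute-force check of the mean-field
// reduction. Each neuron carries a voltage and sees the two class-aggregated
// synaptic conductances of its own compartment; spikes jump postsynaptic
// conductances by a fixed weight. Connectivity (CSR adjacency) and the
// Lorentzian background currents are drawn in R so that all randomness is
// governed by R's RNG; this routine is deterministic given its inputs.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List micro_qif_cpp(const arma::vec& zeta_n, const arma::vec& eta_n,
                   const arma::vec& kappa_n, const arma::vec& iback_n,
                   const arma::vec& isens_n, const arma::vec& iattn_n,
                   double Cm,
                   const arma::ivec& adj_ptr,   // CSR over source neurons
                   const arma::ivec& adj_idx,   // 0-based target neuron ids
                   const arma::vec& adj_w,      // conductance jump, mS/cm^2
                   const arma::ivec& src_is_exc, // per neuron, 0/1
                   double tau_e, double tau_i,
                   double vsyn_e, double vsyn_i,
                   double dt, double t_total, double t_onset,
                   double v_peak, double v_reset,
                   double v0) {
  const arma::uword N = zeta_n.n_elem;
  const long n_steps = (long) std::llround(t_total / dt);
  const long onset_step = (long) std::llround(t_onset / dt);

  arma::vec V(N, arma::fill::value(v0));
  arma::vec ge(N, arma::fill::zeros), gi(N, arma::fill::zeros);

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  spike_t.reserve(1 << 20);
  spike_id.reserve(1 << 20);

  const double decay_e = 1.0 - dt / tau_e;
  const double decay_i = 1.0 - dt / tau_i;

  for (long step = 0; step < n_steps; ++step) {
    const bool on = step >= onset_step;
    const double t = step * dt;
    for (arma::uword i = 0; i < N; ++i) {
      double I = iback_n(i);
      if (on) I += isens_n(i) + iattn_n(i);
      const double dV = zeta_n(i) * V(i) * V(i) + eta_n(i) * V(i) + kappa_n(i)
        - (ge(i) * (V(i) - vsyn_e) + gi(i) * (V(i) - vsyn_i)) / Cm
        + I / Cm;
      V(i) += dt * dV;
    }
    ge *= decay_e;
    gi *= decay_i;
    for (arma::uword i = 0; i < N; ++i) {
      if (V(i) >= v_peak) {
        V(i) = v_reset;
        spike_t.push_back(t);
        spike_id.push_back((int) i + 1);
        const bool exc = src_is_exc(i) != 0;
        for (int k = adj_ptr(i); k < adj_ptr(i + 1); ++k) {
          if (exc) ge(adj_idx(k)) += adj_w(k);
          else     gi(adj_idx(k)) += adj_w(k);
        }
      }
    }
    if ((step & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["spike_time"] = wrap(spike_t),
                      _["spike_neuron"] = wrap(spike_id));
}
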