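// Spiking QIF network with shared (population-level) pathway conductances:
// the synaptic state g_YX is one variable per ordered pathway, incremented
// by gbar_YX * P_YX (scaled) for every spike in Y and seen identically by
// every neuron of X. This is the coupling the exact mean-field reduction
// describes; Bernoulli-realized connectivity (micro_qif_cpp) adds quenched
// in-degree disorder on top of it.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List micro_qif_shared_cpp(const arma::vec& zeta_n, const arma::vec& eta_n,
                          const arma::vec& kappa_n, const arma::vec& iback_n,
                          const arma::vec& isens_n, const arma::vec& iattn_n,
                          double Cm,
                          const arma::ivec& pop_of,    // 0-based, per neuron
                          const arma::ivec& path_src,  // 0-based pop index
                          const arma::ivec& path_tgt,
                          const arma::vec& path_w,     // jump per spike
                          const arma::ivec& path_is_exc,
                          double tau_e, double tau_i,
                          double vsyn_e, double vsyn_i,
                          double dt, double t_total, double t_onset,
                          double v_peak, double v_reset, double v0) {
  const arma::uword N = zeta_n.n_elem;
  const arma::uword P = (arma::uword)(pop_of.max() + 1);
  const arma::uword M = path_src.n_elem;
  const long n_steps = (long) std::llround(t_total / dt);
  const long onset_step = (long) std::llround(t_onset / dt);

  arma::vec V(N, arma::fill::value(v0));
  arma::vec ge(P, arma::fill::zeros), gi(P, arma::fill::zeros);

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
      const arma::uword p = (arma::uword) pop_of(i);
      double I = iback_n(i);
      if (on) I += isens_n(i) + iattn_n(i);
      const double dV = zeta_n(i) * V(i) * V(i) + eta_n(i) * V(i) + kappa_n(i)
        - (ge(p) * (V(i) - vsyn_e) + gi(p) * (V(i) - vsyn_i)) / Cm
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
        const int sp = pop_of(i);
        for (arma::uword m = 0; m < M; ++m) {
          if (path_src(m) == sp) {
            if (path_is_exc(m)) ge(path_tgt(m)) += path_w(m);
            else                gi(path_tgt(m)) += path_w(m);
          }
        }
      }
    }
    if ((step & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["spike_time"] = wrap(spike_t),
                      _["spike_neuron"] = wrap(spike_id));
}
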