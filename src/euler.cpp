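// Fixed-step forward-Euler integrator of the Lorentzian-ansatz mean-field
// equations. State per population X: firing rate r_X (ms^-1), mean voltage
// v_X (mV), and the two class-aggregated synaptic conductances g_exc, g_inh
// (mS/cm^2). The drive term of each conductance is the probability- and
// size-weighted sum of presynaptic rates, W[target, source] * r, which is
// equivalent to one conductance per pathway because the decay time depends
// only on the source class and the ODE is linear.
//
// The heterogeneity source term in the rate equation is read as
// (zeta_X / pi) * Delta_back_X, and the rate feedback in the voltage
// equation as -(pi^2 / zeta_X) * r^2: both follow from the reduction of the
// dimensional QIF equation (u = zeta*V + eta/2 maps it to the normal form,
// and the physical rate is the voltage-density flux r = zeta * x / pi).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List euler_meanfield_cpp(const arma::vec& zeta, const arma::vec& eta,
                         const arma::vec& kappa, const arma::vec& iback,
                         const arma::vec& dback, const arma::vec& Cm,
                         const arma::vec& isens, const arma::vec& iattn,
                         const arma::mat& WE, const arma::mat& WI,
                         double tau_e, double tau_i,
                         double vsyn_e, double vsyn_i,
                         double dt, double t_total, double t_onset,
                         int stride,
                         const arma::vec& r0, const arma::vec& v0,
                         const arma::vec& ge0, const arma::vec& gi0,
                         double r_ceiling) {
  const arma::uword P = zeta.n_elem;
  const long n_steps = (long) std::llround(t_total / dt);
  const long onset_step = (long) std::llround(t_onset / dt);
  const arma::uword n_rec = (arma::uword)(n_steps / stride) + 1;

  arma::vec r = r0, v = v0, ge = ge0, gi = gi0;
  arma::mat R(n_rec, P), V(n_rec, P);
  arma::vec times(n_rec);

  const double pi = arma::datum::pi;
  const arma::vec src = (zeta / pi) % dback;      // heterogeneity source
  const arma::vec iback_c = iback / Cm;           // currents enter dv as I/C
  const arma::vec iext_c = (isens + iattn) / Cm;

  bool step_warn = false;
  arma::uword rec = 0;
  for (long step = 0; step <= n_steps; ++step) {
    if (step % stride == 0) {
      if (!r.is_finite() || !v.is_finite() || !ge.is_finite() ||
          !gi.is_finite() || r.max() > r_ceiling) {
        arma::uword bad = 0;
        for (arma::uword p = 0; p < P; ++p) {
          if (!std::isfinite(r(p)) || !std::isfinite(v(p)) ||
              r(p) > r_ceiling) { bad = p; break; }
        }
        return List::create(_["error"] = true,
                            _["bad_population"] = (int) bad + 1,
                            _["bad_time"] = step * dt);
      }
      times(rec) = step * dt;
      R.row(rec) = r.t();
      V.row(rec) = v.t();
      ++rec;
    }
    if (step == n_steps) break;

    const bool on = step >= onset_step;
    const arma::vec sum_g = ge + gi;
    const arma::vec drive_e = WE * r;
    const arma::vec drive_i = WI * r;

    const arma::vec dr = 2.0 * zeta % r % v + eta % r - (r / Cm) % sum_g + src;
    arma::vec dv = zeta % v % v + eta % v + kappa
      - (pi * pi) * (r % r) / zeta
      + (ge * vsyn_e + gi * vsyn_i - v % sum_g) / Cm
      + iback_c;
    if (on) dv += iext_c;
    const arma::vec dge = -ge / tau_e + drive_e;
    const arma::vec dgi = -gi / tau_i + drive_i;

    if (!step_warn && step % stride == 0) {
      for (arma::uword p = 0; p < P; ++p) {
        double rel = std::abs(dr(p)) * dt / (std::abs(r(p)) + 1e-12);
        if (rel > 0.5) { step_warn = true; break; }
      }
    }

    r += dt * dr;
    v += dt * dv;
    ge += dt * dge;
    gi += dt * dgi;
  }

  return List::create(_["error"] = false,
                      _["time"] = times,
                      _["r"] = R, _["v"] = V,
                      _["final_r"] = r, _["final_v"] = v,
                      _["final_ge"] = ge, _["final_gi"] = gi,
                      _["step_warning"] = step_warn);
}
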