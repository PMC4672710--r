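#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Capacitor-leak model of membrane-potential fluctuations.
//
//   C dpsi/dt = I_pump - (G_leak + g_p * N_open(t)) * psi
//
// with surface-area-proportional fluxes: C = c_m * y * A, I_pump = j * A,
// G_leak = g0 * A, pore openings a Poisson process of rate nu * A, each open
// pore adding conductance g_p for a fixed lifetime t_p. Between events psi
// relaxes exponentially toward I/G_tot, so the trajectory and its time
// integrals (mean and second moment) are computed in closed form segment by
// segment — the integration is exact, with no time-step error.

// [[Rcpp::export]]
List cpp_simulate_fluct(double area, double cap, double I_pump, double G_leak,
                        double open_rate, double g_p, double t_p,
                        double t_max, double burn_in, int n_reps) {
  NumericVector mean_psi(n_reps), sigma_rel(n_reps);
  for (int rep = 0; rep < n_reps; ++rep) {
    double t = 0.0;
    double psi = I_pump / G_leak;   // start at the unperturbed steady state
    int n_open = 0;
    std::priority_queue<double, std::vector<double>, std::greater<double> > closings;
    double next_open = (open_rate > 0) ? exp_rand() / open_rate : R_PosInf;
    double S1 = 0.0, S2 = 0.0, Ttot = 0.0;

    while (t < t_max) {
      double t_close = closings.empty() ? R_PosInf : closings.top();
      double t_next = std::min(std::min(next_open, t_close), t_max);
      double G = G_leak + n_open * g_p;
      double k = G / cap;
      double a = I_pump / G;          // asymptote of this segment
      double b = psi - a;

      double t0 = t, t1 = t_next;
      if (t1 > burn_in) {
        double tb = std::max(t0, burn_in);
        double bb = b * exp(-k * (tb - t0));   // deviation at integration start
        double dt = t1 - tb;
        double e1 = -expm1(-k * dt);           // 1 - exp(-k dt)
        double e2 = -expm1(-2.0 * k * dt);
        S1 += a * dt + bb * e1 / k;
        S2 += a * a * dt + 2.0 * a * bb * e1 / k + bb * bb * e2 / (2.0 * k);
        Ttot += dt;
      }
      psi = a + b * exp(-k * (t1 - t0));
      t = t1;
      if (t >= t_max) break;
      if (t_next == next_open) {
        ++n_open;
        closings.push(t + t_p);
        next_open = t + exp_rand() / open_rate;
      } else {
        closings.pop();
        --n_open;
      }
    }
    double m = S1 / Ttot;
    double v = S2 / Ttot - m * m;
    mean_psi[rep] = m;
    sigma_rel[rep] = sqrt(std::max(v, 0.0)) / m;
  }
  return List::create(_["mean_psi"] = mean_psi, _["sigma_rel"] = sigma_rel);
}
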