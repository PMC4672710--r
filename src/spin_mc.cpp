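#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Continuous-time single-flip dynamics of spin-coupled mitochondrial agents.
// Energy E = -J * sum_edges s_i s_j - h * sum_i s_i, states s = +1
// (functional) / -1 (failed). Each agent carries a unit attempt rate; the
// accepted flip rate is Glauber heat-bath 1/(1 + exp(dE/theta)) or
// Metropolis min(1, exp(-dE/theta)), both satisfying detailed balance with
// respect to exp(-E/theta). A trajectory is absorbed when all agents are
// failed; the function returns how many of n_reps trajectories reach that
// state by the horizon T starting from all-functional.

// [[Rcpp::export]]
List cpp_spin_mc(int N, IntegerMatrix edges, double J, double h,
                 double theta, double T, int n_reps, bool metropolis) {
  int m = edges.nrow();
  std::vector<std::vector<int> > adj(N);
  for (int e = 0; e < m; ++e) {
    adj[edges(e, 0)].push_back(edges(e, 1));
    adj[edges(e, 1)].push_back(edges(e, 0));
  }
  auto flip_rate = [&](double dE) {
    return metropolis ? std::min(1.0, exp(-dE / theta))
                      : 1.0 / (1.0 + exp(dE / theta));
  };
  int absorbed = 0;
  std::vector<int> s(N);
  std::vector<double> rate(N);
  for (int rep = 0; rep < n_reps; ++rep) {
    for (int i = 0; i < N; ++i) s[i] = 1;
    int n_up = N;
    double Rtot = 0.0;
    for (int i = 0; i < N; ++i) {
      double f = h;
      for (int j : adj[i]) f += J * s[j];
      rate[i] = flip_rate(2.0 * s[i] * f);
      Rtot += rate[i];
    }
    double t = 0.0;
    bool hit = false;
    while (true) {
      if (Rtot <= 0) break;
      t += exp_rand() / Rtot;
      if (t > T) break;
      double u = unif_rand() * Rtot;
      int i = 0;
      double acc = rate[0];
      while (u > acc && i < N - 1) acc += rate[++i];
      s[i] = -s[i];
      n_up += s[i] > 0 ? 1 : -1;
      if (n_up == 0) { hit = true; break; }
      // refresh rates of i and its neighbours
      double f = h;
      for (int j : adj[i]) f += J * s[j];
      Rtot -= rate[i];
      rate[i] = flip_rate(2.0 * s[i] * f);
      Rtot += rate[i];
      for (int j : adj[i]) {
        double fj = h;
        for (int k : adj[j]) fj += J * s[k];
        Rtot -= rate[j];
        rate[j] = flip_rate(2.0 * s[j] * fj);
        Rtot += rate[j];
      }
    }
    if (hit) ++absorbed;
  }
  return List::create(_["absorbed"] = absorbed, _["n_reps"] = n_reps);
}
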