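#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Event-driven co-simulation of blind-ant walkers on a fluctuating bond
// lattice. Bonds are independent two-state Markov chains (on-probability p,
// relaxation time tau); because a bond's state is only needed when a walker
// attempts to cross it, each bond is propagated lazily to the query time with
// the exact transition probability
//   P(on at t | state s at t0) = p + (s - p) * exp(-(t - t0)/tau),
// which is statistically identical to simulating every bond flip event.
// Walker hop attempts occur at total rate lambda_dif; a uniformly chosen
// neighbour is moved to iff the connecting bond is on (blind-ant rule).
// Queries are globally time-ordered across walkers via a priority queue, so
// walkers sharing the lattice see a consistent bond history.

struct Ev {
  double t;
  int w;
  bool operator<(const Ev& o) const { return t > o.t; }  // min-heap
};

// [[Rcpp::export]]
List cpp_simulate_walkers(int L, int d,
                          LogicalVector exists, LogicalVector state0,
                          double p, double tau, double lambda_dif,
                          int n_walkers, NumericVector record_times,
                          bool random_start) {
  int N = 1;
  for (int k = 0; k < d; ++k) N *= L;
  const int nb = d * N;
  const bool fluct = R_finite(tau) && tau > 0;

  std::vector<signed char> st(nb);
  std::vector<double> tl(nb, 0.0);
  for (int i = 0; i < nb; ++i) st[i] = state0[i] ? 1 : 0;

  const int nt = record_times.size();
  std::vector<double> sum1(nt, 0.0), sum2(nt, 0.0);
  const double t_max = record_times[nt - 1];

  // strides for node indexing (first coordinate fastest)
  int stride[3] = {1, L, L * L};

  std::vector<int> pos(n_walkers * d);      // wrapped coordinates
  std::vector<int> disp(n_walkers * d, 0);  // unwrapped displacement
  std::vector<int> ri(n_walkers, 0);        // next record index per walker

  std::priority_queue<Ev> q;
  for (int w = 0; w < n_walkers; ++w) {
    int node = random_start ? (int)(unif_rand() * N) : 0;
    if (node >= N) node = N - 1;
    int rest = node;
    for (int k = 0; k < d; ++k) { pos[w * d + k] = rest % L; rest /= L; }
    q.push({exp_rand() / lambda_dif, w});
  }

  int done = 0;
  while (done < n_walkers) {
    Ev ev = q.top(); q.pop();
    int w = ev.w;
    // record displacement at all record times passed before this event
    while (ri[w] < nt && record_times[ri[w]] <= ev.t) {
      double r2 = 0.0;
      for (int k = 0; k < d; ++k) {
        double dx = disp[w * d + k];
        r2 += dx * dx;
      }
      sum1[ri[w]] += r2;
      sum2[ri[w]] += r2 * r2;
      ++ri[w];
    }
    if (ev.t > t_max || ri[w] >= nt) { ++done; continue; }

    // attempt one hop
    int k = (int)(unif_rand() * 2 * d);
    if (k >= 2 * d) k = 2 * d - 1;
    int axis = k >> 1;
    int dir = (k & 1) ? 1 : -1;
    // bond id: keyed by the lexicographically smaller endpoint along axis
    int node = 0;
    for (int a = 0; a < d; ++a) node += pos[w * d + a] * stride[a];
    int bond;
    if (dir == 1) {
      bond = axis * N + node;
    } else {
      int c = pos[w * d + axis] - 1;
      if (c < 0) c += L;
      bond = axis * N + node + (c - pos[w * d + axis]) * stride[axis];
    }
    bool on;
    if (!exists[bond]) {
      on = false;  // open boundary: no bond to cross
    } else if (!fluct) {
      on = st[bond] != 0;
    } else {
      double pr = p + ((st[bond] ? 1.0 : 0.0) - p) * exp(-(ev.t - tl[bond]) / tau);
      on = unif_rand() < pr;
      st[bond] = on ? 1 : 0;
      tl[bond] = ev.t;
    }
    if (on) {
      int c = pos[w * d + axis] + dir;
      if (c < 0) c += L;
      if (c >= L) c -= L;
      pos[w * d + axis] = c;
      disp[w * d + axis] += dir;
    }
    q.push({ev.t + exp_rand() / lambda_dif, w});
  }

  NumericVector msd(nt), se(nt);
  for (int i = 0; i < nt; ++i) {
    double m = sum1[i] / n_walkers;
    msd[i] = m;
    if (n_walkers > 1) {
      double v = (sum2[i] - n_walkers * m * m) / (n_walkers - 1.0);
      se[i] = sqrt(std::max(v, 0.0) / n_walkers);
    } else {
      se[i] = NA_REAL;
    }
  }
  return List::create(_["msd"] = msd, _["stderr"] = se);
}
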