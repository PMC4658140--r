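#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// TFCE over a channels x samples statistic map. Connectivity on the
// channel-time lattice: neighbouring channels at the same sample, or the
// same channel at adjacent samples (no diagonal moves). For each threshold
// h = dh, 2dh, ..., hmax (dh = hmax / n_steps), every point in a connected
// supra-threshold (f >= h) component of size k accumulates k^E * h^H * dh.
//
// nbrs: per-channel neighbour lists, 0-based channel indices.
// [[Rcpp::export]]
NumericMatrix tfce_cpp(NumericMatrix f, List nbrs, double E, double H,
                       int n_steps) {
  const int nch = f.nrow(), nt = f.ncol(), n = nch * nt;
  NumericMatrix out(nch, nt);
  double hmax = 0.0;
  for (int i = 0; i < n; ++i) {
    if (f[i] < 0 || !R_finite(f[i]))
      stop("TFCE input must be finite and non-negative");
    if (f[i] > hmax) hmax = f[i];
  }
  if (hmax <= 0.0 || n_steps < 1) return out;
  const double dh = hmax / n_steps;

  // flatten neighbour lists once
  std::vector< std::vector<int> > cnb(nch);
  for (int c = 0; c < nch; ++c) {
    IntegerVector v = nbrs[c];
    cnb[c].assign(v.begin(), v.end());
  }

  std::vector<int> stamp(n, -1);       // last step this node was visited
  std::vector<int> stack, comp;
  stack.reserve(n); comp.reserve(n);

  for (int k = 1; k <= n_steps; ++k) {
    const double h = hmax * ((double)k / n_steps);  // h == hmax exactly at the top step
    const double hterm = std::pow(h, H) * dh;
    for (int i = 0; i < n; ++i) {
      if (f[i] < h || stamp[i] == k) continue;
      // BFS/DFS the component containing i at this threshold
      comp.clear();
      stack.push_back(i);
      stamp[i] = k;
      while (!stack.empty()) {
        int u = stack.back(); stack.pop_back();
        comp.push_back(u);
        int ch = u % nch, t = u / nch;
        if (t > 0) {
          int v = u - nch;
          if (stamp[v] != k && f[v] >= h) { stamp[v] = k; stack.push_back(v); }
        }
        if (t < nt - 1) {
          int v = u + nch;
          if (stamp[v] != k && f[v] >= h) { stamp[v] = k; stack.push_back(v); }
        }
        const std::vector<int>& nb = cnb[ch];
        for (size_t a = 0; a < nb.size(); ++a) {
          int v = nb[a] + t * nch;
          if (stamp[v] != k && f[v] >= h) { stamp[v] = k; stack.push_back(v); }
        }
      }
      const double add = std::pow((double)comp.size(), E) * hterm;
      for (size_t a = 0; a < comp.size(); ++a) out[comp[a]] += add;
    }
  }
  return out;
}

// Map-wide maximum of the TFCE transform (used in the permutation loop,
// where only the maximum feeds the null distribution).
// [[Rcpp::export]]
double tfce_max_cpp(NumericMatrix f, List nbrs, double E, double H,
                    int n_steps) {
  NumericMatrix t = tfce_cpp(f, nbrs, E, H, n_steps);
  double m = 0.0;
  for (int i = 0; i < t.size(); ++i) if (t[i] > m) m = t[i];
  return m;
}
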