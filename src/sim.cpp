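#include <Rcpp.h>
using namespace Rcpp;

// Event-level samplers for the discrete-time contact process. Graphs arrive
// as CSR adjacency (offsets of length V+1 into a flat 0-based neighbor
// array). All randomness flows through R's RNG so set.seed() governs both
// samplers and coupled runs share a stream.

static inline int unif_index(int n) {
  // uniform on {0, ..., n-1}; guards the (measure-zero) u == 1 edge
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// Direct simulation of the update rule: pick a node, pick one of its
// neighbors, infect if the pair is infected -> susceptible; every step,
// wasted or not, advances the clock. Returns steps taken to reach
// `target` infected nodes (target >= 1; the source counts).
// [[Rcpp::export]]
List cpp_run_direct(IntegerVector offsets, IntegerVector nbrs,
                    int source, int target, bool return_state) {
  const int V = offsets.size() - 1;
  std::vector<char> infected(V, 0);
  infected[source] = 1;
  int count = 1;
  double steps = 0.0;
  while (count < target) {
    const int i = unif_index(V);
    const int deg = offsets[i + 1] - offsets[i];
    const int j = nbrs[offsets[i] + unif_index(deg)];
    steps += 1.0;
    if (infected[i] && !infected[j]) {
      infected[j] = 1;
      ++count;
    }
  }
  if (!return_state) return List::create(_["steps"] = steps);
  IntegerVector state(V);
  for (int v = 0; v < V; ++v) state[v] = infected[v];
  return List::create(_["steps"] = steps, _["infected"] = state);
}

// Accelerated sampler, exact in distribution. With infected set I the
// per-step success probability is p = (1/V) * sum over boundary
// susceptibles j of w_j, where w_j = sum_{i in I, i~j} 1/deg(i). The wait
// to the next infection is Geometric(p) (drawn by inverse CDF, so wasted
// steps are counted), and the new infectee is chosen with probability
// proportional to w_j. Boundary weights are updated in O(deg) per event.
// [[Rcpp::export]]
List cpp_run_accel(IntegerVector offsets, IntegerVector nbrs,
                   int source, int target, bool return_state) {
  const int V = offsets.size() - 1;
  std::vector<char> infected(V, 0);
  std::vector<double> w(V, 0.0);
  std::vector<int> boundary;
  std::vector<char> in_boundary(V, 0);
  boundary.reserve(64);

  infected[source] = 1;
  int count = 1;
  double steps = 0.0;

  const double inv_deg_src = 1.0 / (offsets[source + 1] - offsets[source]);
  for (int e = offsets[source]; e < offsets[source + 1]; ++e) {
    const int k = nbrs[e];
    w[k] += inv_deg_src;
    if (!in_boundary[k]) { in_boundary[k] = 1; boundary.push_back(k); }
  }

  while (count < target) {
    // compact the boundary and recompute the total weight exactly
    // (avoids floating-point drift from incremental +/-)
    double W = 0.0;
    size_t keep = 0;
    for (size_t b = 0; b < boundary.size(); ++b) {
      const int j = boundary[b];
      if (infected[j]) { in_boundary[j] = 0; continue; }
      boundary[keep++] = j;
      W += w[j];
    }
    boundary.resize(keep);
    if (keep == 0) stop("no susceptible boundary while below target");

    double p = W / V;
    if (p > 1.0) p = 1.0;

    if (p >= 1.0) {
      steps += 1.0;
      unif_rand(); // keep one draw per wait for stream discipline
    } else {
      const double u = unif_rand();
      double k = std::ceil(std::log(u) / std::log1p(-p));
      if (k < 1.0) k = 1.0;
      steps += k;
    }

    // choose the infectee proportional to its boundary weight
    const double t = unif_rand() * W;
    double acc = 0.0;
    int j = boundary[keep - 1];
    for (size_t b = 0; b < keep; ++b) {
      acc += w[boundary[b]];
      if (acc >= t) { j = boundary[b]; break; }
    }

    infected[j] = 1;
    ++count;
    const double inv_deg_j = 1.0 / (offsets[j + 1] - offsets[j]);
    for (int e = offsets[j]; e < offsets[j + 1]; ++e) {
      const int k = nbrs[e];
      if (infected[k]) continue;
      w[k] += inv_deg_j;
      if (!in_boundary[k]) { in_boundary[k] = 1; boundary.push_back(k); }
    }
  }

  if (!return_state) return List::create(_["steps"] = steps);
  IntegerVector state(V);
  for (int v = 0; v < V; ++v) state[v] = infected[v];
  return List::create(_["steps"] = steps, _["infected"] = state);
}

// Draws of F' = sum_{m=1}^{M} (E(m^eta) - 1/m^eta) / sqrt(H), the centered
// and unit-variance-normalized sum of exponentials with surface-scaled
// rates; H = sum_{m=1}^{M} m^{-2 eta} is its variance before scaling.
// [[Rcpp::export]]
NumericVector cpp_sample_fprime(double eta, int M, int runs) {
  NumericVector out(runs, 0.0);
  std::vector<double> inv_rate(M);
  for (int m = 1; m <= M; ++m) inv_rate[m - 1] = std::pow((double)m, -eta);
  double H = 0.0;
  for (int m = 0; m < M; ++m) H += inv_rate[m] * inv_rate[m];
  const double root_h = std::sqrt(H);
  for (int m = 0; m < M; ++m) {
    const double ir = inv_rate[m];
    for (int r = 0; r < runs; ++r) out[r] += ir * (exp_rand() - 1.0);
  }
  for (int r = 0; r < runs; ++r) out[r] /= root_h;
  return out;
}

// Sum of independent Geometric(p_m) waits on {1,2,...} via inverse CDF,
// one takeover-time draw per run. Vectorized here because chains at
// coupon-collector scale have O(N) stages and runs reach 1e5+.
// [[Rcpp::export]]
NumericVector cpp_sample_geom_chain(NumericVector p, int runs) {
  const int S = p.size();
  NumericVector out(runs);
  std::vector<double> logq(S);
  for (int s = 0; s < S; ++s)
    logq[s] = (p[s] >= 1.0) ? R_NegInf : std::log1p(-p[s]);
  for (int r = 0; r < runs; ++r) {
    double total = 0.0;
    for (int s = 0; s < S; ++s) {
      if (p[s] >= 1.0) { total += 1.0; continue; }
      double k = std::ceil(std::log(unif_rand()) / logq[s]);
      if (k < 1.0) k = 1.0;
      total += k;
    }
    out[r] = total;
  }
  return out;
}
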