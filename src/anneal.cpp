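#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One simulated-annealing chain over read-to-node assignments.
//
// State: integer read counts per node. Objective: Euclidean distance
// between the state's scaled compound vector (metabolite-indexed read mass,
// rescaled to total 100,000) and a fixed scaled target. The distance is
// maintained incrementally through the sufficient statistics
//   A = sum(v^2), B = sum(v * target), S = sum(v)
// (v = raw compound vector), so a move costs O(metabolites touched):
//   D^2 = K^2 A / S^2 - 2 K B / S + sum(target^2), K = 100,000.
// All three are integer-valued or integer-weighted sums updated by +/-1
// steps, so there is no floating-point drift.
//
// Move rules: swap1 moves one read from a node chosen proportionally to its
// count to a uniformly chosen node; swap2 picks a source edge whose two
// endpoints both hold a read and a destination edge, and moves one read
// across each endpoint pair. Metropolis acceptance exp(-dD/T) with
// geometric cooling T_k = T0 * alpha^k. Uses R's RNG.
// [[Rcpp::export]]
List anneal_chain_cpp(IntegerVector counts0, List node_mets, int n_mets,
                      NumericVector target, int iterations,
                      double t0, double alpha, int rule,
                      IntegerMatrix edges, int trace_every) {
  RNGScope scope;
  const int n = counts0.size();
  std::vector<std::vector<int>> mets(n);
  for (int j = 0; j < n; ++j) {
    IntegerVector v = node_mets[j];
    mets[j] = std::vector<int>(v.begin(), v.end()); // 0-based
  }
  std::vector<double> counts(counts0.begin(), counts0.end());
  std::vector<double> v(n_mets, 0.0);
  double total = 0.0;
  for (int j = 0; j < n; ++j) {
    total += counts[j];
    for (int c : mets[j]) v[c] += counts[j];
  }
  const double K = 100000.0;
  double A = 0.0, B = 0.0, Ct = 0.0, S = 0.0;
  for (int c = 0; c < n_mets; ++c) {
    A += v[c] * v[c];
    B += v[c] * target[c];
    Ct += target[c] * target[c];
    S += v[c];
  }
  auto dist = [&](double A_, double B_, double S_) {
    if (S_ <= 0.0) return std::sqrt(Ct);
    double d2 = K * K * A_ / (S_ * S_) - 2.0 * K * B_ / S_ + Ct;
    return std::sqrt(std::max(d2, 0.0));
  };
  // apply moving one read from node f to node t (f == t allowed: no-op)
  auto apply_move = [&](int f, int t, int sign) {
    // sign = +1 apply, -1 undo (move t -> f)
    int from = sign > 0 ? f : t, to = sign > 0 ? t : f;
    counts[from] -= 1.0; counts[to] += 1.0;
    for (int c : mets[from]) { A += -2.0 * v[c] + 1.0; B -= target[c]; v[c] -= 1.0; S -= 1.0; }
    for (int c : mets[to])   { A +=  2.0 * v[c] + 1.0; B += target[c]; v[c] += 1.0; S += 1.0; }
  };

  double D = dist(A, B, S);
  const double D_init = D;
  double bestD = D;
  std::vector<double> best_counts = counts;
  std::vector<double> trace;
  double T = t0;
  const int n_edges = edges.nrow();

  for (int it = 0; it < iterations; ++it) {
    int moves[2][2]; int n_moves = 0;
    if (rule == 1) {
      if (total <= 0.0) break;
      double r = unif_rand() * total;
      int src = 0; double acc = counts[0];
      while (acc <= r && src < n - 1) { ++src; acc += counts[src]; }
      int dst = (int)(unif_rand() * n); if (dst >= n) dst = n - 1;
      moves[0][0] = src; moves[0][1] = dst; n_moves = 1;
    } else {
      if (n_edges == 0) break;
      int se = -1;
      for (int tries = 0; tries < 200; ++tries) {
        int e = (int)(unif_rand() * n_edges); if (e >= n_edges) e = n_edges - 1;
        if (counts[edges(e, 0)] > 0 && counts[edges(e, 1)] > 0) { se = e; break; }
      }
      if (se < 0) { // exhaustive fallback
        for (int e = 0; e < n_edges; ++e)
          if (counts[edges(e, 0)] > 0 && counts[edges(e, 1)] > 0) { se = e; break; }
        if (se < 0) break; // no legal move remains
      }
      int de = (int)(unif_rand() * n_edges); if (de >= n_edges) de = n_edges - 1;
      int sa = edges(se, 0), sb = edges(se, 1);
      if (unif_rand() < 0.5) std::swap(sa, sb);
      int da = edges(de, 0), db = edges(de, 1);
      if (unif_rand() < 0.5) std::swap(da, db);
      moves[0][0] = sa; moves[0][1] = da;
      moves[1][0] = sb; moves[1][1] = db;
      n_moves = 2;
    }

    for (int k = 0; k < n_moves; ++k) apply_move(moves[k][0], moves[k][1], +1);
    double Dnew = dist(A, B, S);
    bool accept = Dnew <= D || unif_rand() < std::exp(-(Dnew - D) / std::max(T, 1e-300));
    if (accept) {
      D = Dnew;
      if (D < bestD - 1e-12) { bestD = D; best_counts = counts; }
    } else {
      for (int k = n_moves - 1; k >= 0; --k) apply_move(moves[k][0], moves[k][1], -1);
    }
    T *= alpha;
    if (trace_every > 0 && (it % trace_every) == 0) trace.push_back(bestD);
  }

  IntegerVector out(n);
  for (int j = 0; j < n; ++j) out[j] = (int)std::lround(best_counts[j]);
  return List::create(_["counts"] = out, _["best_objective"] = bestD,
                      _["final_objective"] = D,
                      _["initial_objective"] = D_init,
                      _["trajectory"] = NumericVector(trace.begin(), trace.end()));
}
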