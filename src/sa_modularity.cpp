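#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Barber modularity machinery. B is the modularity matrix A - K L^T / F;
// Q(partition) = (1/F) * sum_{i,j} B(i,j) [rm_i == cm_j].
// Node indexing: rows 0..nr-1, columns nr..nr+nc-1; module labels 0..n-1.

static double full_q(const NumericMatrix& B,
                     const std::vector<int>& mod,
                     int nr, int nc, double F) {
  double q = 0.0;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      if (mod[i] == mod[nr + j]) q += B(i, j);
  return q / F;
}

// raw (un-normalized) change in sum(B) from moving node u to module `to`
static double delta_move(const NumericMatrix& B,
                         const std::vector<int>& mod,
                         int nr, int nc, int u, int to) {
  int from = mod[u];
  double d = 0.0;
  if (u < nr) {
    for (int j = 0; j < nc; ++j) {
      int m = mod[nr + j];
      if (m == to) d += B(u, j);
      else if (m == from) d -= B(u, j);
    }
  } else {
    int jc = u - nr;
    for (int i = 0; i < nr; ++i) {
      int m = mod[i];
      if (m == to) d += B(i, jc);
      else if (m == from) d -= B(i, jc);
    }
  }
  return d;
}

// small deterministic PRNG for the polishing phase (independent of the
// annealing trajectory so longer budgets polish with the same stream)
static inline double xs_unif(uint32_t& st) {
  st ^= st << 13; st ^= st >> 17; st ^= st << 5;
  return (st >> 8) * (1.0 / 16777216.0);
}

static int count_modules(const std::vector<int>& mod, int n) {
  std::vector<char> seen(n, 0);
  int k = 0;
  for (int u = 0; u < n; ++u) if (!seen[mod[u]]) { seen[mod[u]] = 1; ++k; }
  return k;
}

// Simulated annealing maximization of Barber weighted modularity.
// Moves: single-node reassignment to an occupied or fresh module (95%),
// and whole-module merges (5%). Geometric cooling per sweep; best-seen
// partition returned (ties: fewer modules win). Uses R's RNG, so results
// are reproducible under set.seed().
// [[Rcpp::export(name = ".sa_optimize")]]
List sa_optimize(NumericMatrix B, double F, IntegerVector init,
                 double t0, double cooling, int moves_per_node,
                 int max_sweeps, int patience, int refine_seed) {
  const int nr = B.nrow(), nc = B.ncol(), n = nr + nc;
  std::vector<int> mod(init.begin(), init.end());
  std::vector<int> cnt(n, 0);
  for (int u = 0; u < n; ++u) cnt[mod[u]]++;

  double curQ = full_q(B, mod, nr, nc, F);
  std::vector<int> best(mod);
  double bestQ = curQ;
  int bestM = count_modules(mod, n);

  const double eps = 1e-12;
  double T = t0;
  int since_improve = 0;
  long moves_per_sweep = (long)moves_per_node * n;

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    bool improved = false;
    for (long m = 0; m < moves_per_sweep; ++m) {
      double r = unif_rand();
      if (r < 0.05) {
        // merge the modules of two random nodes
        int u = (int)(unif_rand() * n); if (u >= n) u = n - 1;
        int v = (int)(unif_rand() * n); if (v >= n) v = n - 1;
        int a = mod[u], b = mod[v];
        if (a == b) continue;
        double raw = 0.0;
        for (int i = 0; i < nr; ++i) {
          int mi = mod[i];
          if (mi != a && mi != b) continue;
          for (int j = 0; j < nc; ++j) {
            int mj = mod[nr + j];
            if ((mi == a && mj == b) || (mi == b && mj == a)) raw += B(i, j);
          }
        }
        double dq = raw / F;
        if (dq >= 0 || unif_rand() < std::exp(dq / T)) {
          for (int w = 0; w < n; ++w) if (mod[w] == a) { mod[w] = b; }
          cnt[b] += cnt[a]; cnt[a] = 0;
          curQ += dq;
        }
      } else {
        int u = (int)(unif_rand() * n); if (u >= n) u = n - 1;
        int from = mod[u];
        int to;
        if (unif_rand() < 0.10) {
          // fresh (currently empty) module label
          if (cnt[from] == 1) continue;  // already isolated
          to = -1;
          for (int l = 0; l < n; ++l) if (cnt[l] == 0) { to = l; break; }
          if (to < 0) continue;
        } else {
          int v = (int)(unif_rand() * n); if (v >= n) v = n - 1;
          to = mod[v];
        }
        if (to == from) continue;
        double dq = delta_move(B, mod, nr, nc, u, to) / F;
        if (dq >= 0 || unif_rand() < std::exp(dq / T)) {
          cnt[from]--; cnt[to]++;
          mod[u] = to;
          curQ += dq;
        }
      }
      if (curQ > bestQ + eps) {
        bestQ = curQ; best = mod; bestM = count_modules(mod, n);
        improved = true;
      } else if (curQ > bestQ - eps) {
        int mm = count_modules(mod, n);
        if (mm < bestM) { best = mod; bestM = mm; }
      }
    }
    T *= cooling;
    if (improved) since_improve = 0; else ++since_improve;
    if (since_improve >= patience) break;
    if (sweep % 50 == 0) Rcpp::checkUserInterrupt();
  }

  double annealQ_exact = full_q(B, best, nr, nc, F);

  // Greedy polishing from the best-seen state: alternate (a) node-level
  // sweeps moving each node to its locally optimal module (including a
  // fresh one) until convergence, and (b) the best positive whole-module
  // merge. Stops when neither improves, i.e. at a partition locally
  // optimal w.r.t. single-node moves and pairwise merges.
  mod = best;
  std::fill(cnt.begin(), cnt.end(), 0);
  for (int u = 0; u < n; ++u) cnt[mod[u]]++;
  const double reps = 1e-12;
  uint32_t rst = (uint32_t)refine_seed | 1u;
  for (int outer = 0; outer < n; ++outer) {
    // (a) node refinement to convergence
    for (int pass = 0; pass < 200; ++pass) {
      bool moved = false;
      for (int u = 0; u < n; ++u) {
        int from = mod[u];
        std::vector<double> w(n, 0.0);
        if (u < nr) {
          for (int j = 0; j < nc; ++j) w[mod[nr + j]] += B(u, j);
        } else {
          int jc = u - nr;
          for (int i = 0; i < nr; ++i) w[mod[i]] += B(i, jc);
        }
        int bestTo = from;
        double bestGain = 0.0;
        bool fresh_tried = false;
        for (int l = 0; l < n; ++l) {
          if (l == from) continue;
          double gain;
          if (cnt[l] == 0) {
            if (fresh_tried) continue;
            fresh_tried = true;
            gain = -w[from];       // isolate u in an empty module
          } else {
            gain = w[l] - w[from];
          }
          if (gain > bestGain + reps) { bestGain = gain; bestTo = l; }
        }
        if (bestTo != from) {
          cnt[from]--; cnt[bestTo]++;
          mod[u] = bestTo;
          moved = true;
        }
      }
      if (!moved) break;
    }
    // (b) best pairwise module merge
    std::vector<std::vector<double>> R(n, std::vector<double>(n, 0.0));
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < nc; ++j)
        R[mod[i]][mod[nr + j]] += B(i, j);
    double bestGain = reps;
    int ma = -1, mb = -1;
    for (int a = 0; a < n; ++a) {
      if (cnt[a] == 0) continue;
      for (int b = a + 1; b < n; ++b) {
        if (cnt[b] == 0) continue;
        double gain = R[a][b] + R[b][a];
        if (gain > bestGain) { bestGain = gain; ma = a; mb = b; }
      }
    }
    bool merged = false;
    if (ma >= 0) {
      for (int u = 0; u < n; ++u) if (mod[u] == ma) mod[u] = mb;
      cnt[mb] += cnt[ma]; cnt[ma] = 0;
      merged = true;
    }
    // (c) randomized bisection attempts: for each module, try a random
    // 2-split refined by within-pair node sweeps; keep if Q gains.
    // Only pairs internal to the module affect Q, so the gain is local.
    bool split_any = false;
    for (int a = 0; a < n; ++a) {
      if (cnt[a] < 4) continue;
      int b = -1;
      for (int l = 0; l < n; ++l) if (cnt[l] == 0) { b = l; break; }
      if (b < 0) continue;
      std::vector<int> mem_rows, mem_cols;
      for (int i = 0; i < nr; ++i) if (mod[i] == a) mem_rows.push_back(i);
      for (int j = 0; j < nc; ++j) if (mod[nr + j] == a) mem_cols.push_back(nr + j);
      if (mem_rows.empty() || mem_cols.empty()) continue;
      double before = 0.0;
      for (int i : mem_rows) for (int u : mem_cols) before += B(i, u - nr);
      for (int attempt = 0; attempt < 2; ++attempt) {
        std::vector<int> lab(n, -1);   // only members used
        for (int u : mem_rows) lab[u] = (xs_unif(rst) < 0.5) ? 0 : 1;
        for (int u : mem_cols) lab[u] = (xs_unif(rst) < 0.5) ? 0 : 1;
        for (int pass = 0; pass < 50; ++pass) {
          bool moved = false;
          for (int u : mem_rows) {
            double w0 = 0, w1 = 0;
            for (int v : mem_cols) {
              if (lab[v] == 0) w0 += B(u, v - nr); else w1 += B(u, v - nr);
            }
            int want = (w0 >= w1) ? 0 : 1;
            if (lab[u] != want) { lab[u] = want; moved = true; }
          }
          for (int v : mem_cols) {
            double w0 = 0, w1 = 0;
            for (int u : mem_rows) {
              if (lab[u] == 0) w0 += B(u, v - nr); else w1 += B(u, v - nr);
            }
            int want = (w0 >= w1) ? 0 : 1;
            if (lab[v] != want) { lab[v] = want; moved = true; }
          }
          if (!moved) break;
        }
        double after = 0.0;
        for (int i : mem_rows)
          for (int u : mem_cols)
            if (lab[i] == lab[u]) after += B(i, u - nr);
        if (after > before + reps) {
          int moved_cnt = 0;
          for (int u = 0; u < n; ++u)
            if (lab[u] == 1) { mod[u] = b; ++moved_cnt; }
          if (moved_cnt > 0 && moved_cnt < cnt[a]) {
            cnt[a] -= moved_cnt; cnt[b] += moved_cnt;
            split_any = true;
          } else if (moved_cnt > 0) {  // degenerate: everything moved
            for (int u = 0; u < n; ++u) if (mod[u] == b) mod[u] = a;
          }
          break;
        }
      }
    }
    if (!merged && !split_any) break;
  }
  double refinedQ = full_q(B, mod, nr, nc, F);
  if (refinedQ > bestQ + eps) { best = mod; }

  double bestQ_exact = full_q(B, best, nr, nc, F);
  return List::create(_["assignment"] = IntegerVector(best.begin(), best.end()),
                      _["Q"] = bestQ_exact,
                      _["Q_anneal"] = annealQ_exact,
                      _["n_modules"] = count_modules(best, n));
}
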