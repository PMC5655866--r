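#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Exact minimization of x'Qx - f'x over x in {0,1}^m by depth-first
// branch and bound.
//
// Variables are branched in order of decreasing |f| (ties by original
// index), so the free set at any node is a suffix of the ordering.  With
// S1 the variables fixed to one and F the free suffix, the objective
// decomposes as
//   value(S1) + sum_{j in F, x_j=1} lin_j + sum_{i<j in F, x_i=x_j=1} 2 Q_ij
// where lin_j = Q_jj - f_j + 2 sum_{i in S1} Q_ij.  Dropping positive
// terms gives the lower bound
//   value(S1) + sum_{j in F} min(0, lin_j) + sum_{i<j in F} min(0, 2 Q_ij);
// the pairwise part is precomputed per suffix.  For instances built from a
// mutation matrix, Q is a nonnegative Gram matrix and the pairwise part
// vanishes, but the bound stays valid for arbitrary symmetric Q.
//
// Nodes are pruned only when bound > best + tol, so all optima within the
// tolerance stay reachable; ties are resolved toward fewer selected
// variables, then the lexicographically smallest indicator in the
// *original* variable order, giving deterministic output.

namespace {

struct BBState {
  int m;
  std::vector<double> Qo;       // reordered Q, column-major m*m
  std::vector<double> lin;      // current linear gain of each free var
  std::vector<double> sufneg;   // suffix pairwise negative bound
  std::vector<int> ord;         // position -> original index
  std::vector<int> assign;      // assignment in ordered space
  std::vector<int> best;        // best indicator, original order
  double best_val;
  int best_card;
  double tol;
  // scratch for leaf comparison
  std::vector<int> cand;
};

inline double qo(const BBState& s, int i, int j) {
  return s.Qo[static_cast<size_t>(j) * s.m + i];
}

// true if candidate (val, indicator in ordered 'assign') beats the best
void consider_leaf(BBState& s, double val) {
  if (s.best_card >= 0 && val > s.best_val + s.tol) return;
  // indicator in original order
  std::fill(s.cand.begin(), s.cand.end(), 0);
  int card = 0;
  for (int d = 0; d < s.m; ++d) {
    if (s.assign[d]) {
      s.cand[s.ord[d]] = 1;
      ++card;
    }
  }
  bool take = false;
  if (s.best_card < 0 || val < s.best_val - s.tol) {
    take = true;
  } else if (val <= s.best_val + s.tol) {
    if (card < s.best_card) {
      take = true;
    } else if (card == s.best_card) {
      for (int j = 0; j < s.m; ++j) {
        if (s.cand[j] != s.best[j]) {
          take = (s.cand[j] < s.best[j]);
          break;
        }
      }
    }
  }
  if (take) {
    s.best = s.cand;
    s.best_val = val;      // objective of the returned indicator, exactly
    s.best_card = card;
  }
}

void dfs(BBState& s, int d, double val) {
  if (d == s.m) {
    consider_leaf(s, val);
    return;
  }
  // lower bound over the free suffix
  if (s.best_card >= 0) {
    double bound = val + s.sufneg[d];
    for (int j = d; j < s.m; ++j) {
      if (s.lin[j] < 0) bound += s.lin[j];
    }
    if (bound > s.best_val + s.tol) return;
  }
  int first = (s.lin[d] < 0) ? 1 : 0;   // greedy branch first
  for (int pass = 0; pass < 2; ++pass) {
    int b = (pass == 0) ? first : 1 - first;
    s.assign[d] = b;
    if (b == 1) {
      double v1 = val + s.lin[d];
      for (int j = d + 1; j < s.m; ++j) s.lin[j] += 2.0 * qo(s, d, j);
      dfs(s, d + 1, v1);
      for (int j = d + 1; j < s.m; ++j) s.lin[j] -= 2.0 * qo(s, d, j);
    } else {
      dfs(s, d + 1, val);
    }
  }
  s.assign[d] = 0;
}

} // namespace

// [[Rcpp::export]]
List bqp_solve_bb(NumericMatrix Q, NumericVector f, double offset,
                  double tol) {
  int m = f.size();
  if (Q.nrow() != m || Q.ncol() != m)
    stop("Q dimensions must match f");
  if (m == 0) {
    return List::create(_["indicator"] = IntegerVector(0),
                        _["objective"] = offset,
                        _["optimal"] = true);
  }

  BBState s;
  s.m = m;
  s.tol = tol;
  s.ord.resize(m);
  for (int j = 0; j < m; ++j) s.ord[j] = j;
  std::stable_sort(s.ord.begin(), s.ord.end(), [&](int a, int b) {
    double fa = std::fabs(f[a]), fb = std::fabs(f[b]);
    if (fa != fb) return fa > fb;
    return a < b;
  });

  s.Qo.assign(static_cast<size_t>(m) * m, 0.0);
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < m; ++i)
      s.Qo[static_cast<size_t>(j) * m + i] = Q(s.ord[i], s.ord[j]);

  s.lin.resize(m);
  for (int d = 0; d < m; ++d)
    s.lin[d] = qo(s, d, d) - f[s.ord[d]];

  s.sufneg.assign(m + 1, 0.0);
  for (int d = m - 1; d >= 0; --d) {
    double add = 0.0;
    for (int j = d + 1; j < m; ++j) {
      double q2 = 2.0 * qo(s, d, j);
      if (q2 < 0) add += q2;
    }
    s.sufneg[d] = s.sufneg[d + 1] + add;
  }

  s.assign.assign(m, 0);
  s.best.assign(m, 0);
  s.cand.assign(m, 0);
  s.best_card = -1;
  s.best_val = R_PosInf;

  dfs(s, 0, 0.0);

  IntegerVector ind(m);
  for (int j = 0; j < m; ++j) ind[j] = s.best[j];
  return List::create(_["indicator"] = ind,
                      _["objective"] = s.best_val + offset,
                      _["optimal"] = true);
}
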