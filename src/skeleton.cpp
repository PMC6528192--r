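// PC-stable skeleton search over a Gaussian conditional-independence oracle
// (partial correlations from a fixed correlation matrix, Fisher z test).
// The combinatorial loop lives here because it dominates the runtime of
// network learning and of the subsample-stability tuning.

#include <RcppArmadillo.h>
#include <algorithm>
#include <set>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// partial correlation of (i, j) given S via inversion of the submatrix of C
static bool pcor_ij(const arma::mat& C, const unsigned i, const unsigned j,
                    const std::vector<int>& S, double& out) {
  const unsigned k = S.size();
  if (k == 0) {
    out = C(i, j);
    return true;
  }
  arma::uvec idx(k + 2);
  idx(0) = i;
  idx(1) = j;
  for (unsigned t = 0; t < k; ++t) idx(t + 2) = (unsigned)S[t];
  const arma::mat M = C.submat(idx, idx);
  arma::mat P;
  if (!arma::inv_sympd(P, M) && !arma::inv(P, M)) return false;
  const double d = P(0, 0) * P(1, 1);
  if (d <= 0.0) return false;
  out = -P(0, 1) / std::sqrt(d);
  return true;
}

// Majority-rule classification of an unshielded triple x - j - y:
// enumerate all subsets (up to size `cap`) of adj(x)\{y} and adj(y)\{x},
// count the subsets that separate x and y at level alpha and, of those,
// how many contain j. Returns (n_separating, n_containing_j).
// [[Rcpp::export(name = ".classify_triple")]]
IntegerVector classify_triple(const arma::mat& C, const int n,
                              const double alpha, const LogicalMatrix& G,
                              const int x, const int j, const int y,
                              const int cap) {
  const int p = C.n_rows;
  const double crit = R::qnorm(1.0 - alpha / 2.0, 0.0, 1.0, 1, 0);
  std::set<std::vector<int> > seen;
  int n_sep = 0, n_with_j = 0;
  for (int side = 0; side < 2; ++side) {
    const int a = (side == 0) ? x : y;
    const int b = (side == 0) ? y : x;
    std::vector<int> cand;
    for (int v = 0; v < p; ++v)
      if (v != b && G(a, v)) cand.push_back(v);
    const int m = (int)cand.size();
    const int kmax = std::min(cap, m);
    for (int k = 0; k <= kmax; ++k) {
      if (n - k - 3 <= 0) break;
      const double zscale = std::sqrt((double)(n - k - 3));
      std::vector<int> comb(k);
      for (int t = 0; t < k; ++t) comb[t] = t;
      while (true) {
        std::vector<int> S(k);
        for (int t = 0; t < k; ++t) S[t] = cand[comb[t]];
        std::vector<int> key(S);
        std::sort(key.begin(), key.end());
        if (seen.insert(key).second) {
          double r;
          if (pcor_ij(C, x, y, S, r)) {
            if (r > 1.0 - 1e-12) r = 1.0 - 1e-12;
            if (r < -1.0 + 1e-12) r = -1.0 + 1e-12;
            if (std::fabs(zscale * std::atanh(r)) <= crit) {
              ++n_sep;
              if (std::find(S.begin(), S.end(), j) != S.end()) ++n_with_j;
            }
          }
        }
        if (k == 0) break;
        int t = k - 1;
        while (t >= 0 && comb[t] == m - k + t) --t;
        if (t < 0) break;
        ++comb[t];
        for (int u = t + 1; u < k; ++u) comb[u] = comb[u - 1] + 1;
      }
    }
  }
  return IntegerVector::create(n_sep, n_with_j);
}

// types: 0 = instrument, 1 = metabolite. For a metabolite-metabolite pair
// the conditioning candidates are restricted to adjacent metabolites
// (instruments are exogenous sources; any separable metabolite pair is
// separable within the metabolite layer, and conditioning on instrument
// combinations invites spurious separations).
// [[Rcpp::export(name = ".skeleton_pc_stable")]]
List skeleton_pc_stable(const arma::mat& C, const int n, const double alpha,
                        const LogicalMatrix& G0, const IntegerVector& types,
                        const int m_max) {
  const int p = C.n_rows;
  std::vector<std::vector<bool> > G(p, std::vector<bool>(p, false));
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (G0(i, j)) G[i][j] = true;

  const double crit = R::qnorm(1.0 - alpha / 2.0, 0.0, 1.0, 1, 0);
  std::vector<int> sep_i, sep_j;
  std::vector<std::vector<int> > sep_S;

  int ord = 0;
  bool more = true;
  int max_ord_used = -1;
  while (more && ord <= m_max) {
    if (n - ord - 3 <= 0) break;
    const double zscale = std::sqrt((double)(n - ord - 3));
    // adjacency fixed at the start of the level (order-independent variant)
    std::vector<std::vector<int> > adj(p);
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j)
        if (G[i][j]) adj[i].push_back(j);
    more = false;
    for (int i = 0; i < p - 1; ++i) {
      for (int j = i + 1; j < p; ++j) {
        if (!G[i][j]) continue;
        bool removed = false;
        for (int side = 0; side < 2 && !removed; ++side) {
          if (side == 1 && ord == 0) break;  // empty set already tested
          const int a = (side == 0) ? i : j;
          const int b = (side == 0) ? j : i;
          const bool met_pair = (types[i] == 1 && types[j] == 1);
          std::vector<int> cand;
          cand.reserve(adj[a].size());
          for (size_t t = 0; t < adj[a].size(); ++t) {
            const int v = adj[a][t];
            if (v == b) continue;
            if (met_pair && types[v] != 1) continue;
            cand.push_back(v);
          }
          const int m = (int)cand.size();
          if (m < ord) continue;
          if (m > ord) more = true;
          if (ord == 0) {
            double r = C(i, j);
            if (r > 1.0 - 1e-12) r = 1.0 - 1e-12;
            if (r < -1.0 + 1e-12) r = -1.0 + 1e-12;
            const double z = zscale * std::atanh(r);
            if (std::fabs(z) <= crit) {
              G[i][j] = G[j][i] = false;
              sep_i.push_back(i + 1);
              sep_j.push_back(j + 1);
              sep_S.push_back(std::vector<int>());
              removed = true;
            }
            continue;
          }
          // iterate size-ord combinations of cand
          std::vector<int> comb(ord);
          for (int t = 0; t < ord; ++t) comb[t] = t;
          while (true) {
            std::vector<int> S(ord);
            for (int t = 0; t < ord; ++t) S[t] = cand[comb[t]];
            double r;
            if (pcor_ij(C, i, j, S, r)) {
              if (r > 1.0 - 1e-12) r = 1.0 - 1e-12;
              if (r < -1.0 + 1e-12) r = -1.0 + 1e-12;
              const double z = zscale * std::atanh(r);
              if (std::fabs(z) <= crit) {
                G[i][j] = G[j][i] = false;
                sep_i.push_back(i + 1);
                sep_j.push_back(j + 1);
                std::vector<int> S1(ord);
                for (int t = 0; t < ord; ++t) S1[t] = S[t] + 1;
                sep_S.push_back(S1);
                removed = true;
                break;
              }
            }
            // next combination
            int t = ord - 1;
            while (t >= 0 && comb[t] == m - ord + t) --t;
            if (t < 0) break;
            ++comb[t];
            for (int u = t + 1; u < ord; ++u) comb[u] = comb[u - 1] + 1;
          }
        }
        if (removed && ord > max_ord_used) max_ord_used = ord;
      }
    }
    ++ord;
  }

  LogicalMatrix Gout(p, p);
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j) Gout(i, j) = G[i][j];

  List seps(sep_S.size());
  for (size_t t = 0; t < sep_S.size(); ++t) {
    seps[t] = IntegerVector(sep_S[t].begin(), sep_S[t].end());
  }
  return List::create(
    _["adj"] = Gout,
    _["sep_i"] = IntegerVector(sep_i.begin(), sep_i.end()),
    _["sep_j"] = IntegerVector(sep_j.begin(), sep_j.end()),
    _["sep_S"] = seps,
    _["max_order"] = ord - 1);
}
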