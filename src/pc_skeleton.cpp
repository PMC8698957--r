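// Order-independent (stable) PC skeleton search with Fisher-z partial
// correlation tests. Only the undirected skeleton is produced: edges are
// deleted when some conditioning set drawn from either endpoint's
// neighbourhood (as snapshotted at the start of the level) renders the pair
// conditionally independent at level alpha.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// partial correlation rho(i,j | S) via inversion of the (i,j,S) submatrix of
// the correlation matrix; ok is set false on a singular submatrix
static double partial_cor_inv(const arma::mat& C, int i, int j,
                              const std::vector<int>& S, bool& ok) {
  const int m = 2 + (int)S.size();
  arma::uvec idx(m);
  idx[0] = i;
  idx[1] = j;
  for (size_t k = 0; k < S.size(); ++k) idx[2 + k] = S[k];
  arma::mat P;
  ok = arma::inv(P, C.submat(idx, idx));
  if (!ok) return 0.0;
  double denom = std::sqrt(P(0, 0) * P(1, 1));
  if (!std::isfinite(denom) || denom <= 0.0) {
    ok = false;
    return 0.0;
  }
  return -P(0, 1) / denom;
}

// Fisher z statistic; returns true when the pair is judged independent
static bool fisher_z_independent(double rho, int n, int cond_size, double crit) {
  const double cap = 1.0 - 1e-12;
  if (rho > cap) rho = cap;
  if (rho < -cap) rho = -cap;
  double z = std::sqrt((double)(n - cond_size - 3)) * 0.5 *
             std::log((1.0 + rho) / (1.0 - rho));
  return std::fabs(z) <= crit;
}

// [[Rcpp::export(name = ".pc_skeleton_cpp")]]
List pc_skeleton_cpp(const arma::mat& C, int n_samples, double alpha,
                     int max_order) {
  const int p = C.n_rows;
  arma::umat adj(p, p, arma::fill::ones);
  adj.diag().zeros();
  const double crit = R::qnorm(1.0 - alpha / 2.0, 0.0, 1.0, 1, 0);

  std::vector<int> sep_i, sep_j;
  List sep_sets;

  int l = 0;
  int reached = -1;
  while (true) {
    if (max_order >= 0 && l > max_order) break;
    // Fisher-z requires n - |S| - 3 > 0; larger orders are untestable and
    // edges are conservatively retained
    if (n_samples - l - 3 <= 0) break;
    // structural stop: some adjacent pair must offer a neighbourhood of size l
    bool feasible = false;
    for (int i = 0; i < p && !feasible; ++i) {
      int deg = (int)arma::accu(adj.row(i));
      if (deg - 1 >= l) {
        for (int j = 0; j < p; ++j) {
          if (adj(i, j)) { feasible = true; break; }
        }
      }
    }
    if (!feasible && l > 0) break;
    if (l == 0) feasible = true;
    reached = l;

    const arma::umat snap = adj; // PC-stable: neighbourhoods frozen per level
    for (int i = 0; i < p - 1; ++i) {
      for (int j = i + 1; j < p; ++j) {
        if (!adj(i, j)) continue;
        bool removed = false;
        // candidate conditioning pools: adj(i)\{j}, then adj(j)\{i}
        for (int side = 0; side < 2 && !removed; ++side) {
          const int a = side == 0 ? i : j;
          const int b = side == 0 ? j : i;
          std::vector<int> pool;
          for (int k = 0; k < p; ++k) {
            if (k != b && snap(a, k)) pool.push_back(k);
          }
          if ((int)pool.size() < l) continue;
          if (l == 0 && side == 1) continue; // empty set already tested
          // lexicographic enumeration of l-subsets of pool
          std::vector<int> comb(l);
          for (int k = 0; k < l; ++k) comb[k] = k;
          while (true) {
            std::vector<int> S(l);
            for (int k = 0; k < l; ++k) S[k] = pool[comb[k]];
            bool ok = true;
            double rho = partial_cor_inv(C, i, j, S, ok);
            if (ok && fisher_z_independent(rho, n_samples, l, crit)) {
              adj(i, j) = 0;
              adj(j, i) = 0;
              sep_i.push_back(i + 1);
              sep_j.push_back(j + 1);
              IntegerVector sv(l);
              for (int k = 0; k < l; ++k) sv[k] = S[k] + 1;
              sep_sets.push_back(sv);
              removed = true;
              break;
            }
            // next combination
            int pos = l - 1;
            while (pos >= 0 && comb[pos] == (int)pool.size() - l + pos) --pos;
            if (pos < 0) break;
            ++comb[pos];
            for (int k = pos + 1; k < l; ++k) comb[k] = comb[k - 1] + 1;
            if (l == 0) break;
          }
          if (l == 0) break;
        }
      }
    }
    ++l;
  }

  LogicalMatrix out(p, p);
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j) out(i, j) = adj(i, j) ? true : false;
  return List::create(_["adjacency"] = out,
                      _["sep_i"] = wrap(sep_i),
                      _["sep_j"] = wrap(sep_j),
                      _["sep_sets"] = sep_sets,
                      _["max_level"] = reached);
}
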