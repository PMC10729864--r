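#include <Rcpp.h>
using namespace Rcpp;

// Curveball trade sampling of 0/1 matrices with fixed row and column sums.
//
// The matrix is held as per-row lists of occupied column indices. One trade
// picks two distinct rows, keeps the columns they share, pools the columns
// unique to either row, shuffles the pool and deals it back in the original
// per-row amounts. Every trade preserves all row and column sums; the chain's
// stationary distribution is uniform over matrices with those margins.
//
// Randomness comes from R's RNG stream (unif_rand), so results are
// reproducible under set.seed().

static inline int unif_index(int n) {
  // draw from {0, ..., n-1}; guards the unif_rand() == 1.0 edge
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// [[Rcpp::export]]
IntegerMatrix curveball_trades(const IntegerMatrix& mat, const int n_trades) {
  const int nr = mat.nrow(), nc = mat.ncol();
  IntegerMatrix out(nr, nc);
  if (nr < 2 || nc < 1) {
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < nc; ++j) out(i, j) = mat(i, j);
    return out;
  }

  std::vector< std::vector<int> > rows(nr);
  for (int i = 0; i < nr; ++i) {
    rows[i].reserve(nc);
    for (int j = 0; j < nc; ++j)
      if (mat(i, j) != 0) rows[i].push_back(j);
  }

  std::vector<char> in_b(nc, 0);
  std::vector<int> shared, pool;
  shared.reserve(nc); pool.reserve(2 * nc);

  for (int t = 0; t < n_trades; ++t) {
    int a = unif_index(nr);
    int b = unif_index(nr - 1);
    if (b >= a) ++b;
    std::vector<int>& ra = rows[a];
    std::vector<int>& rb = rows[b];
    if (ra.empty() && rb.empty()) continue;

    for (size_t k = 0; k < rb.size(); ++k) in_b[rb[k]] = 1;
    shared.clear(); pool.clear();
    for (size_t k = 0; k < ra.size(); ++k) {
      const int j = ra[k];
      if (in_b[j]) { shared.push_back(j); in_b[j] = 0; }
      else pool.push_back(j);
    }
    const int ka = (int)pool.size();          // columns unique to row a
    for (size_t k = 0; k < rb.size(); ++k) {
      const int j = rb[k];
      if (in_b[j]) { pool.push_back(j); in_b[j] = 0; }
    }
    if (ka == 0 || ka == (int)pool.size()) continue;  // nothing tradable

    // Fisher-Yates shuffle of the pooled unique columns
    for (int k = (int)pool.size() - 1; k > 0; --k) {
      int m = unif_index(k + 1);
      std::swap(pool[k], pool[m]);
    }

    ra.assign(shared.begin(), shared.end());
    ra.insert(ra.end(), pool.begin(), pool.begin() + ka);
    rb.assign(shared.begin(), shared.end());
    rb.insert(rb.end(), pool.begin() + ka, pool.end());
  }

  for (int i = 0; i < nr; ++i)
    for (size_t k = 0; k < rows[i].size(); ++k)
      out(i, rows[i][k]) = 1;
  return out;
}
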