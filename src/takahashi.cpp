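#include <Rcpp.h>
using namespace Rcpp;

// Takahashi selected inverse.
//
// Given the sparse Cholesky factor L (A = L L', lower triangular, CSC with
// sorted row indices and an explicit diagonal as the first entry of every
// column), returns the entries of A^{-1} on the pattern of L.
//
// Recursion (columns processed last to first):
//   S[i,j] = (delta_ij / L[j,j] - sum_{k > j in col j} L[k,j] S[i,k]) / L[j,j]
// Every S entry the sum touches lies inside the factor pattern (elimination
// tree closure). For each column j the contributions of all pairs
// {i, k} in struct(col j) are gathered by scanning the stored columns k
// once (entry (m,k) with m,k in struct serves both S[m,j] and S[k,j]),
// which keeps the total cost at the order of the factorization flops.
// [[Rcpp::export]]
NumericVector takahashi_inverse(IntegerVector Lp, IntegerVector Li,
                                NumericVector Lx) {
  const int n = Lp.size() - 1;
  NumericVector Sx(Lx.size());
  const int *p = INTEGER(Lp);
  const int *ri = INTEGER(Li);
  const double *lx = REAL(Lx);
  double *sx = REAL(Sx);

  std::vector<int> posInCol(n, -1);   // row -> index in current column j
  std::vector<double> acc(n, 0.0);

  for (int j = n - 1; j >= 0; --j) {
    const int pj = p[j], pj1 = p[j + 1];
    if (pj >= pj1 || ri[pj] != j)
      stop("factor must store an explicit diagonal first in each column");
    const double ljj = lx[pj];
    for (int idx = pj + 1; idx < pj1; ++idx) posInCol[ri[idx]] = idx;
    // acc[i] = sum_{k in struct(col j), k > j} L[k,j] * S(max(i,k), min(i,k))
    for (int kk = pj + 1; kk < pj1; ++kk) {
      const int k = ri[kk];
      const double lkj = lx[kk];
      for (int tt = p[k]; tt < p[k + 1]; ++tt) {
        const int m = ri[tt];
        if (posInCol[m] >= 0) {
          const double s = sx[tt];
          acc[m] += lkj * s;                       // pair (i = m, partner k)
          if (m != k) acc[k] += lx[posInCol[m]] * s; // pair (i = k, partner m)
        }
      }
    }
    double diagSum = 0.0;
    for (int idx = pj + 1; idx < pj1; ++idx) {
      const int i = ri[idx];
      sx[idx] = -acc[i] / ljj;
      diagSum += lx[idx] * sx[idx];
      acc[i] = 0.0;
      posInCol[i] = -1;
    }
    sx[pj] = (1.0 / ljj - diagSum) / ljj;
  }
  return Sx;
}

// Look up entries of the selected inverse at arbitrary (row, col) positions
// (1-based, in the *permuted* ordering). Positions outside the stored
// pattern return NA so callers can detect missing coverage.
// [[Rcpp::export]]
NumericVector selected_entries(IntegerVector Lp, IntegerVector Li,
                               NumericVector Sx, IntegerVector rows,
                               IntegerVector cols) {
  const int m = rows.size();
  NumericVector out(m);
  const int *p = INTEGER(Lp);
  const int *ri = INTEGER(Li);
  const double *sx = REAL(Sx);
  for (int t = 0; t < m; ++t) {
    int a = rows[t] - 1, b = cols[t] - 1;
    if (a < b) std::swap(a, b);
    int lo = p[b], hi = p[b + 1];
    while (lo < hi) {
      int mid = (lo + hi) >> 1;
      if (ri[mid] < a) lo = mid + 1; else hi = mid;
    }
    out[t] = (lo < p[b + 1] && ri[lo] == a) ? sx[lo] : NA_REAL;
  }
  return out;
}
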