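#include <Rcpp.h>
using namespace Rcpp;

// Checkerboard ("independent") swaps on a binary occurrence matrix.
// A swap exchanges a 2x2 submatrix [[1,0],[0,1]] <-> [[0,1],[1,0]] at a
// uniformly chosen pair of rows and columns, which leaves every row and
// column sum unchanged. Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
List independent_swap_cpp(IntegerMatrix m, int n_swaps, double max_attempts) {
  IntegerMatrix out = clone(m);
  const int nr = out.nrow(), nc = out.ncol();
  int done = 0;
  double attempts = 0.0;
  if (nr < 2 || nc < 2)
    return List::create(_["matrix"] = out, _["swaps"] = 0, _["attempts"] = 0.0);
  while (done < n_swaps && attempts < max_attempts) {
    attempts += 1.0;
    int r1 = (int)(unif_rand() * nr);
    int r2 = (int)(unif_rand() * (nr - 1));
    if (r2 >= r1) r2++;
    int c1 = (int)(unif_rand() * nc);
    int c2 = (int)(unif_rand() * (nc - 1));
    if (c2 >= c1) c2++;
    const int a = out(r1, c1), b = out(r1, c2), c = out(r2, c1), d = out(r2, c2);
    if (a == d && b == c && a != b) {
      out(r1, c1) = b; out(r1, c2) = a;
      out(r2, c1) = d; out(r2, c2) = c;
      done++;
    }
  }
  return List::create(_["matrix"] = out, _["swaps"] = done,
                      _["attempts"] = attempts);
}

// Mean pairwise distance for every row (community) of a binary matrix,
// given a species-by-species distance matrix aligned with the columns.
// Rows with fewer than two species yield NA.
// [[Rcpp::export]]
NumericVector mpd_rows_cpp(IntegerMatrix comm, NumericMatrix d) {
  const int nr = comm.nrow(), nc = comm.ncol();
  NumericVector out(nr);
  std::vector<int> idx;
  idx.reserve(nc);
  for (int i = 0; i < nr; i++) {
    idx.clear();
    for (int j = 0; j < nc; j++) if (comm(i, j) != 0) idx.push_back(j);
    const int k = (int)idx.size();
    if (k < 2) { out[i] = NA_REAL; continue; }
    double s = 0.0;
    for (int a = 1; a < k; a++)
      for (int b = 0; b < a; b++) s += d(idx[a], idx[b]);
    out[i] = s / (k * (k - 1) / 2.0);
  }
  return out;
}

// Mean nearest-taxon distance per row: for each present species, the
// distance to its closest co-occurring species, averaged over members.
// [[Rcpp::export]]
NumericVector mntd_rows_cpp(IntegerMatrix comm, NumericMatrix d) {
  const int nr = comm.nrow(), nc = comm.ncol();
  NumericVector out(nr);
  std::vector<int> idx;
  idx.reserve(nc);
  for (int i = 0; i < nr; i++) {
    idx.clear();
    for (int j = 0; j < nc; j++) if (comm(i, j) != 0) idx.push_back(j);
    const int k = (int)idx.size();
    if (k < 2) { out[i] = NA_REAL; continue; }
    double s = 0.0;
    for (int a = 0; a < k; a++) {
      double mn = R_PosInf;
      for (int b = 0; b < k; b++) {
        if (a == b) continue;
        const double v = d(idx[a], idx[b]);
        if (v < mn) mn = v;
      }
      s += mn;
    }
    out[i] = s / k;
  }
  return out;
}
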