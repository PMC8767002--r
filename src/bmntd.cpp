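#include <Rcpp.h>
using namespace Rcpp;

// Beta mean nearest-taxon distance for a set of tip permutations.
//
// D: N x N patristic distance matrix (tip order = column order of P).
// P: S x N per-sample weights (relative abundances, or 1/richness for the
//    unweighted variant); a taxon is "present" when its weight is > 0.
// perms: R x N, 1-based; row r maps OTU j onto tip perms(r, j), so the
//    distance between OTUs i and j under shuffle r is D(perm[i], perm[j]).
//    Row of 1..N = the observed (identity) assignment.
//
// Returns R x (S*(S-1)/2) matrix; pair columns ordered (0,1),(0,2),...,
// i.e. upper triangle by column as R's which(upper.tri(.)) yields.
// [[Rcpp::export]]
NumericMatrix bmntd_perms(const NumericMatrix& D, const NumericMatrix& P,
                          const IntegerMatrix& perms) {
  const int S = P.nrow(), N = P.ncol(), R = perms.nrow();
  if (D.nrow() != N || D.ncol() != N)
    stop("distance matrix does not match the taxon count");
  if (perms.ncol() != N) stop("permutation length does not match taxa");

  // presence lists per sample
  std::vector< std::vector<int> > idx(S);
  for (int s = 0; s < S; ++s)
    for (int j = 0; j < N; ++j)
      if (P(s, j) > 0) idx[s].push_back(j);

  const int npair = S * (S - 1) / 2;
  NumericMatrix out(R, npair);
  std::vector<double> dmin(static_cast<size_t>(S) * N);

  const double* Dp = D.begin();   // column-major N x N
  std::vector<int> perm(N);
  for (int r = 0; r < R; ++r) {
    for (int j = 0; j < N; ++j) perm[j] = perms(r, j) - 1;
    // dmin[s*N + i] = min_{j in sample s} D(perm[i], perm[j])
    for (int s = 0; s < S; ++s) {
      const std::vector<int>& js = idx[s];
      for (int i = 0; i < N; ++i) {
        const double* Dcol = Dp + static_cast<size_t>(perm[i]) * N;
        double best = R_PosInf;
        for (size_t t = 0; t < js.size(); ++t) {
          double d = Dcol[perm[js[t]]];
          if (d < best) best = d;
        }
        dmin[static_cast<size_t>(s) * N + i] = best;
      }
    }
    int col = 0;
    for (int m = 1; m < S; ++m) {
      for (int k = 0; k < m; ++k, ++col) {
        double a = 0.0, b = 0.0;
        const std::vector<int>& ik = idx[k];
        const std::vector<int>& im = idx[m];
        for (size_t t = 0; t < ik.size(); ++t)
          a += P(k, ik[t]) * dmin[static_cast<size_t>(m) * N + ik[t]];
        for (size_t t = 0; t < im.size(); ++t)
          b += P(m, im[t]) * dmin[static_cast<size_t>(k) * N + im[t]];
        out(r, col) = 0.5 * (a + b);
      }
    }
    if (r % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
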