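#include <Rcpp.h>

// Meuwissen & Luo (1992) inbreeding coefficients.
// sire/dam are 1-based indices into a topologically ordered pedigree
// (parents precede offspring); 0 marks an unknown parent, which is
// treated as an unrelated, non-inbred founder.
//
// For each animal the generalized Cholesky row L of A = L D L' is
// accumulated downward over ancestors; A_ii = sum_j L_ij^2 D_j and
// F_i = A_ii - 1. D_j is the Mendelian sampling variance given the
// parents' inbreeding.

// [[Rcpp::export]]
Rcpp::NumericVector ml_inbreeding(Rcpp::IntegerVector sire,
                                  Rcpp::IntegerVector dam) {
  const int n = sire.size();
  Rcpp::NumericVector F(n);
  std::vector<double> D(n), L(n);

  for (int i = 0; i < n; ++i) {
    const int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= i || d >= i) Rcpp::stop("pedigree is not topologically ordered");
    const double fs = (s >= 0) ? F[s] : 0.0;
    const double fd = (d >= 0) ? F[d] : 0.0;
    if (s >= 0 && d >= 0) {
      D[i] = 0.5 - 0.25 * (fs + fd);
    } else if (s >= 0 || d >= 0) {
      D[i] = 0.75 - 0.25 * (s >= 0 ? fs : fd);
    } else {
      D[i] = 1.0;
    }
    if (s < 0 || d < 0) {  // F only arises through both parental paths
      F[i] = 0.0;
      continue;
    }
    std::fill(L.begin(), L.begin() + i + 1, 0.0);
    L[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 0; --j) {
      const double lj = L[j];
      if (lj == 0.0) continue;
      aii += lj * lj * D[j];
      const int sj = sire[j] - 1, dj = dam[j] - 1;
      if (sj >= 0) L[sj] += 0.5 * lj;
      if (dj >= 0) L[dj] += 0.5 * lj;
    }
    F[i] = aii - 1.0;
  }
  return F;
}
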