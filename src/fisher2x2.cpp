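#include <Rcpp.h>
using namespace Rcpp;

// Two-sided Fisher's exact p-values for a vector of 2x2 tables
// ((m1, u1), (m2, u2)).  For each table the hypergeometric point mass is
// evaluated over the whole support of the first cell and all outcomes at
// most as probable as the observed one are summed, with the same
// (1 + 1e-7) relative tie tolerance stats::fisher.test uses.
//
// Written in C++ because a genome-scale window scan tests 10^4-10^5
// pooled read-count tables per context per run.

// [[Rcpp::export(name = ".fisher2x2_cpp")]]
NumericVector fisher2x2_cpp(IntegerVector m1, IntegerVector u1,
                            IntegerVector m2, IntegerVector u2) {
  const double relErr = 1.0 + 1e-7;
  R_xlen_t n = m1.size();
  if (u1.size() != n || m2.size() != n || u2.size() != n)
    stop("count vectors must have equal length");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    int a = m1[i], b = u1[i], c = m2[i], d = u2[i];
    if (a < 0 || b < 0 || c < 0 || d < 0)
      stop("negative cell count in 2x2 table");
    int n1 = a + b;      // reads in sample 1
    int n2 = c + d;      // reads in sample 2
    int K  = a + c;      // methylated reads overall
    int N  = n1 + n2;
    if (N == 0) { out[i] = 1.0; continue; }
    int lo = K - n2 > 0 ? K - n2 : 0;
    int hi = K < n1 ? K : n1;
    // log point mass of x methylated reads in sample 1
    double logObs = R::lchoose(n1, a) + R::lchoose(n2, K - a) -
                    R::lchoose(N, K);
    double thresh = logObs + std::log(relErr);
    double p = 0.0;
    for (int x = lo; x <= hi; ++x) {
      double lp = R::lchoose(n1, x) + R::lchoose(n2, K - x) -
                  R::lchoose(N, K);
      if (lp <= thresh) p += std::exp(lp);
    }
    out[i] = p > 1.0 ? 1.0 : p;
  }
  return out;
}
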