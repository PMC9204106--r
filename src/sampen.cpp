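#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy: -log(A/B) where B counts template pairs of length m and A
// pairs of length m+1 matching within Chebyshev tolerance r (self-matches
// excluded). Returns NA when no m-matches exist and R_PosInf when m-matches
// exist but no (m+1)-matches do.
// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;                 // templates with an (m+1)-th sample available
  if (nt < 2) return NA_REAL;
  const double *p = REAL(x);
  long long A = 0, B = 0;
  for (int i = 0; i < nt - 1; ++i) {
    const double *xi = p + i;
    for (int j = i + 1; j < nt; ++j) {
      const double *xj = p + j;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double dk = xi[k] - xj[k];
        if (dk > r || dk < -r) { ok = false; break; }
      }
      if (!ok) continue;
      ++B;
      double dm = xi[m] - xj[m];
      if (dm <= r && dm >= -r) ++A;
    }
  }
  if (B == 0) return NA_REAL;
  if (A == 0) return R_PosInf;
  return -std::log((double)A / (double)B);
}
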