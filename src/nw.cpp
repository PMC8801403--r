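#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise alignment score by the Gotoh dynamic program.
// A gap of length L costs gap_open + L * gap_extend (both penalties are
// passed as positive numbers). With ends_free = true, leading and trailing
// gaps in either sequence are free (semiglobal / overlap alignment);
// otherwise the alignment is fully global.
//
// This is the package's independent reference scorer: a direct quadratic
// textbook implementation used to cross-check the production alignment
// route in the test suite. Any base outside ACGT scores as a mismatch
// against everything, including itself.
//
// [[Rcpp::export]]
double nw_score_cpp(std::string a, std::string b,
                    double match = 2.0, double mismatch = -3.0,
                    double gap_open = 5.0, double gap_extend = 2.0,
                    bool ends_free = true) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e18;
  auto sub = [&](char x, char y) {
    bool okx = x=='A'||x=='C'||x=='G'||x=='T';
    bool oky = y=='A'||y=='C'||y=='G'||y=='T';
    return (okx && oky && x == y) ? match : mismatch;
  };
  // rolling rows over j
  std::vector<double> M(m + 1), X(m + 1), Y(m + 1), Mp(m + 1), Xp(m + 1), Yp(m + 1);
  Mp[0] = 0.0; Xp[0] = NEG; Yp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG; Xp[j] = NEG;
    Yp[j] = ends_free ? 0.0 : -(gap_open + j * gap_extend);
  }
  double best = NEG;
  if (ends_free && m >= 0) best = std::max(best, Mp[m]); // empty a
  for (int i = 1; i <= n; ++i) {
    M[0] = NEG; Y[0] = NEG;
    X[0] = ends_free ? 0.0 : -(gap_open + i * gap_extend);
    for (int j = 1; j <= m; ++j) {
      double diag = std::max(Mp[j-1], std::max(Xp[j-1], Yp[j-1]));
      M[j] = (diag <= NEG/2) ? NEG : diag + sub(a[i-1], b[j-1]);
      double mo = std::max(Mp[j], Yp[j]);
      X[j] = std::max(mo - (gap_open + gap_extend), Xp[j] - gap_extend);
      double mo2 = std::max(M[j-1], X[j-1]);
      Y[j] = std::max(mo2 - (gap_open + gap_extend), Y[j-1] - gap_extend);
    }
    if (ends_free) best = std::max(best, std::max(M[m], std::max(X[m], Y[m])));
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  if (ends_free) {
    for (int j = 0; j <= m; ++j)
      best = std::max(best, std::max(Mp[j], std::max(Xp[j], Yp[j])));
    return best;
  }
  return std::max(Mp[m], std::max(Xp[m], Yp[m]));
}
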