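#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Duplicate flags under the Chebyshev metric, brute-force O(n^2) oracle.
// Rows of E are sorted energy vectors of equal multiplicity.
// [[Rcpp::export(name = ".cheb_dup_brute")]]
LogicalVector cheb_dup_brute(NumericMatrix E, double delta) {
  const int n = E.nrow(), m = E.ncol();
  LogicalVector dup(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(E(i, k) - E(j, k));
        if (a > d) d = a;
        if (d > delta) break;
      }
      if (d <= delta) { dup[i] = true; dup[j] = true; }
    }
  }
  return dup;
}

// Exact Chebyshev-radius duplicate flags via a sliding window on the first
// sorted coordinate: any pair within Chebyshev distance delta must be within
// delta on coordinate 1, so sorting by it bounds the scan.
// [[Rcpp::export(name = ".cheb_dup_window")]]
LogicalVector cheb_dup_window(NumericMatrix E, double delta) {
  const int n = E.nrow(), m = E.ncol();
  LogicalVector dup(n);
  if (n < 2) return dup;
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return E(a, 0) < E(b, 0);
  });
  for (int ii = 0; ii < n; ++ii) {
    const int i = ord[ii];
    for (int jj = ii + 1; jj < n; ++jj) {
      const int j = ord[jj];
      if (E(j, 0) - E(i, 0) > delta) break;
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double a = std::fabs(E(i, k) - E(j, k));
        if (a > d) d = a;
        if (d > delta) break;
      }
      if (d <= delta) { dup[i] = true; dup[j] = true; }
    }
  }
  return dup;
}
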