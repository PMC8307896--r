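#include <Rcpp.h>

// Exhaustive-history Lempel-Ziv (1976) production counter, Kaspar-Schuster
// formulation. Works over any finite integer alphabet; only equality of
// symbols is used. A trailing component that is still reproducible when the
// sequence ends counts as one final production.
// [[Rcpp::export(name = ".lz76_count_cpp")]]
int lz76_count_cpp(Rcpp::IntegerVector s) {
  const int n = s.size();
  if (n == 0) Rcpp::stop("empty symbol sequence");
  if (n == 1) return 1;

  int c = 1;     // first symbol is component 1
  int l = 1;     // length of the parsed history A
  int i = 0;     // candidate match start within A (0-based)
  int k = 1;     // current extension length of B
  int kmax = 1;  // longest reproducible extension seen for this component

  for (;;) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) {  // sequence ended while B still reproducible
        ++c;
        break;
      }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {  // B not a substring of ABc anywhere: new component
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0;
        k = 1;
        kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
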