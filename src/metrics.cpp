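#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy: number of pairs (i, j), i < j,
// whose length-m subsequences match under the Chebyshev metric within tol,
// and the same for length m+1. Self-matches excluded by i < j.
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double tol) {
  int n = x.size();
  int nm = n - m; // number of length-(m+1) templates is n - m
  long double a = 0.0, b = 0.0;
  for (int i = 0; i < nm - 1; ++i) {
    for (int j = i + 1; j < nm; ++j) {
      double d = 0.0;
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        double diff = std::fabs(x[i + k] - x[j + k]);
        if (diff > d) d = diff;
        if (d > tol) { ok = false; break; }
      }
      if (!ok) continue;
      b += 1.0; // length-m match
      double diff = std::fabs(x[i + m] - x[j + m]);
      if (diff <= tol) a += 1.0; // extends to length m+1
    }
  }
  // Only the first n - m length-m templates are used for both counts, so
  // every counted template has a continuation (Richman-Moorman convention).
  return NumericVector::create((double)a, (double)b);
}

// LZ76 phrase count of a 0/1 integer sequence (exhaustive-history parsing).
// A new phrase is opened each time the current extension is no longer a
// substring of the preceding content; a trailing phrase that remains
// reproducible from history is not counted.
// [[Rcpp::export]]
int lz76_phrases(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  int c = 1;      // first symbol is always a phrase
  int i = 1;      // start of current candidate phrase
  while (i < n) {
    int len = 1;  // candidate phrase s[i .. i+len-1]
    while (i + len <= n) {
      // is s[i .. i+len-1] a substring of s[0 .. i+len-2]?
      bool found = false;
      for (int st = 0; st <= i - 1; ++st) { // overlap with all but Q's last char allowed
        bool match = true;
        for (int k = 0; k < len; ++k) {
          if (s[st + k] != s[i + k]) { match = false; break; }
        }
        if (match) { found = true; break; }
      }
      if (!found) {
        ++c;          // phrase terminates here (s[i..i+len-1] is new)
        i += len;
        len = 0;
        break;
      }
      ++len;          // still reproducible; extend
    }
    if (len > 0) break; // ran off the end while reproducible: trailing phrase uncounted
  }
  return c;
}
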