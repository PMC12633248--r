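#include <Rcpp.h>

// LZ76 exhaustive-history complexity (Kaspar & Schuster recurrence):
// number of phrases in the exhaustive production parsing of a symbol
// sequence. 0-indexed translation of the classic 1-indexed scheme where
// `pos` is the start of the phrase currently being extended, `i` the
// candidate start of a copy source in the prefix, `k` the current match
// length and `k_max` the longest match found for this phrase.
// [[Rcpp::export]]
int lz76_count(Rcpp::IntegerVector s) {
  const int n = s.size();
  if (n <= 1) return n;
  int c = 1, pos = 1, i = 0, k = 1, k_max = 1;
  while (true) {
    if (s[i + k - 1] == s[pos + k - 1]) {
      k++;
      if (pos + k > n) { c++; break; }
    } else {
      if (k > k_max) k_max = k;
      i++;
      if (i == pos) {
        c++;
        pos += k_max;
        if (pos >= n) break;
        i = 0; k = 1; k_max = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
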