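#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with linear gap penalty.
// a = pattern (e.g. a miRNA hairpin), b = subject (e.g. a lncRNA), both
// encoded 1..4. Traceback ties are broken diagonal > up > left; among equal
// maximal cells the one with the smallest pattern index, then subject index,
// is chosen, giving a deterministic total order.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(IntegerVector a, IntegerVector b,
                  double match, double mismatch, double gap) {
  const int n = a.size(), m = b.size();
  NumericMatrix H(n + 1, m + 1);
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = H(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
      double up = H(i - 1, j) + gap;
      double left = H(i, j - 1) + gap;
      double s = diag;
      if (up > s) s = up;
      if (left > s) s = left;
      if (s < 0.0) s = 0.0;
      H(i, j) = s;
      if (s > best) { best = s; bi = i; bj = j; }
    }
  }
  int matches = 0, mismatches = 0, gaps = 0, cols = 0;
  int i = bi, j = bj;
  int pat_end = bi, sub_end = bj;
  while (i > 0 && j > 0 && H(i, j) > 0.0) {
    double s = H(i, j);
    double sub = (a[i - 1] == b[j - 1] ? match : mismatch);
    if (s == H(i - 1, j - 1) + sub) {
      if (a[i - 1] == b[j - 1]) ++matches; else ++mismatches;
      --i; --j;
    } else if (s == H(i - 1, j) + gap) {
      ++gaps; --i;
    } else {
      ++gaps; --j;
    }
    ++cols;
  }
  return List::create(_["score"] = best,
                      _["matches"] = matches,
                      _["mismatches"] = mismatches,
                      _["gaps"] = gaps,
                      _["columns"] = cols,
                      _["pattern_start"] = i + 1,
                      _["pattern_end"] = pat_end,
                      _["subject_start"] = j + 1,
                      _["subject_end"] = sub_end);
}
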