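#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Exact thresholded all-pairs similarity join on L2-normalized sparse rows.
//
// Doc-at-a-time accumulation over an inverted index, with two provably
// lossless prunings:
//  * records sharing no positively weighted term are never touched
//    (cosine > 0 requires a shared term);
//  * each record's terms are processed in decreasing-weight order while
//    tracking the norm of the still-unprocessed suffix; once that norm
//    drops below the threshold, a pair first met now satisfies
//    dot <= ||suffix|| * 1 < threshold, so new candidates are no longer
//    opened (existing candidates keep accumulating, so no pair at or
//    above the threshold is lost).
// A small epsilon guards the inclusive threshold against float round-off.
//
// row_*: per record, features sorted by decreasing weight.
// col_*: per term, posting list sorted by increasing record index.
// All indices 0-based.
// [[Rcpp::export(rng = false)]]
List pair_join_sorted(IntegerVector row_ptr, IntegerVector row_term,
                      NumericVector row_val,
                      IntegerVector col_ptr, IntegerVector col_row,
                      NumericVector col_val,
                      int n_records, double threshold) {
  const double eps = 1e-12;
  std::vector<double> acc(n_records, 0.0);
  std::vector<int> touched;
  touched.reserve(1024);
  std::vector<int> out_a, out_b;
  std::vector<double> out_s;

  for (int r = 0; r < n_records; ++r) {
    double remaining = 0.0;
    for (int k = row_ptr[r]; k < row_ptr[r + 1]; ++k)
      remaining += row_val[k] * row_val[k];
    for (int k = row_ptr[r]; k < row_ptr[r + 1]; ++k) {
      int term = row_term[k];
      double w = row_val[k];
      bool allow_new = remaining >= threshold * threshold - eps;
      // first posting with record index > r
      const int *beg = &col_row[0] + col_ptr[term];
      const int *end = &col_row[0] + col_ptr[term + 1];
      const int *it = std::upper_bound(beg, end, r);
      for (int m = (int)(it - &col_row[0]); m < col_ptr[term + 1]; ++m) {
        int s = col_row[m];
        if (acc[s] == 0.0) {
          if (!allow_new) continue;
          touched.push_back(s);
        }
        acc[s] += w * col_val[m];
      }
      remaining -= w * w;
    }
    for (size_t u = 0; u < touched.size(); ++u) {
      int s = touched[u];
      if (acc[s] >= threshold - eps) {
        out_a.push_back(r + 1);
        out_b.push_back(s + 1);
        out_s.push_back(acc[s] > 1.0 ? 1.0 : acc[s]);
      }
      acc[s] = 0.0;
    }
    touched.clear();
  }
  return List::create(_["i"] = wrap(out_a), _["j"] = wrap(out_b),
                      _["score"] = wrap(out_s));
}
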