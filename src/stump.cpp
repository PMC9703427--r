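#include <Rcpp.h>
using namespace Rcpp;

// Exact weighted decision stump search for the SAMME boosting loop.
// Inputs are precomputed per training set: `ord` holds, per feature column,
// the 1-based row order that sorts the feature; `xs` the correspondingly
// sorted feature values. `y` is the 1-based class index per row, `w` the
// current boosting weights. The stump minimising weighted misclassification
// over all (feature, threshold) pairs is returned; each side predicts its
// weighted-majority class. Splits are only admissible between two distinct
// sorted values. Ties break to the earliest feature and lowest threshold,
// so the search is deterministic.
// [[Rcpp::export(name = ".stump_search")]]
List stump_search(const IntegerMatrix& ord, const NumericMatrix& xs,
                  const IntegerVector& y, const NumericVector& w,
                  const int n_classes) {
  const int n = ord.nrow(), K = ord.ncol();
  std::vector<double> tot(n_classes, 0.0);
  double sumw = 0.0;
  for (int i = 0; i < n; ++i) {
    tot[y[i] - 1] += w[i];
    sumw += w[i];
  }
  int maj = 0;
  for (int c = 1; c < n_classes; ++c) if (tot[c] > tot[maj]) maj = c;

  // no-split fallback: weighted-majority everywhere
  double best_err = sumw - tot[maj];
  int best_feat = 0, best_left = maj + 1, best_right = maj + 1;
  double best_thr = NA_REAL;

  std::vector<double> cw(n_classes);
  for (int k = 0; k < K; ++k) {
    std::fill(cw.begin(), cw.end(), 0.0);
    for (int i = 0; i < n - 1; ++i) {
      const int row = ord(i, k) - 1;
      cw[y[row] - 1] += w[row];
      if (xs(i, k) >= xs(i + 1, k)) continue;  // not a distinct-value boundary
      int lc = 0, rc = 0;
      for (int c = 1; c < n_classes; ++c) {
        if (cw[c] > cw[lc]) lc = c;
        if (tot[c] - cw[c] > tot[rc] - cw[rc]) rc = c;
      }
      const double err = sumw - cw[lc] - (tot[rc] - cw[rc]);
      if (err < best_err - 1e-15) {
        best_err = err;
        best_feat = k + 1;
        best_thr = (xs(i, k) + xs(i + 1, k)) / 2.0;
        best_left = lc + 1;
        best_right = rc + 1;
      }
    }
  }
  return List::create(_["err"] = best_err, _["feature"] = best_feat,
                      _["threshold"] = best_thr, _["left"] = best_left,
                      _["right"] = best_right);
}
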