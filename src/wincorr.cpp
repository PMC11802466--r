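#include <Rcpp.h>
using namespace Rcpp;

// Sliding-window Pearson correlation between every length-L window of each
// profile row and a fixed shape template.  Windows with zero variance (flat
// signal) yield NA: the correlation is undefined there and such windows must
// never count as matches.  Flatness is detected as max == min so the verdict
// is invariant under positive affine transforms of the profile.

// [[Rcpp::export]]
NumericMatrix window_corr_cpp(const NumericMatrix& P, const NumericVector& shape) {
  const int G = P.nrow(), B = P.ncol(), L = shape.size();
  if (L > B) stop("shape longer than profile row");
  const int W = B - L + 1;
  double ms = 0.0;
  for (int j = 0; j < L; ++j) ms += shape[j];
  ms /= L;
  double ssh = 0.0;
  for (int j = 0; j < L; ++j) { double d = shape[j] - ms; ssh += d * d; }
  if (ssh <= 0) stop("shape has zero variance");
  NumericMatrix R(G, W);
  for (int g = 0; g < G; ++g) {
    for (int p = 0; p < W; ++p) {
      double s = 0, q = 0, a = 0;
      double wmin = P(g, p), wmax = P(g, p);
      for (int j = 0; j < L; ++j) {
        double v = P(g, p + j);
        s += v; q += v * v; a += v * shape[j];
        if (v < wmin) wmin = v;
        if (v > wmax) wmax = v;
      }
      double den2 = (q - s * s / L) * ssh;
      if (wmax <= wmin || den2 <= 0) { R(g, p) = NA_REAL; continue; }
      R(g, p) = (a - s * ms) / std::sqrt(den2);
    }
  }
  return R;
}

// Match counts per row: number of window starts with r strictly above cutoff.
// Same arithmetic as window_corr_cpp without materialising the r matrix.

// [[Rcpp::export]]
IntegerVector window_match_count_cpp(const NumericMatrix& P, const NumericVector& shape,
                                     double cutoff) {
  const int G = P.nrow(), B = P.ncol(), L = shape.size();
  if (L > B) stop("shape longer than profile row");
  const int W = B - L + 1;
  double ms = 0.0;
  for (int j = 0; j < L; ++j) ms += shape[j];
  ms /= L;
  double ssh = 0.0;
  for (int j = 0; j < L; ++j) { double d = shape[j] - ms; ssh += d * d; }
  if (ssh <= 0) stop("shape has zero variance");
  IntegerVector out(G);
  for (int g = 0; g < G; ++g) {
    int n = 0;
    for (int p = 0; p < W; ++p) {
      double s = 0, q = 0, a = 0;
      double wmin = P(g, p), wmax = P(g, p);
      for (int j = 0; j < L; ++j) {
        double v = P(g, p + j);
        s += v; q += v * v; a += v * shape[j];
        if (v < wmin) wmin = v;
        if (v > wmax) wmax = v;
      }
      double den2 = (q - s * s / L) * ssh;
      if (wmax <= wmin || den2 <= 0) continue;
      if ((a - s * ms) / std::sqrt(den2) > cutoff) ++n;
    }
    out[g] = n;
  }
  return out;
}
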