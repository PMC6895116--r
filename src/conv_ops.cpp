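// Inner loops of the im2col convolution engine. The gather/scatter
// patterns here are pure data movement; keeping them in C++ leaves the
// heavy matrix products to BLAS while removing per-image R loop
// overhead.

#include <Rcpp.h>

using namespace Rcpp;

// Gather im2col patches for a batch. x: (npix x N) flattened activations,
// idx: (P x L) 1-based linear indices into one image. Returns (N*P x L).
// [[Rcpp::export]]
NumericMatrix im2col_batch(const NumericMatrix& x, const IntegerMatrix& idx) {
  const int npix = x.nrow(), N = x.ncol();
  const int P = idx.nrow(), L = idx.ncol();
  NumericMatrix out(N * P, L);
  for (int l = 0; l < L; ++l) {
    const int* col_idx = &idx(0, l);
    double* out_col = &out(0, l);
    for (int i = 0; i < N; ++i) {
      const double* xi = &x(0, i);
      double* o = out_col + (long long)i * P;
      for (int p = 0; p < P; ++p) o[p] = xi[col_idx[p] - 1];
    }
  }
  (void)npix;
  return out;
}

// Scatter-add the im2col gradient back to the input layout.
// dxcol: (N*P x L); returns (n_in x N).
// [[Rcpp::export]]
NumericMatrix col2im_batch(const NumericMatrix& dxcol,
                           const IntegerMatrix& idx,
                           const int n_in) {
  const int P = idx.nrow(), L = idx.ncol();
  const int N = dxcol.nrow() / P;
  NumericMatrix out(n_in, N);
  for (int l = 0; l < L; ++l) {
    const int* col_idx = &idx(0, l);
    const double* d_col = &dxcol(0, l);
    for (int i = 0; i < N; ++i) {
      double* oi = &out(0, i);
      const double* d = d_col + (long long)i * P;
      for (int p = 0; p < P; ++p) oi[col_idx[p] - 1] += d[p];
    }
  }
  return out;
}

// Reflow batched conv output A (N*P x C, image-major rows) to flattened
// activation columns (P*C x N).
// [[Rcpp::export]]
NumericMatrix reflow_batch(const NumericMatrix& a, const int P) {
  const int C = a.ncol();
  const int N = a.nrow() / P;
  NumericMatrix out(P * C, N);
  for (int c = 0; c < C; ++c) {
    const double* acol = &a(0, c);
    for (int i = 0; i < N; ++i) {
      const double* src = acol + (long long)i * P;
      double* dst = &out(0, i) + (long long)c * P;
      std::copy(src, src + P, dst);
    }
  }
  return out;
}

// Inverse of reflow: flattened activation columns (P*C x N) to batched
// matrix rows (N*P x C).
// [[Rcpp::export]]
NumericMatrix unflow_batch(const NumericMatrix& x, const int P) {
  const int N = x.ncol();
  const int C = x.nrow() / P;
  NumericMatrix out((long long)N * P, C);
  for (int c = 0; c < C; ++c) {
    double* ocol = &out(0, c);
    for (int i = 0; i < N; ++i) {
      const double* src = &x(0, i) + (long long)c * P;
      std::copy(src, src + P, ocol + (long long)i * P);
    }
  }
  return out;
}

// Nearest-neighbour augmentation gather + standardization for one RGB
// image: out = (img[lin], img[lin+np], img[lin+2np]) scaled.
// [[Rcpp::export]]
NumericVector augment_gather(const NumericVector& img,
                             const IntegerVector& lin, const int np,
                             const double mu, const double sd) {
  const int n = lin.size();
  NumericVector out(3 * n);
  const double inv = 1.0 / sd;
  for (int ch = 0; ch < 3; ++ch) {
    const int off = ch * np;
    double* o = &out[0] + (long long)ch * n;
    for (int p = 0; p < n; ++p) o[p] = (img[lin[p] - 1 + off] - mu) * inv;
  }
  return out;
}

static inline int reflect_edge(int j, int n) {
  // mirror-at-edge for 0-based j; exact for one period on each side
  if (j < 0) j = -j;
  if (j > n - 1) j = 2 * (n - 1) - j;
  if (j < 0) j = 0;
  if (j > n - 1) j = n - 1;
  return j;
}

// 1-based linear source indices for flips -> rotation about the centre
// -> shift, with reflected borders (matches the R reference resampler).
// [[Rcpp::export]]
IntegerVector augment_indices_cpp(const int h, const int w,
                                  const double theta, const bool flip_h,
                                  const bool flip_v, const double dx,
                                  const double dy) {
  IntegerVector out((long long)h * w);
  const double ca = std::cos(-theta), sa = std::sin(-theta);
  const double cy = (h + 1) / 2.0, cx = (w + 1) / 2.0;
  long long k = 0;
  for (int c = 0; c < w; ++c) {
    const double gc = (c + 1) - cx;
    for (int r = 0; r < h; ++r, ++k) {
      const double gr = (r + 1) - cy;
      int sr = reflect_edge((int)std::lround(cy + sa * gc + ca * gr - dy) - 1, h);
      int sc = reflect_edge((int)std::lround(cx + ca * gc - sa * gr - dx) - 1, w);
      if (flip_v) sr = h - 1 - sr;
      if (flip_h) sc = w - 1 - sc;
      out[k] = sr + sc * h + 1;
    }
  }
  return out;
}
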