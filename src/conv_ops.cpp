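// Convolution primitives for the denoising network.
//
// Tensor layout: R array with dim c(H, W, N, C) so that each channel of
// each image is a contiguous H*W block; element (h, w, n, c) sits at
// h + H*(w + W*(n + N*c)) (0-based). A full batch therefore reshapes for
// free into an (H*W*N) x C matrix. Weights are (k*k*Cin) x Cout matrices
// whose row index is ko + k*k*ci with ko = (kr + r) + k*(kc + r)
// enumerating kernel offsets column-major, matching the im2col below.
// Same-size convolution with zero padding.
//
// Performance notes (single CPU core):
// - GEMMs run in single precision: the thin shapes of a narrow U-Net go
//   several times faster through sgemm than dgemm, and float rounding
//   (~1e-7 relative) is far below the stochastic-gradient noise floor.
// - The forward im2col matrix can be retained (as an external pointer to
//   a float matrix) and reused for the weight gradient, halving the
//   backward's memory traffic.
// - Input gradients are a convolution of the output gradient with the
//   spatially flipped, transposed kernel: one im2col + one well-shaped
//   GEMM instead of a scatter-add with a K=Cout GEMM.
// - A convolution can take its input as two stacked-channel pieces
//   (upsampled features + encoder skip), which removes the explicit
//   concatenation/split copies of a U-Net in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col of a full tensor into columns [k*k*c0, k*k*(c0+C)) of col.
static void im2col_full(const double* x, int H, int W, int N, int C,
                        int k, arma::fmat& col, int c0) {
  const int r = (k - 1) / 2;
  const long HW = (long)H * W;
  for (int ci = 0; ci < C; ++ci) {
    for (int kc = -r; kc <= r; ++kc) {
      for (int kr = -r; kr <= r; ++kr) {
        const int ko = (kr + r) + k * (kc + r);
        float* dst0 = col.colptr(ko + k * k * (c0 + ci));
        for (int n = 0; n < N; ++n) {
          const double* plane = x + HW * (n + (long)N * ci);
          float* dst = dst0 + HW * n;
          for (int w = 0; w < W; ++w) {
            const int ws = w + kc;
            float* dcol = dst + (long)w * H;
            if (ws < 0 || ws >= W) {
              std::fill(dcol, dcol + H, 0.0f);
              continue;
            }
            const double* scol = plane + (long)ws * H;
            const int lo = std::max(0, -kr), hi = std::min(H, H - kr);
            for (int h = 0; h < lo; ++h) dcol[h] = 0.0f;
            for (int h = lo; h < hi; ++h) dcol[h] = (float)scol[h + kr];
            for (int h = hi; h < H; ++h) dcol[h] = 0.0f;
          }
        }
      }
    }
  }
}

static arma::fmat to_fmat(const NumericMatrix& m) {
  arma::fmat f(m.nrow(), m.ncol());
  const double* src = m.begin();
  float* dst = f.memptr();
  const long n = (long)m.nrow() * m.ncol();
  for (long i = 0; i < n; ++i) dst[i] = (float)src[i];
  return f;
}

// Reusable scratch arenas: repeatedly allocating and freeing the
// multi-hundred-MB im2col buffers costs more (page zeroing) than the
// GEMMs themselves, so scratch grows once and is reused for the rest of
// the session. Wrap the raw buffer in a non-owning strict arma view at
// the call site.
static float* arena_buf(int which, long n) {
  static std::vector<float> store[3];
  std::vector<float>& s = store[which];
  if ((long)s.size() < n) s.resize(n);
  return s.data();
}

// Forward convolution. x2 (optional) supplies additional input channels
// stacked after x's. With keep_col the float im2col matrix is returned
// as an external pointer for the backward pass; pass the previous
// pointer back in as `reuse` to recycle its memory across batches.
// [[Rcpp::export]]
List conv_fwd(NumericVector x, IntegerVector dims,
              Nullable<NumericVector> x2, int C2,
              NumericMatrix w, NumericVector b, int k,
              bool keep_col = false, SEXP reuse = R_NilValue) {
  const int H = dims[0], W = dims[1], N = dims[2], C1 = dims[3];
  const int C = C1 + C2;
  const int Cout = w.ncol();
  if (w.nrow() != k * k * C) stop("weight shape mismatch");
  const long HW = (long)H * W;
  const long M = HW * N;
  arma::fmat* col;
  std::unique_ptr<arma::fmat> col_scratch;
  SEXP colsexp = R_NilValue;
  bool own_col = false;
  if (!keep_col) {
    const long nc = (long)k * k * C;
    col_scratch.reset(new arma::fmat(arena_buf(0, M * nc), M, nc,
                                     false, true));
    col = col_scratch.get();
  } else if (reuse != R_NilValue) {
    XPtr<arma::fmat> prev(reuse);
    if (prev->n_rows == (arma::uword)M &&
        prev->n_cols == (arma::uword)(k * k * C)) {
      col = prev.get();
      colsexp = reuse;
    } else {
      col = new arma::fmat(M, k * k * C);
      own_col = true;
    }
  } else {
    col = new arma::fmat(M, k * k * C);
    own_col = true;
  }
  im2col_full(x.begin(), H, W, N, C1, k, *col, 0);
  if (x2.isNotNull()) {
    NumericVector xb(x2);
    im2col_full(xb.begin(), H, W, N, C2, k, *col, C1);
  }
  arma::fmat wf = to_fmat(w);
  arma::fmat out(arena_buf(1, M * Cout), M, Cout, false, true);
  out = (*col) * wf;  // M x Cout
  NumericVector y(M * Cout);
  for (int co = 0; co < Cout; ++co) {
    const double bias = b[co];
    double* dst = y.begin() + M * co;
    const float* src = out.colptr(co);
    for (long p = 0; p < M; ++p) dst[p] = (double)src[p] + bias;
  }
  y.attr("dim") = IntegerVector::create(H, W, N, Cout);
  if (keep_col) {
    if (own_col) colsexp = XPtr<arma::fmat>(col, true);
    return List::create(_["y"] = y, _["col"] = colsexp);
  }
  return List::create(_["y"] = y, _["col"] = R_NilValue);
}

// Backward pass. `colptr` is the external pointer produced by conv_fwd
// (keep_col = TRUE). Returns dw, db and - when requested - the input
// gradients, split back into the two stacked pieces.
// [[Rcpp::export]]
List conv_bwd(SEXP colptr, IntegerVector dims, int C2,
              NumericMatrix w, NumericVector dy, int k,
              bool need_dx = true) {
  XPtr<arma::fmat> col(colptr);
  const int H = dims[0], W = dims[1], N = dims[2], C1 = dims[3];
  const int C = C1 + C2;
  const int Cout = w.ncol();
  const int kk = k * k;
  const long HW = (long)H * W;
  const long M = HW * N;
  if (col->n_rows != (arma::uword)M || col->n_cols != (arma::uword)(kk * C))
    stop("cached im2col matrix does not match this convolution");
  // full-batch reshape of dy is layout-free: just convert to float
  arma::fmat dyg(arena_buf(1, M * Cout), M, Cout, false, true);
  {
    const double* src = dy.begin();
    float* dst = dyg.memptr();
    for (long i = 0; i < M * Cout; ++i) dst[i] = (float)src[i];
  }
  arma::fmat dwm = col->t() * dyg;
  arma::frowvec dbv = arma::sum(dyg, 0);
  NumericMatrix dw(w.nrow(), w.ncol());
  for (long i = 0; i < (long)w.nrow() * w.ncol(); ++i)
    dw[i] = (double)dwm.memptr()[i];
  NumericVector db(Cout);
  for (int i = 0; i < Cout; ++i) db[i] = (double)dbv[i];
  if (!need_dx)
    return List::create(_["dw"] = dw, _["db"] = db,
                        _["dx"] = R_NilValue, _["dx2"] = R_NilValue);
  // dx = conv(dy, flipped & transposed kernel)
  arma::fmat wf = to_fmat(w);
  arma::fmat wflip(kk * Cout, C);
  for (int ci = 0; ci < C; ++ci)
    for (int co = 0; co < Cout; ++co)
      for (int ko = 0; ko < kk; ++ko)
        wflip(ko + kk * co, ci) = wf((kk - 1 - ko) + kk * ci, co);
  arma::fmat dycol(arena_buf(2, M * kk * Cout), M, kk * Cout, false, true);
  im2col_full(dy.begin(), H, W, N, Cout, k, dycol, 0);
  arma::fmat dxg(arena_buf(0, M * C), M, C, false, true);
  dxg = dycol * wflip;  // M x C
  NumericVector dx(M * C1);
  for (int ci = 0; ci < C1; ++ci) {
    const float* src = dxg.colptr(ci);
    double* dst = dx.begin() + M * ci;
    for (long p = 0; p < M; ++p) dst[p] = (double)src[p];
  }
  dx.attr("dim") = IntegerVector::create(H, W, N, C1);
  if (C2 == 0)
    return List::create(_["dw"] = dw, _["db"] = db, _["dx"] = dx,
                        _["dx2"] = R_NilValue);
  NumericVector dx2(M * C2);
  for (int ci = 0; ci < C2; ++ci) {
    const float* src = dxg.colptr(C1 + ci);
    double* dst = dx2.begin() + M * ci;
    for (long p = 0; p < M; ++p) dst[p] = (double)src[p];
  }
  dx2.attr("dim") = IntegerVector::create(H, W, N, C2);
  return List::create(_["dw"] = dw, _["db"] = db, _["dx"] = dx,
                      _["dx2"] = dx2);
}

// Row medians of a numeric matrix (used by median filters).
// [[Rcpp::export]]
NumericVector row_medians(NumericMatrix m) {
  const int n = m.nrow(), p = m.ncol();
  NumericVector out(n);
  std::vector<double> buf(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) buf[j] = m(i, j);
    const int mid = p / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double hi = buf[mid];
    if (p % 2 == 1) {
      out[i] = hi;
    } else {
      double lo = *std::max_element(buf.begin(), buf.begin() + mid);
      out[i] = 0.5 * (lo + hi);
    }
  }
  return out;
}
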