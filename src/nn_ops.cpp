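// Elementwise / channel-wise network ops. These are trivial loops, but
// doing them in C++ avoids repeated full-array temporaries in R, which
// otherwise dominate the training profile.

#include <Rcpp.h>
using namespace Rcpp;

// Batch normalization forward over layout (H, W, N, C): channel c is the
// contiguous block [c*M, (c+1)*M) with M = H*W*N.
// [[Rcpp::export]]
List bn_fwd(NumericVector x, IntegerVector dims, NumericVector gamma,
            NumericVector beta, NumericVector rmean, NumericVector rvar,
            bool train, double eps) {
  const int C = dims[3];
  const long M = (long)dims[0] * dims[1] * dims[2];
  NumericVector y(M * C), xhat(train ? M * C : 0);
  NumericVector mu(C), v(C), invstd(C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + M * c;
    double m, var;
    if (train) {
      double s = 0, s2 = 0;
      for (long i = 0; i < M; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      m = s / M;
      var = s2 / M - m * m;
      if (var < 0) var = 0;
    } else {
      m = rmean[c];
      var = rvar[c];
    }
    const double is = 1.0 / std::sqrt(var + eps);
    mu[c] = m; v[c] = var; invstd[c] = is;
    const double g = gamma[c], b = beta[c];
    double* yc = y.begin() + M * c;
    if (train) {
      double* hc = xhat.begin() + M * c;
      for (long i = 0; i < M; ++i) {
        const double h = (xc[i] - m) * is;
        hc[i] = h;
        yc[i] = g * h + b;
      }
    } else {
      for (long i = 0; i < M; ++i) yc[i] = g * (xc[i] - m) * is + b;
    }
  }
  y.attr("dim") = dims;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["v"] = v, _["invstd"] = invstd);
}

// [[Rcpp::export]]
List bn_bwd(NumericVector dy, IntegerVector dims, NumericVector gamma,
            NumericVector xhat, NumericVector invstd) {
  const int C = dims[3];
  const long M = (long)dims[0] * dims[1] * dims[2];
  NumericVector dx(M * C), dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    const double* dyc = dy.begin() + M * c;
    const double* hc = xhat.begin() + M * c;
    double sg = 0, sb = 0;
    for (long i = 0; i < M; ++i) { sg += dyc[i] * hc[i]; sb += dyc[i]; }
    dgamma[c] = sg; dbeta[c] = sb;
    const double g = gamma[c], is = invstd[c];
    const double m1 = g * sb / M, m2 = g * sg / M;
    double* dxc = dx.begin() + M * c;
    for (long i = 0; i < M; ++i)
      dxc[i] = is * (g * dyc[i] - m1 - hc[i] * m2);
  }
  dx.attr("dim") = dims;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// y = max(a + b, 0) - the residual add + ReLU of a res-block.
// [[Rcpp::export]]
NumericVector relu_add(NumericVector a, NumericVector b) {
  const long n = a.size();
  NumericVector y(n);
  for (long i = 0; i < n; ++i) {
    const double s = a[i] + b[i];
    y[i] = s > 0 ? s : 0;
  }
  y.attr("dim") = a.attr("dim");
  return y;
}

// dpre = dy where the forward output was positive, 0 elsewhere.
// [[Rcpp::export]]
NumericVector relu_mask_mul(NumericVector dy, NumericVector y) {
  const long n = dy.size();
  NumericVector out(n);
  for (long i = 0; i < n; ++i) out[i] = y[i] > 0 ? dy[i] : 0;
  out.attr("dim") = dy.attr("dim");
  return out;
}

// 2x2 max pooling; `which` records the winning quadrant (0..3,
// first-wins under ties) for the backward pass.
// [[Rcpp::export]]
List maxpool_fwd(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  const long NC = (long)N * C;
  NumericVector y((long)Ho * Wo * NC);
  RawVector which((long)Ho * Wo * NC);
  for (long s = 0; s < NC; ++s) {
    const double* xs = x.begin() + (long)H * W * s;
    double* ys = y.begin() + (long)Ho * Wo * s;
    Rbyte* ws = which.begin() + (long)Ho * Wo * s;
    for (int w = 0; w < Wo; ++w) {
      const double* c0 = xs + (long)(2 * w) * H;
      const double* c1 = xs + (long)(2 * w + 1) * H;
      for (int h = 0; h < Ho; ++h) {
        const double v0 = c0[2 * h], v1 = c0[2 * h + 1];
        const double v2 = c1[2 * h], v3 = c1[2 * h + 1];
        double best = v0; int arg = 0;
        if (v1 > best) { best = v1; arg = 1; }
        if (v2 > best) { best = v2; arg = 2; }
        if (v3 > best) { best = v3; arg = 3; }
        ys[h + (long)Ho * w] = best;
        ws[h + (long)Ho * w] = (Rbyte)arg;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  return List::create(_["y"] = y, _["which"] = which);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(NumericVector dy, RawVector which,
                          IntegerVector dims) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int Ho = H / 2, Wo = W / 2;
  const long NC = (long)N * C;
  NumericVector dx((long)H * W * NC);
  for (long s = 0; s < NC; ++s) {
    double* xs = dx.begin() + (long)H * W * s;
    const double* ys = dy.begin() + (long)Ho * Wo * s;
    const Rbyte* ws = which.begin() + (long)Ho * Wo * s;
    for (int w = 0; w < Wo; ++w) {
      for (int h = 0; h < Ho; ++h) {
        const int arg = ws[h + (long)Ho * w];
        const int hh = 2 * h + (arg & 1), ww = 2 * w + (arg >> 1);
        xs[hh + (long)H * ww] = ys[h + (long)Ho * w];
      }
    }
  }
  dx.attr("dim") = dims;
  return dx;
}

// 2x nearest-neighbor upsampling.
// [[Rcpp::export]]
NumericVector upsample_fwd(NumericVector x, IntegerVector dims) {
  const int H = dims[0], W = dims[1], N = dims[2], C = dims[3];
  const int Ho = 2 * H, Wo = 2 * W;
  const long NC = (long)N * C;
  NumericVector y((long)Ho * Wo * NC);
  for (long s = 0; s < NC; ++s) {
    const double* xs = x.begin() + (long)H * W * s;
    double* ys = y.begin() + (long)Ho * Wo * s;
    for (int w = 0; w < W; ++w) {
      const double* xc = xs + (long)w * H;
      double* y0 = ys + (long)(2 * w) * Ho;
      double* y1 = ys + (long)(2 * w + 1) * Ho;
      for (int h = 0; h < H; ++h) {
        const double v = xc[h];
        y0[2 * h] = v; y0[2 * h + 1] = v;
        y1[2 * h] = v; y1[2 * h + 1] = v;
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, N, C);
  return y;
}

// [[Rcpp::export]]
NumericVector upsample_bwd(NumericVector dy, IntegerVector odims) {
  const int Ho = odims[0], Wo = odims[1], N = odims[2], C = odims[3];
  const int H = Ho / 2, W = Wo / 2;
  const long NC = (long)N * C;
  NumericVector dx((long)H * W * NC);
  for (long s = 0; s < NC; ++s) {
    const double* ys = dy.begin() + (long)Ho * Wo * s;
    double* xs = dx.begin() + (long)H * W * s;
    for (int w = 0; w < W; ++w) {
      const double* y0 = ys + (long)(2 * w) * Ho;
      const double* y1 = ys + (long)(2 * w + 1) * Ho;
      double* xc = xs + (long)w * H;
      for (int h = 0; h < H; ++h)
        xc[h] = y0[2 * h] + y0[2 * h + 1] + y1[2 * h] + y1[2 * h + 1];
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, N, C);
  return dx;
}
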