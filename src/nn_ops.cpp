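// Minimal conv / maxpool kernels for the phenotype classifier.
// Layout convention follows R arrays: x is (H, W, C, N) column-major,
// weights are (k, k, Cin, Cout), so im2col rows line up with the flattened
// weight matrix and convolution reduces to one GEMM per image.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// fill one image's patch rows into a batch-wide colT at row offset
static void im2col_rows(const double* x, int H, int W, int Cin,
                        int k, int stride, int pad, arma::mat& colT,
                        size_t row0) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  for (int c = 0; c < Cin; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int iw = 0; iw < k; ++iw) {
      for (int ih = 0; ih < k; ++ih) {
        const int r = ih + k * iw + k * k * c;
        double* dst = colT.colptr(r) + row0;
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + iw;
          if (w < 0 || w >= W) {
            for (int ho = 0; ho < Ho; ++ho) dst[ho + Ho * wo] = 0.0;
            continue;
          }
          const double* src = xc + (size_t)H * w;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * stride - pad + ih;
            dst[ho + Ho * wo] = (h < 0 || h >= H) ? 0.0 : src[h];
          }
        }
      }
    }
  }
}

static void col2im_acc(const arma::mat& colT, int H, int W, int Cin,
                       int k, int stride, int pad, double* gx) {
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  for (int c = 0; c < Cin; ++c) {
    double* gc = gx + (size_t)H * W * c;
    for (int iw = 0; iw < k; ++iw) {
      for (int ih = 0; ih < k; ++ih) {
        const int r = ih + k * iw + k * k * c;
        const double* src = colT.colptr(r);
        for (int wo = 0; wo < Wo; ++wo) {
          const int w = wo * stride - pad + iw;
          if (w < 0 || w >= W) continue;
          double* dst = gc + (size_t)H * w;
          for (int ho = 0; ho < Ho; ++ho) {
            const int h = ho * stride - pad + ih;
            if (h >= 0 && h < H) dst[h] += src[ho + Ho * wo];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         int stride, int pad) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int k = dw[0], Cout = dw[3];
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  const int kk = k * k * Cin;

  arma::mat Wm(const_cast<double*>(w.begin()), kk, Cout, false, true);
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  const size_t hw = (size_t)Ho * Wo;
  arma::mat colT(hw, kk);
  for (int n = 0; n < N; ++n) {
    im2col_rows(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, k, stride,
                pad, colT, 0);
    arma::mat Y(y.begin() + hw * Cout * n, hw, Cout, false, true);
    Y = colT * Wm;
    Y.each_row() += arma::rowvec(const_cast<double*>(b.begin()), Cout,
                                 false, true);
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                int stride, int pad) {
  IntegerVector dx = x.attr("dim"), dw = w.attr("dim");
  const int H = dx[0], W = dx[1], Cin = dx[2], N = dx[3];
  const int k = dw[0], Cout = dw[3];
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  const int kk = k * k * Cin;

  arma::mat Wm(const_cast<double*>(w.begin()), kk, Cout, false, true);
  NumericVector gx((size_t)H * W * Cin * N);
  gx.attr("dim") = dx;
  NumericVector gw((size_t)kk * Cout);
  gw.attr("dim") = dw;
  NumericVector gb(Cout);
  arma::mat gWm(gw.begin(), kk, Cout, false, true);
  arma::rowvec gbv(gb.begin(), Cout, false, true);

  const size_t hw = (size_t)Ho * Wo;
  arma::mat colT(hw, kk);
  arma::mat gcolT(hw, kk);
  for (int n = 0; n < N; ++n) {
    im2col_rows(x.begin() + (size_t)H * W * Cin * n, H, W, Cin, k, stride,
                pad, colT, 0);
    arma::mat Gy(const_cast<double*>(gy.begin()) + hw * Cout * n, hw, Cout,
                 false, true);
    gWm += colT.t() * Gy;
    gbv += arma::sum(Gy, 0);
    gcolT = Gy * Wm.t();
    col2im_acc(gcolT, H, W, Cin, k, stride, pad,
               gx.begin() + (size_t)H * W * Cin * n);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool_fwd(NumericVector x, int k, int stride, int pad) {
  IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], N = dx[3];
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);  // linear index into (H,W) slice
  IntegerVector dy = IntegerVector::create(Ho, Wo, C, N);
  y.attr("dim") = dy; idx.attr("dim") = dy;
  size_t q = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300; int bi = -1;
          for (int iw = 0; iw < k; ++iw) {
            const int w = wo * stride - pad + iw;
            if (w < 0 || w >= W) continue;
            for (int ih = 0; ih < k; ++ih) {
              const int h = ho * stride - pad + ih;
              if (h < 0 || h >= H) continue;
              const double v = xs[h + (size_t)H * w];
              if (v > best) { best = v; bi = h + H * w; }
            }
          }
          // note loop order: output written in (wo, ho) order but y is
          // (Ho,Wo)-major, so compute the target position explicitly
          const size_t pos = (size_t)ho + (size_t)Ho * wo +
            (size_t)Ho * Wo * (c + (size_t)C * n);
          y[pos] = (bi < 0) ? 0.0 : best;
          idx[pos] = bi;
          ++q;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd(NumericVector gy, IntegerVector idx,
                          int H, int W) {
  IntegerVector dy = gy.attr("dim");
  const int Ho = dy[0], Wo = dy[1], C = dy[2], N = dy[3];
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t off_in = (size_t)H * W * (c + (size_t)C * n);
      const size_t off_out = (size_t)Ho * Wo * (c + (size_t)C * n);
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) {
        const int bi = idx[off_out + p];
        if (bi >= 0) gx[off_in + bi] += gy[off_out + p];
      }
    }
  }
  return gx;
}

// batch-norm forward over (H,W,C,N): returns y and xhat given per-channel
// mean/invstd computed here (train) or supplied (eval)
// [[Rcpp::export]]
List bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
            NumericVector run_mean, NumericVector run_var,
            bool train, double momentum, double eps) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t hw = (size_t)H * W, cs = hw * C;
  NumericVector mu(C), var(C);
  if (train) {
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + cs * n + hw * c;
        for (size_t i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      const double m = (double)hw * N;
      mu[c] = s / m;
      var[c] = s2 / m - mu[c] * mu[c];
    }
  } else {
    mu = clone(run_mean); var = clone(run_var);
  }
  NumericVector y(x.size()), xhat(x.size());
  y.attr("dim") = d; xhat.attr("dim") = d;
  NumericVector invstd(C);
  for (int c = 0; c < C; ++c) invstd[c] = 1.0 / std::sqrt(var[c] + eps);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + cs * n + hw * c;
      double* ph = xhat.begin() + cs * n + hw * c;
      double* py = y.begin() + cs * n + hw * c;
      const double m0 = mu[c], is = invstd[c], g = gamma[c], b = beta[c];
      for (size_t i = 0; i < hw; ++i) {
        ph[i] = (p[i] - m0) * is;
        py[i] = ph[i] * g + b;
      }
    }
  }
  NumericVector nm(C), nv(C);
  for (int c = 0; c < C; ++c) {
    nm[c] = (1 - momentum) * run_mean[c] + momentum * mu[c];
    nv[c] = (1 - momentum) * run_var[c] + momentum * var[c];
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["invstd"] = invstd,
                      _["run_mean"] = train ? nm : run_mean,
                      _["run_var"] = train ? nv : run_var);
}

// [[Rcpp::export]]
List bn_bwd(NumericVector g, NumericVector xhat, NumericVector invstd,
            NumericVector gamma, bool train) {
  IntegerVector d = g.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t hw = (size_t)H * W, cs = hw * C;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0.0, sgx = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* pg = g.begin() + cs * n + hw * c;
      const double* ph = xhat.begin() + cs * n + hw * c;
      for (size_t i = 0; i < hw; ++i) { sg += pg[i]; sgx += pg[i] * ph[i]; }
    }
    dgamma[c] = sgx; dbeta[c] = sg;
  }
  NumericVector gx(g.size());
  gx.attr("dim") = d;
  const double m = (double)hw * N;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* pg = g.begin() + cs * n + hw * c;
      const double* ph = xhat.begin() + cs * n + hw * c;
      double* px = gx.begin() + cs * n + hw * c;
      const double ga = gamma[c], is = invstd[c];
      if (train) {
        const double t1 = dbeta[c] * ga / m, t2 = dgamma[c] * ga / m;
        for (size_t i = 0; i < hw; ++i)
          px[i] = (pg[i] * ga - t1 - ph[i] * t2) * is;
      } else {
        for (size_t i = 0; i < hw; ++i) px[i] = pg[i] * ga * is;
      }
    }
  }
  return List::create(_["gx"] = gx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}
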