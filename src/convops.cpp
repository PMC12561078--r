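#include <RcppArmadillo.h>
using namespace Rcpp;

// [[Rcpp::depends(RcppArmadillo)]]

// Feature maps are numeric arrays with dim (H, W, C, B), column-major.
// Convolution weights have dim (kh, kw, Cin, Cout).
//
// im2col uses an (N x K) layout, N = Ho*Wo output positions, K = kh*kw*Cin:
// writes down column `krow` are contiguous and the GEMM col * W_mat yields
// an (N x Cout) matrix that is exactly the output slice's memory layout.

static inline int out_dim(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static void im2col_nk(const double* x, int H, int W, int C,
                      int kh, int kw, int stride, int pad,
                      int Ho, int Wo, arma::mat& col) {
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int krow = i + kh * (j + kw * c);
        double* dst = col.colptr(krow);
        for (int ow = 0; ow < Wo; ++ow) {
          int wi = ow * stride - pad + j;
          double* d = dst + (size_t)Ho * ow;
          if (wi < 0 || wi >= W) {
            std::fill(d, d + Ho, 0.0);
            continue;
          }
          const double* xc = x + (size_t)H * (wi + (size_t)W * c);
          for (int oh = 0; oh < Ho; ++oh) {
            int hi = oh * stride - pad + i;
            d[oh] = (hi >= 0 && hi < H) ? xc[hi] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im_nk(double* dx, int H, int W, int C,
                      int kh, int kw, int stride, int pad,
                      int Ho, int Wo, const arma::mat& dcol) {
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < kw; ++j) {
      for (int i = 0; i < kh; ++i) {
        int krow = i + kh * (j + kw * c);
        const double* src = dcol.colptr(krow);
        for (int ow = 0; ow < Wo; ++ow) {
          int wi = ow * stride - pad + j;
          if (wi < 0 || wi >= W) continue;
          const double* s = src + (size_t)Ho * ow;
          double* xc = dx + (size_t)H * (wi + (size_t)W * c);
          for (int oh = 0; oh < Ho; ++oh) {
            int hi = oh * stride - pad + i;
            if (hi >= 0 && hi < H) xc[hi] += s[oh];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, NumericVector w,
                             NumericVector bias, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels, kernel expects %d", C, Cin);
  int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  int K = kh * kw * C, N = Ho * Wo;

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector y((size_t)N * Cout * B);
  arma::mat col(N, K);
  for (int b = 0; b < B; ++b) {
    im2col_nk(x.begin() + (size_t)H * W * C * b, H, W, C, kh, kw, stride, pad,
              Ho, Wo, col);
    // write the GEMM straight into the output slice (same memory layout)
    arma::mat Y(y.begin() + (size_t)N * Cout * b, N, Cout, false, true);
    Y = col * Wm;
    for (int o = 0; o < Cout; ++o) {
      double bo = bias[o];
      double* yp = Y.colptr(o);
      for (int n = 0; n < N; ++n) yp[n] += bo;
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, B);
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, NumericVector w, NumericVector dy,
                    int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = out_dim(H, kh, stride, pad), Wo = out_dim(W, kw, stride, pad);
  int K = kh * kw * C, N = Ho * Wo;

  arma::mat Wm(const_cast<double*>(w.begin()), K, Cout, false, true);
  NumericVector dx((size_t)H * W * C * B);
  NumericVector dw((size_t)K * Cout);
  NumericVector db(Cout);
  arma::mat dWacc(K, Cout, arma::fill::zeros);
  arma::vec dbacc(Cout, arma::fill::zeros);
  arma::mat col(N, K);
  arma::mat dcol(N, K);
  for (int b = 0; b < B; ++b) {
    im2col_nk(x.begin() + (size_t)H * W * C * b, H, W, C, kh, kw, stride, pad,
              Ho, Wo, col);
    arma::mat Dm(const_cast<double*>(dy.begin()) + (size_t)N * Cout * b,
                 N, Cout, false, true);
    dWacc += col.t() * Dm;
    dbacc += arma::sum(Dm, 0).t();
    dcol = Dm * Wm.t();  // N x K
    col2im_nk(dx.begin() + (size_t)H * W * C * b, H, W, C, kh, kw, stride,
              pad, Ho, Wo, dcol);
  }
  std::copy(dWacc.begin(), dWacc.end(), dw.begin());
  std::copy(dbacc.begin(), dbacc.end(), db.begin());
  dx.attr("dim") = IntegerVector::create(H, W, C, B);
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  int Ho = out_dim(H, k, stride, pad), Wo = out_dim(W, k, stride, pad);
  NumericVector y((size_t)Ho * Wo * C * B);
  IntegerVector am((size_t)Ho * Wo * C * B);  // 1-based flat index into x
  for (int b = 0; b < B; ++b) {
    const double* xs = x.begin() + (size_t)H * W * C * b;
    size_t off = (size_t)H * W * C * b;
    for (int c = 0; c < C; ++c) {
      for (int ow = 0; ow < Wo; ++ow) {
        for (int oh = 0; oh < Ho; ++oh) {
          double best = R_NegInf; size_t bidx = 0;
          for (int j = 0; j < k; ++j) {
            int wi = ow * stride - pad + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < k; ++i) {
              int hi = oh * stride - pad + i;
              if (hi < 0 || hi >= H) continue;
              size_t idx = hi + (size_t)H * (wi + (size_t)W * c);
              if (xs[idx] > best) { best = xs[idx]; bidx = idx; }
            }
          }
          size_t oidx = (size_t)oh +
            (size_t)Ho * (ow + (size_t)Wo * (c + (size_t)C * b));
          y[oidx] = best;
          am[oidx] = (int)(off + bidx) + 1;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, B);
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dy, IntegerVector argmax,
                              IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  for (R_xlen_t i = 0; i < dy.size(); ++i)
    dx[argmax[i] - 1] += dy[i];
  dx.attr("dim") = xdim;
  return dx;
}

// ---- batch normalization ---------------------------------------------------
// Per-channel moments over (H, W, B). Training mode computes batch moments;
// eval mode applies the provided running moments.

// [[Rcpp::export]]
List bn_fwd_cpp(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector mean_in, NumericVector var_in,
                double eps, bool training) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  size_t HW = (size_t)H * W;
  NumericVector y(x.size());
  NumericVector mu(C), va(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int b = 0; b < B; ++b) {
        const double* p = x.begin() + HW * (c + (size_t)C * b);
        for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      double n = (double)HW * B;
      mu[c] = s / n;
      double v = s2 / n - mu[c] * mu[c];
      va[c] = v > 0 ? v : 0;
    }
  } else {
    mu = clone(mean_in);
    va = clone(var_in);
  }
  NumericVector invstd(C);
  for (int c = 0; c < C; ++c) invstd[c] = 1.0 / std::sqrt(va[c] + eps);
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < C; ++c) {
      const double* p = x.begin() + HW * (c + (size_t)C * b);
      double* q = y.begin() + HW * (c + (size_t)C * b);
      double m = mu[c], is = invstd[c], g = gamma[c], bt = beta[c];
      for (size_t i = 0; i < HW; ++i) q[i] = g * (p[i] - m) * is + bt;
    }
  }
  y.attr("dim") = xd;
  return List::create(_["y"] = y, _["mean"] = mu, _["var"] = va,
                      _["invstd"] = invstd);
}

// [[Rcpp::export]]
List bn_bwd_cpp(NumericVector x, NumericVector dy, NumericVector gamma,
                NumericVector mean, NumericVector invstd, bool training) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], B = xd[3];
  size_t HW = (size_t)H * W;
  double n = (double)HW * B;
  NumericVector dx(x.size());
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sdy = 0, sdyx = 0;
    double m = mean[c], is = invstd[c];
    for (int b = 0; b < B; ++b) {
      const double* px = x.begin() + HW * (c + (size_t)C * b);
      const double* pd = dy.begin() + HW * (c + (size_t)C * b);
      for (size_t i = 0; i < HW; ++i) {
        sdy += pd[i];
        sdyx += pd[i] * (px[i] - m) * is;
      }
    }
    dgamma[c] = sdyx;
    dbeta[c] = sdy;
    double gis = gamma[c] * is;
    double mdy = sdy / n, mdyx = sdyx / n;
    for (int b = 0; b < B; ++b) {
      const double* px = x.begin() + HW * (c + (size_t)C * b);
      const double* pd = dy.begin() + HW * (c + (size_t)C * b);
      double* pq = dx.begin() + HW * (c + (size_t)C * b);
      if (training) {
        for (size_t i = 0; i < HW; ++i)
          pq[i] = gis * (pd[i] - mdy - (px[i] - m) * is * mdyx);
      } else {
        for (size_t i = 0; i < HW; ++i) pq[i] = gis * pd[i];
      }
    }
  }
  dx.attr("dim") = xd;
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ---- relu ------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector relu_fwd_cpp(NumericVector x) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd_cpp(NumericVector x, NumericVector dy) {
  NumericVector dx(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) dx[i] = x[i] > 0 ? dy[i] : 0;
  dx.attr("dim") = x.attr("dim");
  return dx;
}
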