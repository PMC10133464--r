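#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Tensor layout convention (column-major, matching R arrays):
//   activations  : (H, W, C, N)
//   conv weights : flattened to a (kh*kw*inC) x outC matrix, row index
//                  ki + kh*(kj + kw*c)  -- i.e. matrix(array(kh,kw,inC,outC))

static inline int out_len(int H, int k, int stride, int pad) {
  return (H + 2 * pad - k) / stride + 1;
}

static void im2col_one(const double* x, int H, int W, int C,
                       int kh, int kw, int stride, int pad,
                       arma::mat& cols) {
  const int oh = out_len(H, kh, stride, pad);
  const int ow = out_len(W, kw, stride, pad);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < ow; ++oj) {
          const int jin = oj * stride - pad + kj;
          const bool jok = (jin >= 0 && jin < W);
          for (int oi = 0; oi < oh; ++oi) {
            const int iin = oi * stride - pad + ki;
            double v = 0.0;
            if (jok && iin >= 0 && iin < H) v = x[iin + H * (jin + (long)W * c)];
            cols(row, oi + (long)oh * oj) = v;
          }
        }
      }
    }
  }
}

static void col2im_one(const arma::mat& cols, int H, int W, int C,
                       int kh, int kw, int stride, int pad, double* gx) {
  const int oh = out_len(H, kh, stride, pad);
  const int ow = out_len(W, kw, stride, pad);
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int row = ki + kh * (kj + kw * c);
        for (int oj = 0; oj < ow; ++oj) {
          const int jin = oj * stride - pad + kj;
          if (jin < 0 || jin >= W) continue;
          for (int oi = 0; oi < oh; ++oi) {
            const int iin = oi * stride - pad + ki;
            if (iin < 0 || iin >= H) continue;
            gx[iin + H * (jin + (long)W * c)] += cols(row, oi + (long)oh * oj);
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericMatrix wm, NumericVector b,
                         int kh, int kw, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int K = wm.nrow(), outC = wm.ncol();
  if (K != kh * kw * C) stop("weight matrix rows do not match kernel/channels");
  const int oh = out_len(H, kh, stride, pad);
  const int ow = out_len(W, kw, stride, pad);
  if (oh < 1 || ow < 1) stop("input spatially too small for this convolution");
  NumericVector y((R_xlen_t)oh * ow * outC * N);
  arma::mat wmat(wm.begin(), K, outC, false, true);
  arma::vec bv(b.begin(), outC, false, true);
  arma::mat cols(K, (long)oh * ow);
  const long sx = (long)H * W * C, sy = (long)oh * ow * outC;
  for (int n = 0; n < N; ++n) {
    im2col_one(x.begin() + n * sx, H, W, C, kh, kw, stride, pad, cols);
    arma::mat ym = wmat.t() * cols;           // outC x (oh*ow)
    ym.each_col() += bv;
    double* yp = y.begin() + n * sy;
    // write ym rows into (oh,ow,oc) column-major blocks
    for (long j = 0; j < (long)oh * ow; ++j)
      for (int oc = 0; oc < outC; ++oc)
        yp[j % oh + oh * ((j / oh) + (long)ow * oc)] = ym(oc, j);
  }
  y.attr("dim") = IntegerVector::create(oh, ow, outC, N);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericMatrix wm, NumericVector gy,
                int kh, int kw, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  IntegerVector dg = gy.attr("dim");
  const int oh = dg[0], ow = dg[1], outC = dg[2];
  const int K = wm.nrow();
  arma::mat wmat(wm.begin(), K, outC, false, true);
  NumericVector gx((long)H * W * C * N);
  NumericMatrix gw(K, outC);
  NumericVector gb(outC);
  arma::mat gwm(gw.begin(), K, outC, false, true);
  arma::vec gbv(gb.begin(), outC, false, true);
  arma::mat cols(K, (long)oh * ow);
  arma::mat gym(outC, (long)oh * ow);
  const long sx = (long)H * W * C, sy = (long)oh * ow * outC;
  for (int n = 0; n < N; ++n) {
    const double* gp = gy.begin() + n * sy;
    for (long j = 0; j < (long)oh * ow; ++j)
      for (int oc = 0; oc < outC; ++oc)
        gym(oc, j) = gp[j % oh + oh * ((j / oh) + (long)ow * oc)];
    im2col_one(x.begin() + n * sx, H, W, C, kh, kw, stride, pad, cols);
    gwm += cols * gym.t();
    gbv += arma::sum(gym, 1);
    arma::mat gcols = wmat * gym;
    col2im_one(gcols, H, W, C, kh, kw, stride, pad, gx.begin() + n * sx);
  }
  gx.attr("dim") = d;
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns pooled values and 1-based linear argmax
// indices into the input vector (for the scatter in the backward pass).
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("maxpool2 needs even spatial dims");
  const int oh = H / 2, ow = W / 2;
  NumericVector y((long)oh * ow * C * N);
  IntegerVector idx((long)oh * ow * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const long base = (long)H * W * (c + (long)C * n);
      for (int oj = 0; oj < ow; ++oj)
        for (int oi = 0; oi < oh; ++oi) {
          long best = base + (2 * oi) + (long)H * (2 * oj);
          double bv = x[best];
          const long cand[3] = {base + (2 * oi + 1) + (long)H * (2 * oj),
                                base + (2 * oi) + (long)H * (2 * oj + 1),
                                base + (2 * oi + 1) + (long)H * (2 * oj + 1)};
          for (int t = 0; t < 3; ++t)
            if (x[cand[t]] > bv) { bv = x[cand[t]]; best = cand[t]; }
          // output is (oh,ow,c,n) column-major but we fill per (c,n) block
          long oidx = oi + (long)oh * (oj + (long)ow * (c + (long)C * n));
          y[oidx] = bv;
          idx[oidx] = (int)(best + 1);
        }
    }
  y.attr("dim") = IntegerVector::create(oh, ow, C, N);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  NumericVector gx((long)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (long i = 0; i < gy.size(); ++i) gx[idx[i] - 1] += gy[i];
  gx.attr("dim") = xdim;
  return gx;
}

// Batch normalization over (H, W, N) per channel for (H, W, C, N) tensors.
// Layout makes each (c, n) pair a contiguous slab of H*W values.
// [[Rcpp::export(name = ".bn_fwd")]]
List bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
            NumericVector rmean, NumericVector rvar, bool train,
            double momentum, double eps) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const long hw = (long)H * W;
  const long m = hw * N;
  std::vector<double> mu(C), va(C), ivstd(C);
  if (train) {
    for (int c = 0; c < C; ++c) {
      double s = 0, s2 = 0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + hw * (c + (long)C * n);
        for (long i = 0; i < hw; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      mu[c] = s / m;
      va[c] = s2 / m - mu[c] * mu[c];
      if (va[c] < 0) va[c] = 0;
    }
  } else {
    for (int c = 0; c < C; ++c) { mu[c] = rmean[c]; va[c] = rvar[c]; }
  }
  NumericVector y(x.size()), xhat(x.size());
  for (int c = 0; c < C; ++c) {
    ivstd[c] = 1.0 / std::sqrt(va[c] + eps);
    const double g = gamma[c], b = beta[c], iv = ivstd[c], u = mu[c];
    for (int n = 0; n < N; ++n) {
      const long off = hw * (c + (long)C * n);
      const double* p = x.begin() + off;
      double* ph = xhat.begin() + off;
      double* py = y.begin() + off;
      for (long i = 0; i < hw; ++i) {
        ph[i] = (p[i] - u) * iv;
        py[i] = g * ph[i] + b;
      }
    }
  }
  NumericVector nm(C), nv(C), iv(C);
  for (int c = 0; c < C; ++c) {
    iv[c] = ivstd[c];
    if (train) {
      double unb = (m > 1) ? (double)m / (m - 1) : 1.0;
      nm[c] = (1 - momentum) * rmean[c] + momentum * mu[c];
      nv[c] = (1 - momentum) * rvar[c] + momentum * va[c] * unb;
    } else { nm[c] = rmean[c]; nv[c] = rvar[c]; }
  }
  y.attr("dim") = d; xhat.attr("dim") = d;
  return List::create(_["y"] = y, _["xhat"] = xhat, _["ivstd"] = iv,
                      _["run_mean"] = nm, _["run_var"] = nv);
}

// [[Rcpp::export(name = ".bn_bwd")]]
List bn_bwd(NumericVector gy, NumericVector xhat, NumericVector ivstd,
            NumericVector gamma, bool train) {
  IntegerVector d = gy.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const long hw = (long)H * W;
  const long m = hw * N;
  NumericVector gx(gy.size()), gg(C), gb(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0, sgx = 0;
    for (int n = 0; n < N; ++n) {
      const long off = hw * (c + (long)C * n);
      const double* pg = gy.begin() + off;
      const double* ph = xhat.begin() + off;
      for (long i = 0; i < hw; ++i) { sg += pg[i]; sgx += pg[i] * ph[i]; }
    }
    gg[c] = sgx; gb[c] = sg;
    const double ga = gamma[c], iv = ivstd[c];
    const double mg = sg / m, mgx = sgx / m;
    for (int n = 0; n < N; ++n) {
      const long off = hw * (c + (long)C * n);
      const double* pg = gy.begin() + off;
      const double* ph = xhat.begin() + off;
      double* px = gx.begin() + off;
      if (train)
        for (long i = 0; i < hw; ++i)
          px[i] = ga * iv * (pg[i] - mg - ph[i] * mgx);
      else
        for (long i = 0; i < hw; ++i)
          px[i] = ga * iv * pg[i];
    }
  }
  gx.attr("dim") = d;
  return List::create(_["gx"] = gx, _["ggamma"] = gg, _["gbeta"] = gb);
}

// [[Rcpp::export(name = ".relu_fwd")]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  for (long i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export(name = ".relu_bwd")]]
NumericVector relu_bwd(NumericVector y, NumericVector gy) {
  NumericVector gx(gy.size());
  for (long i = 0; i < gy.size(); ++i) gx[i] = y[i] > 0 ? gy[i] : 0;
  gx.attr("dim") = gy.attr("dim");
  return gx;
}
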