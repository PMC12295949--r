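// Low-level numeric kernels for the segmentation network and the surface
// metrics. Array layout conventions (column-major, as R stores them):
//   activations x : dim (H, W, C, N)
//   conv weights  : dim (k, k, Cin, Cout), same-padding, odd k
//   transposed 2x2 stride-2 weights: dim (2, 2, Cin, Cout)
// All convolutions are implemented as im2col + GEMM through Armadillo.

#include <RcppArmadillo.h>
using namespace Rcpp;

static inline IntegerVector dims4(const NumericVector& x) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  return d;
}

static inline NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

static inline IntegerVector alloc4i(int a, int b, int c, int d) {
  IntegerVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

// Build the im2col matrix for one sample: (k*k*Cin) x (H*W).
// Row index r = ki + k*kj + k*k*ci ; column index = h + H*w.
static void im2col(const double* x, int H, int W, int C, int k, int pad,
                   arma::mat& K) {
  const int HW = H * W;
  K.zeros();
  for (int ci = 0; ci < C; ++ci) {
    const double* plane = x + (size_t)ci * HW;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * ci;
        for (int w = 0; w < W; ++w) {
          const int iw = w + kj - pad;
          if (iw < 0 || iw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int ih = h + ki - pad;
            if (ih < 0 || ih >= H) continue;
            K(r, h + H * w) = plane[ih + H * iw];
          }
        }
      }
    }
  }
}

// Scatter-add a column matrix (k*k*Cin x H*W) back into an image plane.
static void col2im_add(const arma::mat& G, int H, int W, int C, int k, int pad,
                       double* gx) {
  const int HW = H * W;
  for (int ci = 0; ci < C; ++ci) {
    double* plane = gx + (size_t)ci * HW;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int r = ki + k * kj + k * k * ci;
        for (int w = 0; w < W; ++w) {
          const int iw = w + kj - pad;
          if (iw < 0 || iw >= W) continue;
          for (int h = 0; h < H; ++h) {
            const int ih = h + ki - pad;
            if (ih < 0 || ih >= H) continue;
            plane[ih + H * iw] += G(r, h + H * w);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cin = wd[2], Cout = wd[3];
  if (wd[1] != k) stop("non-square kernel");
  if (Cin != C) stop("conv2d: input has %d channels, weights expect %d", C, Cin);
  const int pad = (k - 1) / 2, HW = H * W, KK = k * k * Cin;

  NumericVector y = alloc4(H, W, Cout, N);
  arma::mat Wmat((double*)w.begin(), KK, Cout, false, true); // (kkCin x Cout)
  arma::rowvec bv((double*)b.begin(), Cout, false, true);
  arma::mat K(KK, HW);
  for (int s = 0; s < N; ++s) {
    im2col(x.begin() + (size_t)s * HW * C, H, W, C, k, pad, K);
    arma::mat ys(y.begin() + (size_t)s * HW * Cout, HW, Cout, false, true);
    ys = K.t() * Wmat;            // (HW x Cout)
    ys.each_row() += bv;
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const int pad = (k - 1) / 2, HW = H * W, KK = k * k * C;

  NumericVector gx = alloc4(H, W, C, N);
  NumericVector gw = alloc4(k, k, C, Cout);
  NumericVector gb(Cout);

  arma::mat Wmat((double*)w.begin(), KK, Cout, false, true);
  arma::mat GW((double*)gw.begin(), KK, Cout, false, true);
  arma::vec GB((double*)gb.begin(), Cout, false, true);
  arma::mat K(KK, HW);
  for (int s = 0; s < N; ++s) {
    im2col(x.begin() + (size_t)s * HW * C, H, W, C, k, pad, K);
    arma::mat gys((double*)gy.begin() + (size_t)s * HW * Cout, HW, Cout, false, true);
    GW += K * gys;                               // (kkCin x Cout)
    GB += arma::sum(gys, 0).t();
    arma::mat Gcol = Wmat * gys.t();             // (kkCin x HW)
    col2im_add(Gcol, H, W, C, k, pad, gx.begin() + (size_t)s * HW * C);
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transposed 2x2 stride-2 convolution: (H, W, Cin, N) -> (2H, 2W, Cout, N).
// [[Rcpp::export]]
NumericVector cpp_convt2_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("convt2: channel mismatch");
  const int HW = H * W, H2 = 2 * H, W2 = 2 * W;

  NumericVector y = alloc4(H2, W2, Cout, N);
  for (int s = 0; s < N; ++s) {
    arma::mat X((double*)x.begin() + (size_t)s * HW * C, HW, C, false, true);
    double* yp = y.begin() + (size_t)s * H2 * W2 * Cout;
    for (int kj = 0; kj < 2; ++kj) {
      for (int ki = 0; ki < 2; ++ki) {
        arma::mat Wk(C, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < C; ++ci)
            Wk(ci, co) = w[ki + 2 * (kj + 2 * (ci + C * co))];
        arma::mat Ys = X * Wk;   // (HW x Cout)
        for (int co = 0; co < Cout; ++co) {
          for (int wcol = 0; wcol < W; ++wcol) {
            for (int h = 0; h < H; ++h) {
              yp[(2 * h + ki) + H2 * ((2 * wcol + kj) + W2 * co)] +=
                Ys(h + H * wcol, co);
            }
          }
        }
      }
    }
    for (int co = 0; co < Cout; ++co) {
      double* plane = yp + (size_t)co * H2 * W2;
      for (int i = 0; i < H2 * W2; ++i) plane[i] += b[co];
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_convt2_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = dims4(x);
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Cout = wd[3];
  const int HW = H * W, H2 = 2 * H, W2 = 2 * W;

  NumericVector gx = alloc4(H, W, C, N);
  NumericVector gw = alloc4(2, 2, C, Cout);
  NumericVector gb(Cout);
  for (int s = 0; s < N; ++s) {
    arma::mat X((double*)x.begin() + (size_t)s * HW * C, HW, C, false, true);
    arma::mat GX((double*)gx.begin() + (size_t)s * HW * C, HW, C, false, true);
    const double* gyp = gy.begin() + (size_t)s * H2 * W2 * Cout;
    arma::mat Gs(HW, Cout);
    for (int kj = 0; kj < 2; ++kj) {
      for (int ki = 0; ki < 2; ++ki) {
        for (int co = 0; co < Cout; ++co)
          for (int wcol = 0; wcol < W; ++wcol)
            for (int h = 0; h < H; ++h)
              Gs(h + H * wcol, co) =
                gyp[(2 * h + ki) + H2 * ((2 * wcol + kj) + W2 * co)];
        arma::mat Wk(C, Cout);
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < C; ++ci)
            Wk(ci, co) = w[ki + 2 * (kj + 2 * (ci + C * co))];
        GX += Gs * Wk.t();
        arma::mat GWk = X.t() * Gs;  // (C x Cout)
        for (int co = 0; co < Cout; ++co)
          for (int ci = 0; ci < C; ++ci)
            gw[ki + 2 * (kj + 2 * (ci + C * co))] += GWk(ci, co);
        // every output pixel belongs to exactly one (ki,kj) phase, so the
        // four phase sums together give the full bias gradient
        for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(Gs.col(co));
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 stride-2 max pooling; idx stores 0-based linear index into x.
// [[Rcpp::export]]
List cpp_maxpool2_fw(NumericVector x) {
  IntegerVector xd = dims4(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % 2 || W % 2) stop("maxpool2: spatial dims must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N);
  size_t o = 0;
  for (int s = 0; s < N; ++s) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)(s * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300; size_t bi = 0;
          for (int dj = 0; dj < 2; ++dj) {
            for (int di = 0; di < 2; ++di) {
              size_t ii = base + (2 * ho + di) + (size_t)H * (2 * wo + dj);
              if (x[ii] > best) { best = x[ii]; bi = ii; }
            }
          }
          y[o] = best; idx[o] = (int)bi; ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// 3x3 stride-1 same-padded max pooling.
// [[Rcpp::export]]
List cpp_maxpool3s1_fw(NumericVector x) {
  IntegerVector xd = dims4(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  NumericVector y = alloc4(H, W, C, N);
  IntegerVector idx = alloc4i(H, W, C, N);
  size_t o = 0;
  for (int s = 0; s < N; ++s) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)(s * C + c) * H * W;
      for (int w = 0; w < W; ++w) {
        for (int h = 0; h < H; ++h) {
          double best = -1e300; size_t bi = 0;
          for (int dj = -1; dj <= 1; ++dj) {
            const int iw = w + dj; if (iw < 0 || iw >= W) continue;
            for (int di = -1; di <= 1; ++di) {
              const int ih = h + di; if (ih < 0 || ih >= H) continue;
              size_t ii = base + ih + (size_t)H * iw;
              if (x[ii] > best) { best = x[ii]; bi = ii; }
            }
          }
          y[o] = best; idx[o] = (int)bi; ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// Shared scatter-add backward for both pooling ops.
// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(IntegerVector idx, NumericVector gy, IntegerVector xdim) {
  NumericVector gx = alloc4(xdim[0], xdim[1], xdim[2], xdim[3]);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}

// Batch normalization over (H, W, N) per channel, training mode.
// [[Rcpp::export]]
List cpp_bn_train_fw(NumericVector x, NumericVector gamma, NumericVector beta,
                     double eps) {
  IntegerVector xd = dims4(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W;
  const double M = (double)HW * N;
  NumericVector y = alloc4(H, W, C, N);
  NumericVector mean(C), var(C), invstd(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    const double mu = s / M;
    const double v = s2 / M - mu * mu;
    mean[c] = mu; var[c] = v > 0 ? v : 0;
    invstd[c] = 1.0 / std::sqrt(var[c] + eps);
    const double a = gamma[c] * invstd[c], b0 = beta[c] - a * mu;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + ((size_t)n * C + c) * HW;
      double* q = y.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) q[i] = a * p[i] + b0;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mean, _["var"] = var,
                      _["invstd"] = invstd);
}

// [[Rcpp::export]]
List cpp_bn_train_bw(NumericVector x, NumericVector mean, NumericVector invstd,
                     NumericVector gamma, NumericVector gy) {
  IntegerVector xd = dims4(x);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W;
  const double M = (double)HW * N;
  NumericVector gx = alloc4(H, W, C, N);
  NumericVector ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    const double mu = mean[c], is = invstd[c];
    double sum_gy = 0, sum_gy_xhat = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + ((size_t)n * C + c) * HW;
      const double* g = gy.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) {
        sum_gy += g[i];
        sum_gy_xhat += g[i] * (p[i] - mu) * is;
      }
    }
    ggamma[c] = sum_gy_xhat; gbeta[c] = sum_gy;
    const double gc = gamma[c];
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + ((size_t)n * C + c) * HW;
      const double* g = gy.begin() + ((size_t)n * C + c) * HW;
      double* q = gx.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) {
        const double xhat = (p[i] - mu) * is;
        q[i] = gc * is / M * (M * g[i] - sum_gy - xhat * sum_gy_xhat);
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// [[Rcpp::export]]
NumericVector cpp_bn_eval_fw(NumericVector x, NumericVector gamma,
                             NumericVector beta, NumericVector rmean,
                             NumericVector rvar, double eps) {
  IntegerVector xd = dims4(x);
  const int C = xd[2], N = xd[3];
  const size_t HW = (size_t)xd[0] * xd[1];
  NumericVector y = alloc4(xd[0], xd[1], C, N);
  for (int c = 0; c < C; ++c) {
    const double is = 1.0 / std::sqrt(rvar[c] + eps);
    const double a = gamma[c] * is, b0 = beta[c] - a * rmean[c];
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + ((size_t)n * C + c) * HW;
      double* q = y.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) q[i] = a * p[i] + b0;
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_bn_eval_bw(NumericVector gamma, NumericVector rvar,
                             double eps, NumericVector gy) {
  IntegerVector xd = dims4(gy);
  const int C = xd[2], N = xd[3];
  const size_t HW = (size_t)xd[0] * xd[1];
  NumericVector gx = alloc4(xd[0], xd[1], C, N);
  for (int c = 0; c < C; ++c) {
    const double a = gamma[c] / std::sqrt(rvar[c] + eps);
    for (int n = 0; n < N; ++n) {
      const double* g = gy.begin() + ((size_t)n * C + c) * HW;
      double* q = gx.begin() + ((size_t)n * C + c) * HW;
      for (size_t i = 0; i < HW; ++i) q[i] = a * g[i];
    }
  }
  return gx;
}

// ---- exact anisotropic Euclidean distance transform (squared), 3-d ----
// One-dimensional lower envelope of parabolas on an evenly spaced grid with
// spacing s; f holds squared distances, INF where no site yet.
// The "no site" value is the large finite 1e300, not IEEE Inf, so that the
// intersection formula stays well defined on empty scan lines (1e300 - 1e300
// is exactly 0, giving the midpoint intersection of equal parabolas).
static void dt1d(std::vector<double>& f, double s, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  const int n = (int)f.size();
  const double INF = 1e300;
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    const double xq = q * s;
    double xv, inter;
    while (true) {
      xv = v[k] * s;
      inter = (f[q] + xq * xq - f[v[k]] - xv * xv) / (2 * xq - 2 * xv);
      if (k > 0 && inter <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = inter; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * s;
    while (z[k + 1] < xq) ++k;
    const double xv = v[k] * s;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
  f = d;
}

// Squared-distance transform to the TRUE voxels of a 3-d logical array,
// with per-axis physical spacing (mm). Returns distances in mm.
// [[Rcpp::export]]
NumericVector cpp_edt3d(LogicalVector sites, NumericVector spacing) {
  IntegerVector sd = sites.attr("dim");
  if (sd.size() != 3) stop("expected a 3-d array");
  const int H = sd[0], W = sd[1], D = sd[2];
  const double INF = 1e300;
  std::vector<double> F((size_t)H * W * D);
  for (size_t i = 0; i < F.size(); ++i) F[i] = sites[i] ? 0.0 : INF;

  const int nmax = std::max(H, std::max(W, D));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 1 (H, fastest)
  for (int t = 0; t < D; ++t)
    for (int w = 0; w < W; ++w) {
      f.resize(H); d.resize(H);
      for (int h = 0; h < H; ++h) f[h] = F[h + (size_t)H * (w + (size_t)W * t)];
      dt1d(f, spacing[0], d, v, z);
      for (int h = 0; h < H; ++h) F[h + (size_t)H * (w + (size_t)W * t)] = f[h];
    }
  // axis 2 (W)
  for (int t = 0; t < D; ++t)
    for (int h = 0; h < H; ++h) {
      f.resize(W); d.resize(W);
      for (int w = 0; w < W; ++w) f[w] = F[h + (size_t)H * (w + (size_t)W * t)];
      dt1d(f, spacing[1], d, v, z);
      for (int w = 0; w < W; ++w) F[h + (size_t)H * (w + (size_t)W * t)] = f[w];
    }
  // axis 3 (D)
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      f.resize(D); d.resize(D);
      for (int t = 0; t < D; ++t) f[t] = F[h + (size_t)H * (w + (size_t)W * t)];
      dt1d(f, spacing[2], d, v, z);
      for (int t = 0; t < D; ++t) F[h + (size_t)H * (w + (size_t)W * t)] = f[t];
    }

  NumericVector out(Dimension(H, W, D));
  for (size_t i = 0; i < F.size(); ++i)
    out[i] = F[i] >= INF ? R_PosInf : std::sqrt(F[i]);
  return out;
}

// Foreground voxels with at least one background 6-neighbor (the volume
// boundary counts as background). Returns 1-based (i, j, t) coordinates.
// [[Rcpp::export]]
IntegerMatrix cpp_surface_voxels(LogicalVector mask) {
  IntegerVector md = mask.attr("dim");
  if (md.size() != 3) stop("expected a 3-d array");
  const int H = md[0], W = md[1], D = md[2];
  auto at = [&](int h, int w, int t) -> bool {
    if (h < 0 || h >= H || w < 0 || w >= W || t < 0 || t >= D) return false;
    return mask[h + (size_t)H * (w + (size_t)W * t)];
  };
  std::vector<int> hs, ws, ts;
  for (int t = 0; t < D; ++t)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        if (!at(h, w, t)) continue;
        if (!at(h - 1, w, t) || !at(h + 1, w, t) || !at(h, w - 1, t) ||
            !at(h, w + 1, t) || !at(h, w, t - 1) || !at(h, w, t + 1)) {
          hs.push_back(h + 1); ws.push_back(w + 1); ts.push_back(t + 1);
        }
      }
  IntegerMatrix out((int)hs.size(), 3);
  for (int i = 0; i < (int)hs.size(); ++i) {
    out(i, 0) = hs[i]; out(i, 1) = ws[i]; out(i, 2) = ts[i];
  }
  return out;
}
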