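// Low-level numerical kernels: im2col-based 2-D convolution (forward and
// backward), 2x2 max pooling, and a flood-fill component counter for binary
// rasters. Tensors are R arrays in (H, W, C, N) column-major layout; kernels
// are (kh, kw, Cin, Cout).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Batched single-precision im2col: fills the (Ho*Wo*N x kh*kw*C) column
// matrix for all samples at once. Column index = ki + kh*(kj + kw*c); row
// index = ho + Ho*(wo + Wo*n). Single precision halves memory traffic and
// doubles BLAS throughput; weights/activations are well inside float range.
static void im2col_batch(const double* x, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad,
                         arma::fmat& col) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  const size_t hwo = (size_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        float* dst0 = col.colptr(ki + kh * (kj + kw * c));
        for (int n = 0; n < N; ++n) {
          const double* xc = x + (size_t)H * W * (c + (size_t)C * n);
          float* dst = dst0 + hwo * n;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kj;
            float* d = dst + (size_t)Ho * wo;
            if (wi < 0 || wi >= W) {
              std::fill(d, d + Ho, 0.0f);
              continue;
            }
            const double* s = xc + (size_t)H * wi;
            if (stride == 1) {
              const int hi0 = -pad + ki;
              int ho = 0;
              for (; ho < Ho && ho + hi0 < 0; ++ho) d[ho] = 0.0f;
              const int hmax = std::min(Ho, H - hi0);
              for (; ho < hmax; ++ho) d[ho] = (float)s[ho + hi0];
              for (; ho < Ho; ++ho) d[ho] = 0.0f;
            } else {
              for (int ho = 0; ho < Ho; ++ho) {
                const int hi = ho * stride - pad + ki;
                d[ho] = (hi >= 0 && hi < H) ? (float)s[hi] : 0.0f;
              }
            }
          }
        }
      }
    }
  }
}

// scatter-add the im2col gradient back into the (H, W, C, N) input layout
static void col2im_batch(const arma::fmat& gcol, int H, int W, int C, int N,
                         int kh, int kw, int stride, int pad, double* gx) {
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  const size_t hwo = (size_t)Ho * Wo;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const float* src0 = gcol.colptr(ki + kh * (kj + kw * c));
        for (int n = 0; n < N; ++n) {
          double* gc = gx + (size_t)H * W * (c + (size_t)C * n);
          const float* src = src0 + hwo * n;
          for (int wo = 0; wo < Wo; ++wo) {
            const int wi = wo * stride - pad + kj;
            if (wi < 0 || wi >= W) continue;
            const float* s = src + (size_t)Ho * wo;
            double* g = gc + (size_t)H * wi;
            for (int ho = 0; ho < Ho; ++ho) {
              const int hi = ho * stride - pad + ki;
              if (hi >= 0 && hi < H) g[hi] += (double)s[ho];
            }
          }
        }
      }
    }
  }
}

static arma::fmat weights_f(const double* w, int kkc, int Co) {
  arma::fmat wm(kkc, Co);
  std::copy(w, w + (size_t)kkc * Co, wm.begin());
  return wm;
}

static NumericVector conv_fw_impl(NumericVector x, NumericVector w,
                                  NumericVector b, int stride, int pad,
                                  arma::fmat& col) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  if (wd[2] != C) stop("conv: channel mismatch");
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  const size_t hwo = (size_t)Ho * Wo;

  arma::fmat wm = weights_f(w.begin(), kh * kw * C, Co);
  col.set_size(hwo * N, kh * kw * C);
  im2col_batch(x.begin(), H, W, C, N, kh, kw, stride, pad, col);
  arma::fmat Y = col * wm;                          // one sgemm
  NumericVector y(hwo * (size_t)Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      const float* s = Y.colptr(co) + hwo * n;
      double* d = y.begin() + hwo * (co + (size_t)Co * n);
      const double bc = b[co];
      for (size_t i = 0; i < hwo; ++i) d[i] = (double)s[i] + bc;
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv_fw(NumericVector x, NumericVector w, NumericVector b,
                          int stride, int pad) {
  arma::fmat col;
  return conv_fw_impl(x, w, b, stride, pad, col);
}

// forward that also hands back the im2col matrix for reuse in the backward
// pass (saves rebuilding it)
// [[Rcpp::export]]
List cpp_conv_fw_cache(NumericVector x, NumericVector w, NumericVector b,
                       int stride, int pad) {
  XPtr<arma::fmat> colp(new arma::fmat(), true);
  NumericVector y = conv_fw_impl(x, w, b, stride, pad, *colp);
  return List::create(_["y"] = y, _["col"] = colp);
}

// [[Rcpp::export]]
List cpp_conv_bw(NumericVector x, NumericVector w, NumericVector gy,
                 int stride, int pad, bool need_gx = true,
                 SEXP col_cache = R_NilValue) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Co = wd[3];
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  const size_t hwo = (size_t)Ho * Wo;

  arma::fmat wm = weights_f(w.begin(), kh * kw * C, Co);
  arma::fmat col_local;
  arma::fmat* col;
  if (col_cache != R_NilValue) {
    XPtr<arma::fmat> colp(col_cache);
    col = colp.get();
  } else {
    col_local.set_size(hwo * N, kh * kw * C);
    im2col_batch(x.begin(), H, W, C, N, kh, kw, stride, pad, col_local);
    col = &col_local;
  }

  // gather gy into (Ho*Wo*N x Co) float layout
  arma::fmat Gy(hwo * N, Co);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Co; ++co) {
      const double* s = gy.begin() + hwo * (co + (size_t)Co * n);
      float* d = Gy.colptr(co) + hwo * n;
      for (size_t i = 0; i < hwo; ++i) d[i] = (float)s[i];
    }

  arma::fmat gwf = col->t() * Gy;                   // (kkC x Co)

  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Co);
  std::copy(gwf.begin(), gwf.end(), gw.begin());
  arma::frowvec gbf = arma::sum(Gy, 0);
  for (int co = 0; co < Co; ++co) gb[co] = gbf[co];

  if (!need_gx) {
    return List::create(_["gx"] = R_NilValue, _["gw"] = gw, _["gb"] = gb);
  }
  arma::fmat gcol = Gy * wm.t();                    // (rows x kkC)
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  col2im_batch(gcol, H, W, C, N, kh, kw, stride, pad, gx.begin());
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// in-place-style fast ReLU pair
// [[Rcpp::export]]
NumericVector cpp_relu(NumericVector z) {
  NumericVector y(z.size());
  y.attr("dim") = z.attr("dim");
  const double* zi = z.begin();
  double* yi = y.begin();
  for (R_xlen_t i = 0; i < z.size(); ++i) yi[i] = zi[i] > 0 ? zi[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bw(NumericVector gy, NumericVector z) {
  NumericVector g(gy.size());
  g.attr("dim") = gy.attr("dim");
  const double* gi = gy.begin();
  const double* zi = z.begin();
  double* go = g.begin();
  for (R_xlen_t i = 0; i < gy.size(); ++i) go[i] = zi[i] > 0 ? gi[i] : 0.0;
  return g;
}

// 2x2 max pooling, stride 2; returns pooled values and flat argmax indices
// [[Rcpp::export]]
List cpp_pool_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const int h0 = 2 * ho, w0 = 2 * wo;
          size_t best = h0 + (size_t)H * w0;
          double bv = xc[best];
          const size_t cand[3] = {h0 + 1 + (size_t)H * w0,
                                  h0 + (size_t)H * (w0 + 1),
                                  h0 + 1 + (size_t)H * (w0 + 1)};
          for (int t = 0; t < 3; ++t)
            if (xc[cand[t]] > bv) { bv = xc[cand[t]]; best = cand[t]; }
          y[o] = bv;
          idx[o] = (int)(best + (size_t)H * W * (c + (size_t)C * n));
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_pool_bw(NumericVector gy, IntegerVector idx,
                          IntegerVector in_dim) {
  size_t total = (size_t)in_dim[0] * in_dim[1] * in_dim[2] * in_dim[3];
  NumericVector gx(total);
  gx.attr("dim") = in_dim;
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[idx[i]] += gy[i];
  return gx;
}

// number of 4-connected foreground components of a binary matrix
// [[Rcpp::export]]
int cpp_n_components(NumericMatrix m) {
  const int H = m.nrow(), W = m.ncol();
  std::vector<char> seen((size_t)H * W, 0);
  std::vector<int> stack;
  int comps = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      const size_t id = i + (size_t)H * j;
      if (m[id] == 0 || seen[id]) continue;
      ++comps;
      stack.push_back((int)id);
      seen[id] = 1;
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        int ci = cur % H, cj = cur / H;
        const int di[4] = {1, -1, 0, 0};
        const int dj[4] = {0, 0, 1, -1};
        for (int t = 0; t < 4; ++t) {
          int ni = ci + di[t], nj = cj + dj[t];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          size_t nid = ni + (size_t)H * nj;
          if (m[nid] != 0 && !seen[nid]) {
            seen[nid] = 1;
            stack.push_back((int)nid);
          }
        }
      }
    }
  }
  return comps;
}

// Instance normalization: per (channel, sample) standardization over the
// spatial plane. Returns y plus the per-slice mean and inverse sigma needed
// by the backward pass.
// [[Rcpp::export]]
List cpp_inorm_fw(NumericVector x, NumericVector g, NumericVector b,
                  double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t hw = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  NumericVector mu(C * N), inv(C * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + hw * (c + (size_t)C * n);
      double* ys = y.begin() + hw * (c + (size_t)C * n);
      double s = 0.0, s2 = 0.0;
      for (size_t i = 0; i < hw; ++i) { s += xs[i]; s2 += xs[i] * xs[i]; }
      const double m = s / hw;
      const double v = s2 / hw - m * m;
      const double iv = 1.0 / std::sqrt(v > 0 ? v + eps : eps);
      mu[c + C * n] = m;
      inv[c + C * n] = iv;
      const double gc = g[c] * iv, bc = b[c];
      for (size_t i = 0; i < hw; ++i) ys[i] = gc * (xs[i] - m) + bc;
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["inv"] = inv);
}

// [[Rcpp::export]]
List cpp_inorm_bw(NumericVector x, NumericVector g, NumericVector mu,
                  NumericVector inv, NumericVector gy) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t hw = (size_t)H * W;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gg(C), gb(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + hw * (c + (size_t)C * n);
      const double* gs = gy.begin() + hw * (c + (size_t)C * n);
      double* go = gx.begin() + hw * (c + (size_t)C * n);
      const double m = mu[c + C * n], iv = inv[c + C * n];
      double s1 = 0.0, s2 = 0.0;
      for (size_t i = 0; i < hw; ++i) {
        const double xh = (xs[i] - m) * iv;
        s1 += gs[i];
        s2 += gs[i] * xh;
      }
      gg[c] += s2;
      gb[c] += s1;
      const double m1 = s1 / hw, m2 = s2 / hw, giv = g[c] * iv;
      for (size_t i = 0; i < hw; ++i) {
        const double xh = (xs[i] - m) * iv;
        go[i] = giv * (gs[i] - m1 - xh * m2);
      }
    }
  }
  return List::create(_["gx"] = gx, _["gg"] = gg, _["gb"] = gb);
}

// 2x2 stride-2 transposed convolution (forward): each input pixel paints a
// 2x2 output block
// [[Rcpp::export]]
NumericVector cpp_upconv_fw(NumericVector x, NumericVector w,
                            NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int Co = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * Co * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Co, N);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      double* yo = y.begin() + (size_t)Ho * Wo * (co + (size_t)Co * n);
      const double bc = b[co];
      for (R_xlen_t i = 0; i < (R_xlen_t)Ho * Wo; ++i) yo[i] = bc;
      for (int ci = 0; ci < Ci; ++ci) {
        const double* xs = x.begin() + (size_t)H * W * (ci + (size_t)Ci * n);
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const double wv = w[di + 2 * (dj + 2 * (ci + (size_t)Ci * co))];
            if (wv == 0) continue;
            for (int wc = 0; wc < W; ++wc) {
              const double* xc = xs + (size_t)H * wc;
              double* yc = yo + di + (size_t)Ho * (2 * wc + dj);
              for (int h = 0; h < H; ++h) yc[2 * h] += wv * xc[h];
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_upconv_bw(NumericVector x, NumericVector w, NumericVector gy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Ci = xd[2], N = xd[3];
  const int Co = wd[3];
  const int Ho = 2 * H;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  NumericVector gb(Co);
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Co; ++co) {
      const double* go = gy.begin() + (size_t)Ho * 2 * W * (co + (size_t)Co * n);
      double s = 0.0;
      for (R_xlen_t i = 0; i < (R_xlen_t)Ho * 2 * W; ++i) s += go[i];
      gb[co] += s;
      for (int ci = 0; ci < Ci; ++ci) {
        const double* xs = x.begin() + (size_t)H * W * (ci + (size_t)Ci * n);
        double* gxs = gx.begin() + (size_t)H * W * (ci + (size_t)Ci * n);
        for (int dj = 0; dj < 2; ++dj) {
          for (int di = 0; di < 2; ++di) {
            const double wv = w[di + 2 * (dj + 2 * (ci + (size_t)Ci * co))];
            double acc = 0.0;
            for (int wc = 0; wc < W; ++wc) {
              const double* gc = go + di + (size_t)Ho * (2 * wc + dj);
              const double* xc = xs + (size_t)H * wc;
              double* gxc = gxs + (size_t)H * wc;
              for (int h = 0; h < H; ++h) {
                const double gv = gc[2 * h];
                acc += gv * xc[h];
                gxc[h] += gv * wv;
              }
            }
            gw[di + 2 * (dj + 2 * (ci + (size_t)Ci * co))] += acc;
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}


// Fused instance norm + ReLU: y = max(0, g * xhat + b). The backward pass
// reuses y > 0 as the ReLU mask.
// [[Rcpp::export]]
List cpp_inrelu_fw(NumericVector x, NumericVector g, NumericVector b,
                   double eps) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t hw = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  NumericVector mu(C * N), inv(C * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + hw * (c + (size_t)C * n);
      double* ys = y.begin() + hw * (c + (size_t)C * n);
      double s = 0.0, s2 = 0.0;
      for (size_t i = 0; i < hw; ++i) { s += xs[i]; s2 += xs[i] * xs[i]; }
      const double m = s / hw;
      const double v = s2 / hw - m * m;
      const double iv = 1.0 / std::sqrt(v > 0 ? v + eps : eps);
      mu[c + C * n] = m;
      inv[c + C * n] = iv;
      const double gc = g[c] * iv, bc = b[c];
      for (size_t i = 0; i < hw; ++i) {
        const double val = gc * (xs[i] - m) + bc;
        ys[i] = val > 0 ? val : 0.0;
      }
    }
  }
  return List::create(_["y"] = y, _["mu"] = mu, _["inv"] = inv);
}

// [[Rcpp::export]]
List cpp_inrelu_bw(NumericVector x, NumericVector g, NumericVector mu,
                   NumericVector inv, NumericVector gy, NumericVector y) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t hw = (size_t)H * W;
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gg(C), gb(C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xs = x.begin() + hw * (c + (size_t)C * n);
      const double* gs = gy.begin() + hw * (c + (size_t)C * n);
      const double* ys = y.begin() + hw * (c + (size_t)C * n);
      double* go = gx.begin() + hw * (c + (size_t)C * n);
      const double m = mu[c + C * n], iv = inv[c + C * n];
      double s1 = 0.0, s2 = 0.0;
      for (size_t i = 0; i < hw; ++i) {
        const double gi = ys[i] > 0 ? gs[i] : 0.0;
        const double xh = (xs[i] - m) * iv;
        s1 += gi;
        s2 += gi * xh;
      }
      gg[c] += s2;
      gb[c] += s1;
      const double m1 = s1 / hw, m2 = s2 / hw, giv = g[c] * iv;
      for (size_t i = 0; i < hw; ++i) {
        const double gi = ys[i] > 0 ? gs[i] : 0.0;
        const double xh = (xs[i] - m) * iv;
        go[i] = giv * (gi - m1 - xh * m2);
      }
    }
  }
  return List::create(_["gx"] = gx, _["gg"] = gg, _["gb"] = gb);
}
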