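// Low-level stride-1 convolution, 2x2 max-pool and 2x2 transposed-convolution
// kernels used by the residual U-net. Activations are R arrays laid out
// H x W x C x N (column-major); weights for a k x k convolution are stored as
// a (k*k*Cin) x Cout matrix whose row index runs kr + kc*k + ch*k*k, matching
// the im2col layout below.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static void check_dims4(const NumericVector& x, IntegerVector& d) {
  if (!x.hasAttribute("dim")) stop("expected a 4-d array");
  d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array");
}

// im2col for one sample, transposed layout: cols is (H*W) x (k*k*Cin) with
// output pixel p = r + c*H in the rows, so each kernel-offset/channel fills
// one contiguous column via segment copies.
static void im2col(const double* x, int H, int W, int C, int k, int pad,
                   arma::mat& cols) {
  const int kk = k * k;
  for (int ch = 0; ch < C; ++ch) {
    const double* xc = x + (size_t)ch * H * W;
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        double* col = cols.colptr(kr + kc * k + ch * kk);
        const int dr = kr - pad;               // source row = r + dr
        const int r_lo = std::max(0, -dr);     // valid output rows
        const int r_hi = std::min(H, H - dr);
        for (int c = 0; c < W; ++c) {
          double* dst = col + (size_t)c * H;
          const int sc = c + kc - pad;
          if (sc < 0 || sc >= W || r_lo >= r_hi) {
            std::fill(dst, dst + H, 0.0);
            continue;
          }
          const double* src = xc + (size_t)sc * H + dr;
          if (r_lo > 0) std::fill(dst, dst + r_lo, 0.0);
          std::copy(src + r_lo, src + r_hi, dst + r_lo);
          if (r_hi < H) std::fill(dst + r_hi, dst + H, 0.0);
        }
      }
    }
  }
}

// scatter-add of column gradients back to the padded input positions
static void col2im(const arma::mat& cols, int H, int W, int C, int k, int pad,
                   double* dx) {
  const int kk = k * k;
  for (int ch = 0; ch < C; ++ch) {
    double* xc = dx + (size_t)ch * H * W;
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        const double* col = cols.colptr(kr + kc * k + ch * kk);
        const int dr = kr - pad;
        const int r_lo = std::max(0, -dr);
        const int r_hi = std::min(H, H - dr);
        if (r_lo >= r_hi) continue;
        for (int c = 0; c < W; ++c) {
          const int sc = c + kc - pad;
          if (sc < 0 || sc >= W) continue;
          const double* src = col + (size_t)c * H;
          double* dst = xc + (size_t)sc * H + dr;
          for (int r = r_lo; r < r_hi; ++r) dst[r] += src[r];
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericMatrix w, NumericVector b,
                        int k, int pad) {
  IntegerVector d;
  check_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = w.ncol();
  if (w.nrow() != k * k * C) stop("weight/input channel mismatch");
  NumericVector out(NumericVector((size_t)H * W * Cout * N));
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::rowvec bv(b.begin(), b.size());
  arma::mat cols(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * C;
    im2col(xs, H, W, C, k, pad, cols);
    // output sample memory is exactly (H*W) x Cout column-major
    arma::mat y(out.begin() + (size_t)n * H * W * Cout, H * W, Cout,
                false, true);
    y = cols * wm;
    y.each_row() += bv;
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericMatrix w, NumericVector dy,
               int k, int pad) {
  IntegerVector d, dd;
  check_dims4(x, d);
  check_dims4(dy, dd);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = w.ncol();
  if (dd[2] != Cout || dd[0] != H || dd[1] != W || dd[3] != N)
    stop("gradient shape mismatch");
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = d;
  NumericMatrix dw(w.nrow(), w.ncol());
  NumericVector db(Cout);
  arma::mat wm(w.begin(), w.nrow(), w.ncol(), false);
  arma::mat dwm(dw.begin(), dw.nrow(), dw.ncol(), false, true);
  arma::vec dbv(db.begin(), db.size(), false, true);
  arma::mat cols(H * W, k * k * C);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * C;
    // gradient sample memory is already (H*W) x Cout column-major
    const arma::mat dym(const_cast<double*>(dy.begin()) +
                        (size_t)n * H * W * Cout, H * W, Cout, false);
    im2col(xs, H, W, C, k, pad, cols);
    dwm += cols.t() * dym;
    dbv += arma::sum(dym, 0).t();
    arma::mat dcols = dym * wm.t();       // (H*W) x (k*k*C)
    col2im(dcols, H, W, C, k, pad, dx.begin() + (size_t)n * H * W * C);
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(NumericVector x) {
  IntegerVector d;
  check_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  if (H % 2 || W % 2) stop("max-pool input must have even spatial size");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((size_t)Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx((size_t)Ho * Wo * C * N); // linear index into the input plane
  idx.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int ch = 0; ch < C; ++ch) {
      const double* pl = x.begin() + ((size_t)n * C + ch) * H * W;
      for (int c = 0; c < Wo; ++c) {
        for (int r = 0; r < Ho; ++r) {
          const int r0 = 2 * r, c0 = 2 * c;
          int best = r0 + c0 * H;
          double bv = pl[best];
          const int cand[3] = { r0 + 1 + c0 * H, r0 + (c0 + 1) * H,
                                r0 + 1 + (c0 + 1) * H };
          for (int t = 0; t < 3; ++t)
            if (pl[cand[t]] > bv) { bv = pl[cand[t]]; best = cand[t]; }
          out[o] = bv;
          idx[o] = best;
          ++o;
        }
      }
    }
  }
  return List::create(_["y"] = out, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
NumericVector maxpool2_bw(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  IntegerVector d;
  check_dims4(dy, d);
  const int Ho = d[0], Wo = d[1], C = d[2], N = d[3];
  const int H = xdim[0], W = xdim[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int ch = 0; ch < C; ++ch) {
      double* pl = dx.begin() + ((size_t)n * C + ch) * H * W;
      for (int j = 0; j < Ho * Wo; ++j, ++o) pl[idx[o]] += dy[o];
    }
  }
  return dx;
}

// Transposed convolution, kernel 2, stride 2 (non-overlapping upsampling).
// w is (4*Cin) x Cout with row index a + 2*b + 4*ch for offset (a, b).
// [[Rcpp::export(name = ".upconv2_fw")]]
NumericVector upconv2_fw(NumericVector x, NumericMatrix w, NumericVector b) {
  IntegerVector d;
  check_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = w.ncol();
  if (w.nrow() != 4 * C) stop("weight/input channel mismatch");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * C;
    double* os = out.begin() + (size_t)n * Ho * Wo * Cout;
    for (int oc = 0; oc < Cout; ++oc) {
      double* pl = os + (size_t)oc * Ho * Wo;
      const double bias = b[oc];
      for (size_t j = 0; j < (size_t)Ho * Wo; ++j) pl[j] = bias;
      for (int ch = 0; ch < C; ++ch) {
        const double* xp = xs + (size_t)ch * H * W;
        const double w00 = w(0 + 4 * ch, oc), w10 = w(1 + 4 * ch, oc);
        const double w01 = w(2 + 4 * ch, oc), w11 = w(3 + 4 * ch, oc);
        for (int c = 0; c < W; ++c) {
          for (int r = 0; r < H; ++r) {
            const double v = xp[r + (size_t)c * H];
            double* q = pl + 2 * r + (size_t)(2 * c) * Ho;
            q[0] += w00 * v;
            q[1] += w10 * v;
            q[Ho] += w01 * v;
            q[Ho + 1] += w11 * v;
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".upconv2_bw")]]
List upconv2_bw(NumericVector x, NumericMatrix w, NumericVector dy) {
  IntegerVector d, dd;
  check_dims4(x, d);
  check_dims4(dy, dd);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Cout = w.ncol();
  const int Ho = 2 * H;
  if (dd[0] != Ho || dd[2] != Cout || dd[3] != N) stop("gradient shape mismatch");
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = d;
  NumericMatrix dw(w.nrow(), w.ncol());
  NumericVector db(Cout);
  const int Wo = 2 * W;
  for (int n = 0; n < N; ++n) {
    const double* xs = x.begin() + (size_t)n * H * W * C;
    const double* dys = dy.begin() + (size_t)n * Ho * Wo * Cout;
    double* dxs = dx.begin() + (size_t)n * H * W * C;
    for (int oc = 0; oc < Cout; ++oc) {
      const double* pl = dys + (size_t)oc * Ho * Wo;
      double acc = 0.0;
      for (size_t j = 0; j < (size_t)Ho * Wo; ++j) acc += pl[j];
      db[oc] += acc;
      for (int ch = 0; ch < C; ++ch) {
        const double* xp = xs + (size_t)ch * H * W;
        double* dxp = dxs + (size_t)ch * H * W;
        const double w00 = w(0 + 4 * ch, oc), w10 = w(1 + 4 * ch, oc);
        const double w01 = w(2 + 4 * ch, oc), w11 = w(3 + 4 * ch, oc);
        double g00 = 0, g10 = 0, g01 = 0, g11 = 0;
        for (int c = 0; c < W; ++c) {
          for (int r = 0; r < H; ++r) {
            const double v = xp[r + (size_t)c * H];
            const double* q = pl + 2 * r + (size_t)(2 * c) * Ho;
            g00 += v * q[0];
            g10 += v * q[1];
            g01 += v * q[Ho];
            g11 += v * q[Ho + 1];
            dxp[r + (size_t)c * H] +=
              w00 * q[0] + w10 * q[1] + w01 * q[Ho] + w11 * q[Ho + 1];
          }
        }
        dw(0 + 4 * ch, oc) += g00;
        dw(1 + 4 * ch, oc) += g10;
        dw(2 + 4 * ch, oc) += g01;
        dw(3 + 4 * ch, oc) += g11;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// per-channel mean and (population) variance over H, W and batch
// [[Rcpp::export(name = ".channel_stats")]]
List channel_stats(NumericVector x) {
  IntegerVector d;
  check_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t plane = (size_t)H * W;
  NumericVector mean(C), var(C);
  for (int ch = 0; ch < C; ++ch) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + ((size_t)n * C + ch) * plane;
      for (size_t j = 0; j < plane; ++j) { s += p[j]; s2 += p[j] * p[j]; }
    }
    const double m = s / (plane * N);
    mean[ch] = m;
    double v = s2 / (plane * N) - m * m;
    var[ch] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// y = gamma * (x - mu) * inv + beta, per channel
// [[Rcpp::export(name = ".bn_apply")]]
NumericVector bn_apply(NumericVector x, NumericVector gamma,
                       NumericVector beta, NumericVector mu,
                       NumericVector inv) {
  IntegerVector d;
  check_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t plane = (size_t)H * W;
  NumericVector y((size_t)H * W * C * N);
  y.attr("dim") = d;
  for (int n = 0; n < N; ++n) {
    for (int ch = 0; ch < C; ++ch) {
      const double g = gamma[ch] * inv[ch];
      const double b = beta[ch] - gamma[ch] * inv[ch] * mu[ch];
      const double* p = x.begin() + ((size_t)n * C + ch) * plane;
      double* q = y.begin() + ((size_t)n * C + ch) * plane;
      for (size_t j = 0; j < plane; ++j) q[j] = g * p[j] + b;
    }
  }
  return y;
}

// batch-norm backward (training statistics)
// [[Rcpp::export(name = ".bn_bw")]]
List bn_bw(NumericVector x, NumericVector dy, NumericVector gamma,
           NumericVector mu, NumericVector inv) {
  IntegerVector d;
  check_dims4(x, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t plane = (size_t)H * W;
  const double m = (double)plane * N;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = d;
  NumericVector dgamma(C), dbeta(C);
  for (int ch = 0; ch < C; ++ch) {
    double s1 = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + ((size_t)n * C + ch) * plane;
      const double* pd = dy.begin() + ((size_t)n * C + ch) * plane;
      for (size_t j = 0; j < plane; ++j) {
        const double xh = (px[j] - mu[ch]) * inv[ch];
        s1 += pd[j];
        s2 += pd[j] * xh;
      }
    }
    dbeta[ch] = s1;
    dgamma[ch] = s2;
    const double gi = gamma[ch] * inv[ch];
    const double c1 = s1 / m, c2 = s2 / m;
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + ((size_t)n * C + ch) * plane;
      const double* pd = dy.begin() + ((size_t)n * C + ch) * plane;
      double* pq = dx.begin() + ((size_t)n * C + ch) * plane;
      for (size_t j = 0; j < plane; ++j) {
        const double xh = (px[j] - mu[ch]) * inv[ch];
        pq[j] = gi * (pd[j] - c1 - xh * c2);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// [[Rcpp::export(name = ".relu_fw")]]
NumericVector relu_fw(NumericVector x) {
  NumericVector y(clone(x));
  for (double& v : y) if (v < 0) v = 0;
  return y;
}

// dy where pre > 0, else 0
// [[Rcpp::export(name = ".relu_bw")]]
NumericVector relu_bw(NumericVector dy, NumericVector pre) {
  NumericVector dx(clone(dy));
  for (R_xlen_t i = 0; i < dx.size(); ++i) if (pre[i] <= 0) dx[i] = 0;
  return dx;
}

// weighted softmax cross-entropy over H x W x C x N logits with 0-based
// integer labels (H x W x N); returns mean loss and optionally dlogits
// [[Rcpp::export(name = ".wce_loss")]]
List wce_loss(NumericVector logits, IntegerVector truth, NumericVector w,
              bool grad) {
  IntegerVector d;
  check_dims4(logits, d);
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const size_t plane = (size_t)H * W;
  const double npix = (double)plane * N;
  NumericVector dlog;
  if (grad) {
    dlog = NumericVector((size_t)H * W * C * N);
    dlog.attr("dim") = d;
  }
  std::vector<double> z(C), p(C);
  double loss = 0;
  for (int n = 0; n < N; ++n) {
    const double* base = logits.begin() + (size_t)n * C * plane;
    double* dbase = grad ? dlog.begin() + (size_t)n * C * plane : nullptr;
    const int* lb = truth.begin() + (size_t)n * plane;
    for (size_t j = 0; j < plane; ++j) {
      double mx = base[j];
      for (int c = 1; c < C; ++c) {
        const double v = base[j + c * plane];
        if (v > mx) mx = v;
      }
      double s = 0;
      for (int c = 0; c < C; ++c) {
        z[c] = std::exp(base[j + c * plane] - mx);
        s += z[c];
      }
      const int lab = lb[j];
      if (lab < 0 || lab >= C) stop("truth labels must lie in 0..C-1");
      const double wl = w[lab];
      const double pl = z[lab] / s;
      // floor the probability but let NaN propagate so the trainer aborts
      const double pv = ISNAN(pl) ? pl : (pl > 1e-300 ? pl : 1e-300);
      loss += -wl * std::log(pv);
      if (grad) {
        for (int c = 0; c < C; ++c) {
          double g = z[c] / s;
          if (c == lab) g -= 1.0;
          dbase[j + c * plane] = wl * g / npix;
        }
      }
    }
  }
  loss /= npix;
  if (grad) return List::create(_["loss"] = loss, _["dlogits"] = dlog);
  return List::create(_["loss"] = loss);
}
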