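#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Tensors are R arrays in (H, W, C, N) layout, column-major, so the linear
// index of x[h, w, c, n] is h + H*(w + W*(c + C*n)). Convolutions are "same"
// padding, stride 1, odd kernel. Weights are (k, k, Cin, Cout); flattening the
// first three dims row index q = kh + k*kw + k*k*ci matches the im2col column
// order below, so a single GEMM per sample does the convolution.

static NumericVector alloc4(int a, int b, int c, int d) {
  NumericVector v((R_xlen_t)a * b * c * d);
  v.attr("dim") = IntegerVector::create(a, b, c, d);
  return v;
}

template <typename MT>
static void im2col_into(const double* xn, int H, int W, int C, int k,
                        MT& M, size_t row0) {
  const int pad = (k - 1) / 2, HW = H * W, kk = k * k;
  for (int c = 0; c < C; ++c) {
    const double* xc = xn + (size_t)c * HW;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int q = kh + k * kw + kk * c;
        auto* col = M.colptr(q) + row0;
        for (int w = 0; w < W; ++w) {
          const int ws = w + kw - pad;
          if (ws < 0 || ws >= W) {
            std::fill(col + (size_t)w * H, col + (size_t)w * H + H, 0.0);
            continue;
          }
          const double* src = xc + (size_t)ws * H;
          auto* dst = col + (size_t)w * H;
          for (int h = 0; h < H; ++h) {
            const int hs = h + kh - pad;
            dst[h] = (hs < 0 || hs >= H) ? 0.0 : src[hs];
          }
        }
      }
    }
  }
}

template <typename MT>
static void col2im_acc_from(const MT& M, double* dxn, int H, int W,
                            int C, int k, size_t row0) {
  const int pad = (k - 1) / 2, HW = H * W, kk = k * k;
  for (int c = 0; c < C; ++c) {
    double* dxc = dxn + (size_t)c * HW;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int q = kh + k * kw + kk * c;
        const auto* col = M.colptr(q) + row0;
        for (int w = 0; w < W; ++w) {
          const int ws = w + kw - pad;
          if (ws < 0 || ws >= W) continue;
          double* dst = dxc + (size_t)ws * H;
          const auto* src = col + (size_t)w * H;
          for (int h = 0; h < H; ++h) {
            const int hs = h + kh - pad;
            if (hs >= 0 && hs < H) dst[hs] += src[h];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  if (wd[2] != C) stop("conv: input channels (%d) do not match kernel (%d)", C, (int)wd[2]);
  const size_t HW = (size_t)H * W;
  // single precision inside the GEMMs: training tolerates it and OpenBLAS
  // sgemm is roughly twice as fast as dgemm
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(
    arma::mat(const_cast<double*>(w.begin()), (size_t)k * k * C, Cout, false, true));
  arma::frowvec bv = arma::conv_to<arma::frowvec>::from(
    arma::rowvec(const_cast<double*>(b.begin()), Cout, false, true));
  NumericVector out = alloc4(H, W, Cout, N);
  // batch samples share one im2col GEMM, chunked to keep the buffer small
  const size_t cols = (size_t)k * k * C;
  int chunk = (int)std::max((size_t)1, (size_t)(4 << 20) / (HW * cols * 4) + 1);
  chunk = std::min(chunk, N);
  for (int n0 = 0; n0 < N; n0 += chunk) {
    const int nb = std::min(chunk, N - n0);
    arma::fmat M((size_t)nb * HW, cols);
    for (int n = 0; n < nb; ++n)
      im2col_into(x.begin() + (size_t)(n0 + n) * HW * C, H, W, C, k, M, (size_t)n * HW);
    arma::fmat O = M * Wm;
    O.each_row() += bv;
    for (int n = 0; n < nb; ++n)
      for (int c = 0; c < Cout; ++c)
        std::copy(O.colptr(c) + (size_t)n * HW, O.colptr(c) + (size_t)(n + 1) * HW,
                  out.begin() + ((size_t)(n0 + n) * Cout + c) * HW);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dout) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int k = wd[0], Cout = wd[3];
  const size_t HW = (size_t)H * W;
  arma::fmat Wm = arma::conv_to<arma::fmat>::from(
    arma::mat(const_cast<double*>(w.begin()), (size_t)k * k * C, Cout, false, true));
  NumericVector dx = alloc4(H, W, C, N);
  NumericVector dw = alloc4(k, k, C, Cout);
  NumericVector db(Cout);
  const size_t cols = (size_t)k * k * C;
  arma::fmat dWf(cols, Cout, arma::fill::zeros);
  arma::frowvec dbf(Cout, arma::fill::zeros);
  int chunk = (int)std::max((size_t)1, (size_t)(4 << 20) / (HW * cols * 4) + 1);
  chunk = std::min(chunk, N);
  for (int n0 = 0; n0 < N; n0 += chunk) {
    const int nb = std::min(chunk, N - n0);
    arma::fmat M((size_t)nb * HW, cols);
    arma::fmat dO((size_t)nb * HW, Cout);
    for (int n = 0; n < nb; ++n) {
      im2col_into(x.begin() + (size_t)(n0 + n) * HW * C, H, W, C, k, M, (size_t)n * HW);
      for (int c = 0; c < Cout; ++c) {
        const double* src = dout.begin() + ((size_t)(n0 + n) * Cout + c) * HW;
        float* dst = dO.colptr(c) + (size_t)n * HW;
        for (size_t i = 0; i < HW; ++i) dst[i] = (float)src[i];
      }
    }
    dWf += M.t() * dO;
    dbf += arma::sum(dO, 0);
    arma::fmat dM = dO * Wm.t();
    for (int n = 0; n < nb; ++n)
      col2im_acc_from(dM, dx.begin() + (size_t)(n0 + n) * HW * C, H, W, C, k, (size_t)n * HW);
  }
  std::copy(dWf.begin(), dWf.end(), dw.begin());
  std::copy(dbf.begin(), dbf.end(), db.begin());
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, int f) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  if (H % f || W % f) stop("maxpool: spatial dims must be divisible by the pool factor");
  const int Ho = H / f, Wo = W / f;
  NumericVector out = alloc4(Ho, Wo, C, N);
  IntegerVector arg(out.size());
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -std::numeric_limits<double>::infinity();
          size_t bi = 0;
          for (int dw2 = 0; dw2 < f; ++dw2)
            for (int dh = 0; dh < f; ++dh) {
              const size_t idx = base + (size_t)(wo * f + dw2) * H + ho * f + dh;
              if (x[idx] > best) { best = x[idx]; bi = idx; }
            }
          out[o] = best;
          arg[o] = (int)bi;
          ++o;
        }
    }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector argmax, NumericVector dout, IntegerVector xdim) {
  NumericVector dx = alloc4(xdim[0], xdim[1], xdim[2], xdim[3]);
  for (R_xlen_t i = 0; i < dout.size(); ++i) dx[argmax[i]] += dout[i];
  return dx;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_fwd(NumericVector x, int f) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H * f, Wo = W * f;
  NumericVector out = alloc4(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bi = ((size_t)n * C + c) * H * W;
      const size_t bo = ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          const double v = x[bi + (size_t)w * H + h];
          for (int dw2 = 0; dw2 < f; ++dw2) {
            double* dst = out.begin() + bo + (size_t)(w * f + dw2) * Ho + (size_t)h * f;
            std::fill(dst, dst + f, v);
          }
        }
    }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_upsample_bwd(NumericVector dout, int f) {
  IntegerVector od = dout.attr("dim");
  const int Ho = od[0], Wo = od[1], C = od[2], N = od[3];
  const int H = Ho / f, W = Wo / f;
  NumericVector dx = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t bi = ((size_t)n * C + c) * H * W;
      const size_t bo = ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h) {
          double s = 0.0;
          for (int dw2 = 0; dw2 < f; ++dw2) {
            const double* src = dout.begin() + bo + (size_t)(w * f + dw2) * Ho + (size_t)h * f;
            for (int dh = 0; dh < f; ++dh) s += src[dh];
          }
          dx[bi + (size_t)w * H + h] = s;
        }
    }
  return dx;
}

// Connected-component labelling with selectable 4/8 connectivity. Labels are
// assigned in raster order of each component's first-visited pixel, which the
// R side relies on only through areas; tie-breaking is done in R.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int>> stack;
  const int d4r[] = {-1, 1, 0, 0}, d4c[] = {0, 0, -1, 1};
  const int d8r[] = {-1, 1, 0, 0, -1, -1, 1, 1}, d8c[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = (connectivity == 8) ? d8r : d4r;
  const int* dc = (connectivity == 8) ? d8c : d4c;
  const int nd = (connectivity == 8) ? 8 : 4;
  int next = 0;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.push_back({r, c});
      lab(r, c) = next;
      while (!stack.empty()) {
        auto p = stack.back();
        stack.pop_back();
        for (int i = 0; i < nd; ++i) {
          const int rr = p.first + dr[i], cc = p.second + dc[i];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back({rr, cc});
          }
        }
      }
    }
  return lab;
}
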