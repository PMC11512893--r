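#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Layout conventions: a single sample is an (H, W, C) column-major array;
// im2col produces a (kh*kw*C) x (OH*OW) matrix whose row index runs fastest
// over ki, then kj, then c, matching matrix(w, kh*kw*C, OC) for a weight
// array of dim (kh, kw, C, OC).

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int C,
                         int kh, int kw, int sh, int sw,
                         int ph, int pw, int dh, int dw) {
  const int OH = (H + 2 * ph - dh * (kh - 1) - 1) / sh + 1;
  const int OW = (W + 2 * pw - dw * (kw - 1) - 1) / sw + 1;
  NumericMatrix out(kh * kw * C, OH * OW);
  const double *px = x.begin();
  for (int oj = 0; oj < OW; ++oj) {
    for (int oi = 0; oi < OH; ++oi) {
      const int col = oi + OH * oj;
      double *pcol = &out(0, col);
      for (int c = 0; c < C; ++c) {
        const double *plane = px + (size_t)c * H * W;
        for (int kj = 0; kj < kw; ++kj) {
          const int wj = oj * sw - pw + kj * dw;
          for (int ki = 0; ki < kh; ++ki) {
            const int wi = oi * sh - ph + ki * dh;
            double v = 0.0;
            if (wi >= 0 && wi < H && wj >= 0 && wj < W)
              v = plane[wi + (size_t)wj * H];
            pcol[ki + kh * (kj + kw * c)] = v;
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add of a column matrix back onto an (H, W, C) array; adjoint of
// cpp_im2col and also the core of the transposed convolution forward pass.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int sh, int sw,
                         int ph, int pw, int dh, int dw) {
  const int OH = (H + 2 * ph - dh * (kh - 1) - 1) / sh + 1;
  const int OW = (W + 2 * pw - dw * (kw - 1) - 1) / sw + 1;
  NumericVector x((size_t)H * W * C);
  double *px = x.begin();
  for (int oj = 0; oj < OW; ++oj) {
    for (int oi = 0; oi < OH; ++oi) {
      const int col = oi + OH * oj;
      const double *pcol = &cols(0, col);
      for (int c = 0; c < C; ++c) {
        double *plane = px + (size_t)c * H * W;
        for (int kj = 0; kj < kw; ++kj) {
          const int wj = oj * sw - pw + kj * dw;
          for (int ki = 0; ki < kh; ++ki) {
            const int wi = oi * sh - ph + ki * dh;
            if (wi >= 0 && wi < H && wj >= 0 && wj < W)
              plane[wi + (size_t)wj * H] += pcol[ki + kh * (kj + kw * c)];
          }
        }
      }
    }
  }
  return x;
}

// Max pooling on one (H, W, C) sample.  Returns the pooled values and the
// 0-based linear index (into the input array) of each selected element, so
// the decoder can unpool into the exact argmax positions.
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int H, int W, int C,
                 int kh, int kw, int sh, int sw) {
  const int OH = (H - kh) / sh + 1;
  const int OW = (W - kw) / sw + 1;
  NumericVector out((size_t)OH * OW * C);
  IntegerVector idx((size_t)OH * OW * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double *plane = px + (size_t)c * H * W;
    for (int oj = 0; oj < OW; ++oj) {
      for (int oi = 0; oi < OH; ++oi) {
        double best = R_NegInf;
        int besti = 0;
        for (int kj = 0; kj < kw; ++kj) {
          const int wj = oj * sw + kj;
          for (int ki = 0; ki < kh; ++ki) {
            const int wi = oi * sh + ki;
            const double v = plane[wi + (size_t)wj * H];
            if (v > best) { best = v; besti = wi + wj * H; }
          }
        }
        const size_t o = oi + (size_t)OH * (oj + (size_t)OW * c);
        out[o] = best;
        idx[o] = besti + c * H * W;
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx,
                      _["oh"] = OH, _["ow"] = OW);
}

// Accumulating scatter for the pooling backward pass (safe under ties /
// overlapping windows).
// [[Rcpp::export]]
NumericVector cpp_scatter_add(NumericVector grad_out, IntegerVector idx,
                              int n_in) {
  NumericVector gx(n_in);
  for (R_xlen_t i = 0; i < grad_out.size(); ++i)
    gx[idx[i]] += grad_out[i];
  return gx;
}

// Median filter with edge replication; win is odd.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix x, int win) {
  const int H = x.nrow(), W = x.ncol(), r = win / 2;
  NumericMatrix out(H, W);
  std::vector<double> buf((size_t)win * win);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      size_t n = 0;
      for (int dj = -r; dj <= r; ++dj) {
        int cj = std::min(std::max(j + dj, 0), W - 1);
        for (int di = -r; di <= r; ++di) {
          int ci = std::min(std::max(i + di, 0), H - 1);
          buf[n++] = x(ci, cj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.begin() + n);
      out(i, j) = buf[n / 2];
    }
  }
  return out;
}
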