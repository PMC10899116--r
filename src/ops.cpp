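#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Layout conventions shared with the R side:
//  - feature maps are R arrays dim (H, W, C), column-major (row index fastest);
//  - im2col rows index output pixels as ho + Ho*wo (ho fastest, matching R);
//  - im2col columns index the receptive field as kh + k*kw + k*k*c, matching
//    `dim(W) <- c(k*k*Cin, Cout)` on a weight array of dim (k, k, Cin, Cout).

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericMatrix col(Ho * Wo, k * k * C);
  const double *px = x.begin();
  for (int c = 0; c < C; ++c) {
    const double *plane = px + (R_xlen_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int j = kh + k * kw + k * k * c;
        double *pc = &col(0, j);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          const double *src = plane + (R_xlen_t)wi * H;
          double *dst = pc + (R_xlen_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            dst[ho] = src[hi];
          }
        }
      }
    }
  }
  return col;
}

// Scatter-add of a column gradient back onto the input grid (adjoint of im2col).
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix col, int H, int W, int C, int k,
                         int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector out((R_xlen_t)H * W * C);
  out.attr("dim") = IntegerVector::create(H, W, C);
  double *po = out.begin();
  for (int c = 0; c < C; ++c) {
    double *plane = po + (R_xlen_t)c * H * W;
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int j = kh + k * kw + k * k * c;
        const double *pc = &col(0, j);
        for (int wo = 0; wo < Wo; ++wo) {
          const int wi = wo * stride - pad + kw;
          if (wi < 0 || wi >= W) continue;
          double *dst = plane + (R_xlen_t)wi * H;
          const double *src = pc + (R_xlen_t)wo * Ho;
          for (int ho = 0; ho < Ho; ++ho) {
            const int hi = ho * stride - pad + kh;
            if (hi < 0 || hi >= H) continue;
            dst[hi] += src[ho];
          }
        }
      }
    }
  }
  return out;
}

// Connected components of a binary mask (nonzero = foreground), 4- or
// 8-connectivity, labels 1..K in scan order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  const int dh4[] = {-1, 1, 0, 0};
  const int dw4[] = {0, 0, -1, 1};
  const int dh8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dw8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int ndir = (connectivity == 8) ? 8 : 4;
  const int *dh = (connectivity == 8) ? dh8 : dh4;
  const int *dw = (connectivity == 8) ? dw8 : dw4;
  std::queue<std::pair<int, int> > q;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      if (mask(h, w) == 0 || lab(h, w) != 0) continue;
      lab(h, w) = ++next;
      q.push(std::make_pair(h, w));
      while (!q.empty()) {
        int ch = q.front().first, cw = q.front().second;
        q.pop();
        for (int t = 0; t < ndir; ++t) {
          int nh = ch + dh[t], nw = cw + dw[t];
          if (nh < 0 || nh >= H || nw < 0 || nw >= W) continue;
          if (mask(nh, nw) == 0 || lab(nh, nw) != 0) continue;
          lab(nh, nw) = next;
          q.push(std::make_pair(nh, nw));
        }
      }
    }
  }
  return lab;
}

// Per-block majority label over f x f blocks (edge blocks may be partial);
// ties resolved in favor of the lowest label index. Labels in 0..(nclass-1).
// [[Rcpp::export]]
IntegerMatrix cpp_block_mode(IntegerMatrix lab, int f, int nclass) {
  const int H = lab.nrow(), W = lab.ncol();
  const int Ho = (H + f - 1) / f, Wo = (W + f - 1) / f;
  IntegerMatrix out(Ho, Wo);
  std::vector<int> cnt(nclass);
  for (int bw = 0; bw < Wo; ++bw) {
    for (int bh = 0; bh < Ho; ++bh) {
      std::fill(cnt.begin(), cnt.end(), 0);
      const int h1 = bh * f, h2 = std::min(H, h1 + f);
      const int w1 = bw * f, w2 = std::min(W, w1 + f);
      for (int w = w1; w < w2; ++w)
        for (int h = h1; h < h2; ++h)
          ++cnt[lab(h, w)];
      int best = 0;
      for (int c = 1; c < nclass; ++c)
        if (cnt[c] > cnt[best]) best = c;
      out(bh, bw) = best;
    }
  }
  return out;
}

// Per-class pixel counts of an integer label matrix (labels 0..nclass-1).
// [[Rcpp::export]]
IntegerVector cpp_class_counts(IntegerMatrix lab, int nclass) {
  IntegerVector cnt(nclass);
  const int n = lab.nrow() * lab.ncol();
  const int *p = lab.begin();
  for (int i = 0; i < n; ++i) ++cnt[p[i]];
  return cnt;
}
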