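#include <Rcpp.h>
using namespace Rcpp;

// 3x3, pad-1, stride-1 convolution support. Feature maps are stored
// channel-fastest: an array with dim c(C, H, W) (column-major), so element
// (ch, r, c) sits at ch + C*(r + H*c). Patch matrices are (C*9) x (H*W) with
// row order ch fastest, then dr, then dc, and column order r fastest.

// [[Rcpp::export]]
NumericMatrix im2col3(NumericVector x, int C, int H, int W) {
  NumericMatrix out(C * 9, H * W);
  const double* px = x.begin();
  double* po = out.begin();
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double* col = po + (std::size_t)(c * H + r) * (C * 9);
      int k = 0;
      for (int dc = -1; dc <= 1; ++dc) {
        int cc = c + dc;
        for (int dr = -1; dr <= 1; ++dr) {
          int rr = r + dr;
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) {
            for (int ch = 0; ch < C; ++ch) col[k++] = 0.0;
          } else {
            const double* src = px + (std::size_t)(cc * H + rr) * C;
            for (int ch = 0; ch < C; ++ch) col[k++] = src[ch];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im3(NumericMatrix dcols, int C, int H, int W) {
  NumericVector out((std::size_t)C * H * W);
  double* po = out.begin();
  const double* pd = dcols.begin();
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const double* col = pd + (std::size_t)(c * H + r) * (C * 9);
      int k = 0;
      for (int dc = -1; dc <= 1; ++dc) {
        int cc = c + dc;
        for (int dr = -1; dr <= 1; ++dr) {
          int rr = r + dr;
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) {
            k += C;
          } else {
            double* dst = po + (std::size_t)(cc * H + rr) * C;
            for (int ch = 0; ch < C; ++ch) dst[ch] += col[k++];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(C, H, W);
  return out;
}
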