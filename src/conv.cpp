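#include <Rcpp.h>
using namespace Rcpp;

// 2-D convolution (cross-correlation) over an H x W x C array.
// weights: kh x kw x C x OC, column-major as passed from R.
// Asymmetric zero padding supported so even kernels can preserve size.
// [[Rcpp::export]]
NumericVector conv2d_hwc(const NumericVector& input, const IntegerVector& dimIn,
                         const NumericVector& weights, const IntegerVector& dimW,
                         const NumericVector& bias,
                         int padTop, int padLeft, int padBottom, int padRight,
                         int stride) {
  const int H = dimIn[0], W = dimIn[1], C = dimIn[2];
  const int kh = dimW[0], kw = dimW[1], Cw = dimW[2], OC = dimW[3];
  if (Cw != C) stop("channel mismatch: input has %d, kernel expects %d", C, Cw);
  const int Hp = H + padTop + padBottom, Wp = W + padLeft + padRight;
  if (Hp < kh || Wp < kw) stop("kernel larger than padded input");
  const int Ho = (Hp - kh) / stride + 1;
  const int Wo = (Wp - kw) / stride + 1;

  NumericVector out(Ho * (R_xlen_t)Wo * OC);
  const double* in = input.begin();
  const double* w = weights.begin();
  double* o = out.begin();

  for (int oc = 0; oc < OC; ++oc) {
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        double acc = bias[oc];
        const int h0 = oh * stride - padTop;
        const int w0 = ow * stride - padLeft;
        for (int c = 0; c < C; ++c) {
          for (int j = 0; j < kw; ++j) {
            const int wi = w0 + j;
            if (wi < 0 || wi >= W) continue;
            for (int i = 0; i < kh; ++i) {
              const int hi = h0 + i;
              if (hi < 0 || hi >= H) continue;
              acc += in[hi + H * (wi + (R_xlen_t)W * c)] *
                     w[i + kh * (j + kw * (c + (R_xlen_t)C * oc))];
            }
          }
        }
        o[oh + Ho * (ow + (R_xlen_t)Wo * oc)] = acc;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, OC);
  return out;
}

// Max pooling over an H x W x C array, square kernel, no padding.
// [[Rcpp::export]]
NumericVector maxpool_hwc(const NumericVector& input, const IntegerVector& dimIn,
                          int kernel, int stride) {
  const int H = dimIn[0], W = dimIn[1], C = dimIn[2];
  if (kernel > H || kernel > W) stop("pooling kernel larger than input");
  const int Ho = (H - kernel) / stride + 1;
  const int Wo = (W - kernel) / stride + 1;
  NumericVector out(Ho * (R_xlen_t)Wo * C);
  const double* in = input.begin();
  double* o = out.begin();
  for (int c = 0; c < C; ++c) {
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        double m = R_NegInf;
        for (int j = 0; j < kernel; ++j) {
          const int wi = ow * stride + j;
          for (int i = 0; i < kernel; ++i) {
            const double v = in[(oh * stride + i) + H * (wi + (R_xlen_t)W * c)];
            if (v > m) m = v;
          }
        }
        o[oh + Ho * (ow + (R_xlen_t)Wo * c)] = m;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return out;
}
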