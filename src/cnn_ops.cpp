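#include <Rcpp.h>
using namespace Rcpp;

// Generic valid (no padding, stride 1) cross-correlation of a C x H x W
// input with K kernels of size C x kh x kw, optional ReLU.
// input dim = (C, H, W); kernels dim = (K, C, kh, kw); output (K, H', W').
// [[Rcpp::export(name = ".conv_forward_cpp")]]
NumericVector conv_forward_cpp(NumericVector input, NumericVector kernels,
                               NumericVector bias, bool relu) {
  IntegerVector di = input.attr("dim");
  IntegerVector dk = kernels.attr("dim");
  if (di.size() != 3 || dk.size() != 4)
    stop("input must be a 3-d array and kernels a 4-d array");
  const int C = di[0], H = di[1], W = di[2];
  const int K = dk[0], Ck = dk[1], kh = dk[2], kw = dk[3];
  if (Ck != C) stop("kernel channel count does not match input");
  if (kh > H || kw > W) stop("kernel larger than input");
  const int Ho = H - kh + 1, Wo = W - kw + 1;

  NumericVector out(K * Ho * Wo);
  out.attr("dim") = IntegerVector::create(K, Ho, Wo);
  for (int j = 0; j < Wo; ++j)
    for (int i = 0; i < Ho; ++i)
      for (int k = 0; k < K; ++k) {
        double s = bias[k];
        for (int y = 0; y < kw; ++y)
          for (int x = 0; x < kh; ++x)
            for (int c = 0; c < C; ++c)
              s += kernels[k + K * (c + C * (x + kh * y))] *
                   input[c + C * ((i + x) + H * (j + y))];
        if (relu && s < 0) s = 0;
        out[k + K * (i + Ho * j)] = s;
      }
  return out;
}

// Max pooling over non-overlapping ph x pw windows (stride = window);
// trailing rows/columns not filling a window are dropped.
// [[Rcpp::export(name = ".maxpool_forward_cpp")]]
NumericVector maxpool_forward_cpp(NumericVector input, int ph, int pw) {
  IntegerVector di = input.attr("dim");
  if (di.size() != 3) stop("input must be a 3-d array");
  const int C = di[0], H = di[1], W = di[2];
  const int Ho = H / ph, Wo = W / pw;
  if (Ho < 1 || Wo < 1) stop("pooling window larger than input");

  NumericVector out(C * Ho * Wo);
  out.attr("dim") = IntegerVector::create(C, Ho, Wo);
  for (int j = 0; j < Wo; ++j)
    for (int i = 0; i < Ho; ++i)
      for (int c = 0; c < C; ++c) {
        double m = R_NegInf;
        for (int y = 0; y < pw; ++y)
          for (int x = 0; x < ph; ++x) {
            double v = input[c + C * ((i * ph + x) + H * (j * pw + y))];
            if (v > m) m = v;
          }
        out[c + C * (i + Ho * j)] = m;
      }
  return out;
}
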