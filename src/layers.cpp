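#include <Rcpp.h>
using namespace Rcpp;

// Feature maps are column-major R arrays dim (H, W, C); kernel banks are
// dim (kh, kw, Cin, Cout).  All loops are plain nested index arithmetic so
// the code stays a line-by-line transcription of the layer definitions; the
// R-side nested-loop oracle used in the tests is the independent reference.

static inline int idx3(int h, int w, int c, int H, int W) {
  return h + H * (w + W * c);
}

// [[Rcpp::export(name = ".conv_forward_cpp")]]
NumericVector conv_forward_cpp(NumericVector input, NumericVector kernels,
                               NumericVector bias, int stride) {
  IntegerVector din = input.attr("dim");
  IntegerVector dk = kernels.attr("dim");
  const int H = din[0], W = din[1], Cin = din[2];
  const int kh = dk[0], kw = dk[1], KCin = dk[2], Cout = dk[3];
  if (KCin != Cin) stop("kernel in_channels != input channels");
  const int Ho = (H - kh) / stride + 1;
  const int Wo = (W - kw) / stride + 1;
  NumericVector out(Ho * Wo * Cout);
  const double *pin = REAL(input), *pker = REAL(kernels), *pb = REAL(bias);
  double *pout = REAL(out);
  for (int co = 0; co < Cout; ++co) {
    const double b = pb[co];
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double acc = b;
        const int h0 = ho * stride, w0 = wo * stride;
        for (int ci = 0; ci < Cin; ++ci) {
          const double *kbase = pker + kh * kw * (ci + Cin * co);
          for (int j = 0; j < kw; ++j) {
            const double *icol = pin + idx3(h0, w0 + j, ci, H, W);
            const double *kcol = kbase + j * kh;
            for (int i = 0; i < kh; ++i) acc += icol[i] * kcol[i];
          }
        }
        pout[idx3(ho, wo, co, Ho, Wo)] = acc;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout);
  return out;
}

// [[Rcpp::export(name = ".conv_backward_cpp")]]
List conv_backward_cpp(NumericVector dout, NumericVector input,
                       NumericVector kernels, int stride) {
  IntegerVector din = input.attr("dim");
  IntegerVector dk = kernels.attr("dim");
  IntegerVector ddo = dout.attr("dim");
  const int H = din[0], W = din[1], Cin = din[2];
  const int kh = dk[0], kw = dk[1], Cout = dk[3];
  const int Ho = ddo[0], Wo = ddo[1];
  NumericVector dinput(H * W * Cin);
  NumericVector dkernels(kh * kw * Cin * Cout);
  NumericVector dbias(Cout);
  const double *pin = REAL(input), *pker = REAL(kernels), *pdo = REAL(dout);
  double *pdi = REAL(dinput), *pdk = REAL(dkernels), *pdb = REAL(dbias);
  for (int co = 0; co < Cout; ++co) {
    double db = 0.0;
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double g = pdo[idx3(ho, wo, co, Ho, Wo)];
        if (g == 0.0) continue;
        db += g;
        const int h0 = ho * stride, w0 = wo * stride;
        for (int ci = 0; ci < Cin; ++ci) {
          const double *kbase = pker + kh * kw * (ci + Cin * co);
          double *dkbase = pdk + kh * kw * (ci + Cin * co);
          for (int j = 0; j < kw; ++j) {
            const int off = idx3(h0, w0 + j, ci, H, W);
            const double *icol = pin + off;
            const double *kcol = kbase + j * kh;
            double *dicol = pdi + off;
            double *dkcol = dkbase + j * kh;
            for (int i = 0; i < kh; ++i) {
              dicol[i] += g * kcol[i];
              dkcol[i] += g * icol[i];
            }
          }
        }
      }
    }
    pdb[co] += db;
  }
  dinput.attr("dim") = din;
  dkernels.attr("dim") = dk;
  return List::create(_["dinput"] = dinput, _["dkernels"] = dkernels,
                      _["dbias"] = dbias);
}

// 2x2 stride-2 max pooling; argmax stores the 1-based linear index into the
// input array so the backward pass can scatter gradients exactly.
// [[Rcpp::export(name = ".maxpool_forward_cpp")]]
List maxpool_forward_cpp(NumericVector input) {
  IntegerVector din = input.attr("dim");
  const int H = din[0], W = din[1], C = din[2];
  if (H % 2 != 0 || W % 2 != 0) stop("maxpool_forward: H and W must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out(Ho * Wo * C);
  IntegerVector argmax(Ho * Wo * C);
  const double *pin = REAL(input);
  double *pout = REAL(out);
  int *parg = INTEGER(argmax);
  for (int c = 0; c < C; ++c) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        // row-major window order (0,0),(0,1),(1,0),(1,1); ties keep the
        // first occurrence, which then receives the whole gradient
        int best = idx3(2 * ho, 2 * wo, c, H, W);
        double bv = pin[best];
        const int cand[3] = {idx3(2 * ho, 2 * wo + 1, c, H, W),
                             idx3(2 * ho + 1, 2 * wo, c, H, W),
                             idx3(2 * ho + 1, 2 * wo + 1, c, H, W)};
        for (int t = 0; t < 3; ++t) {
          if (pin[cand[t]] > bv) { bv = pin[cand[t]]; best = cand[t]; }
        }
        const int o = idx3(ho, wo, c, Ho, Wo);
        pout[o] = bv;
        parg[o] = best + 1;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, C);
  argmax.attr("dim") = IntegerVector::create(Ho, Wo, C);
  return List::create(_["output"] = out, _["argmax"] = argmax);
}

// [[Rcpp::export(name = ".maxpool_backward_cpp")]]
NumericVector maxpool_backward_cpp(NumericVector dout, IntegerVector argmax,
                                   IntegerVector input_dim) {
  const int n = input_dim[0] * input_dim[1] * input_dim[2];
  NumericVector dinput(n);
  const int m = dout.size();
  const double *pdo = REAL(dout);
  const int *parg = INTEGER(argmax);
  double *pdi = REAL(dinput);
  for (int i = 0; i < m; ++i) pdi[parg[i] - 1] += pdo[i];
  dinput.attr("dim") = input_dim;
  return dinput;
}
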