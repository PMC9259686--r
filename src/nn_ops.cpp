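// Hot inner loops of the CNN engine: direct 3x3 same-padded convolution
// (forward, and backward to input/weight/bias gradients) on H x W x B x C
// tensors. Weight matrices are (9 * C_in) x C_out with rows ordered
// (dx major, dy, then input channel), matching the R-side initializers.
// Everything else (pooling, optimization, losses) stays in R.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector conv3_fwd_cpp(NumericVector x, NumericMatrix W,
                            NumericVector bias, int H, int Wd, int B, int C) {
  const size_t HW = (size_t)H * Wd;
  const size_t HWB = HW * B;
  const int Cout = W.ncol();
  NumericVector y(HWB * Cout);
  double* yp = y.begin();
  const double* xp = x.begin();
  const double* wp = W.begin();
  const int wrows = W.nrow();

  for (int co = 0; co < Cout; ++co) {
    double* yo = yp + (size_t)co * HWB;
    const double bco = bias[co];
    for (size_t i = 0; i < HWB; ++i) yo[i] = bco;
    for (int dx = 0; dx <= 2; ++dx) {
      for (int dy = 0; dy <= 2; ++dy) {
        for (int ci = 0; ci < C; ++ci) {
          const double wv = wp[(size_t)co * wrows + ((dx * 3 + dy) * C + ci)];
          if (wv == 0.0) continue;
          const double* xi = xp + (size_t)ci * HWB;
          for (int b = 0; b < B; ++b) {
            for (int w = 0; w < Wd; ++w) {
              const int sw = w + dx - 1;
              if (sw < 0 || sw >= Wd) continue;
              double* yrow = yo + (size_t)b * HW + (size_t)w * H;
              const double* xrow = xi + (size_t)b * HW + (size_t)sw * H;
              const int h0 = (dy == 0) ? 1 : 0;      // sh = h + dy - 1
              const int h1 = (dy == 2) ? H - 1 : H;
              const int sh_off = dy - 1;
              for (int h = h0; h < h1; ++h) yrow[h] += wv * xrow[h + sh_off];
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(H, Wd, B, Cout);
  return y;
}

// [[Rcpp::export]]
List conv3_bwd_cpp(NumericVector dy, NumericVector x, NumericMatrix W,
                   int H, int Wd, int B, int C) {
  const size_t HW = (size_t)H * Wd;
  const size_t HWB = HW * B;
  const int Cout = W.ncol();
  const int wrows = W.nrow();
  NumericVector dx_(HWB * C);
  NumericMatrix dW(wrows, Cout);
  NumericVector db(Cout);
  const double* dyp = dy.begin();
  const double* xp = x.begin();
  const double* wp = W.begin();
  double* dxp = dx_.begin();
  double* dwp = dW.begin();

  for (int co = 0; co < Cout; ++co) {
    const double* dyo = dyp + (size_t)co * HWB;
    double acc = 0.0;
    for (size_t i = 0; i < HWB; ++i) acc += dyo[i];
    db[co] = acc;
    for (int dx = 0; dx <= 2; ++dx) {
      for (int dy_ = 0; dy_ <= 2; ++dy_) {
        for (int ci = 0; ci < C; ++ci) {
          const size_t widx = (size_t)co * wrows + ((dx * 3 + dy_) * C + ci);
          const double wv = wp[widx];
          const double* xi = xp + (size_t)ci * HWB;
          double* dxi = dxp + (size_t)ci * HWB;
          double wacc = 0.0;
          for (int b = 0; b < B; ++b) {
            for (int w = 0; w < Wd; ++w) {
              const int sw = w + dx - 1;
              if (sw < 0 || sw >= Wd) continue;
              const double* dyrow = dyo + (size_t)b * HW + (size_t)w * H;
              const double* xrow = xi + (size_t)b * HW + (size_t)sw * H;
              double* dxrow = dxi + (size_t)b * HW + (size_t)sw * H;
              const int h0 = (dy_ == 0) ? 1 : 0;
              const int h1 = (dy_ == 2) ? H - 1 : H;
              const int sh_off = dy_ - 1;
              for (int h = h0; h < h1; ++h) {
                const double g = dyrow[h];
                wacc += g * xrow[h + sh_off];
                dxrow[h + sh_off] += wv * g;
              }
            }
          }
          dwp[widx] = wacc;
        }
      }
    }
  }
  dx_.attr("dim") = IntegerVector::create(H, Wd, B, C);
  return List::create(Named("dx") = dx_, Named("dW") = dW, Named("db") = db);
}
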