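#include <Rcpp.h>
using namespace Rcpp;

// Hot accumulation loops, compiled with runtime ISA dispatch so AVX2 is
// used where the CPU supports it while the binary stays portable.
#if defined(__GNUC__) && defined(__x86_64__) && !defined(__clang__)
#define PPI_CLONES __attribute__((target_clones("avx2", "default")))
#else
#define PPI_CLONES
#endif

PPI_CLONES
static void axpy_q(double* __restrict__ y, const double* __restrict__ x,
                   const double a, const int n) {
  for (int q = 0; q < n; ++q) y[q] += a * x[q];
}

PPI_CLONES
static double dot_q(const double* __restrict__ x, const double* __restrict__ y,
                    const int n) {
  double acc = 0.0;
  for (int q = 0; q < n; ++q) acc += x[q] * y[q];
  return acc;
}

// Direct stride-1 valid convolution and max-pooling kernels for the
// pair-map classifier. No patch matrices are materialized: each sample's
// activation block is small enough to stay cache-resident, so the loops
// run at compute speed on one core.
//
// The convolution loops run in "extended" output coordinates: output
// position (i, j) is addressed as i + j*H (input row stride), so for a
// fixed kernel offset the whole accumulation is one long contiguous
// stride-1 loop; rows i >= Hout accumulate junk that the final
// compaction step never reads (and the backward passes zero-pad, so the
// junk positions contribute nothing).
//
// Layout conventions (matching the R side):
//  - activations: (H*W) x (C*B) matrix, channel fastest within a sample;
//  - conv weights: (k*k*Cin) x Cout matrix, kernel offset fastest within
//    an input channel; offset kk = di + dj*k (di row shift, dj column
//    shift);
//  - conv outputs: (Hout*Wout) x (Cout*B).

// [[Rcpp::export]]
NumericMatrix conv_fwd_cb(const NumericMatrix& X, const NumericMatrix& W,
                          const NumericVector& bias,
                          int H, int Wd, int k, int Cin, int Cout, int B) {
  const int Hout = H - k + 1, Wout = Wd - k + 1;
  const int npatch = Hout * Wout, k2 = k * k;
  const R_xlen_t HW = (R_xlen_t)H * Wd;
  const int Qlen = H * (Wout - 1) + Hout;      // extended output span
  NumericMatrix Y(npatch, (R_xlen_t)Cout * B);
  std::vector<double> yext(Qlen);
  const double* x = X.begin();
  const double* w = W.begin();
  double* y = Y.begin();
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < Cout; ++co) {
      std::fill(yext.begin(), yext.end(), 0.0);
      double* __restrict__ ye = yext.data();
      for (int c = 0; c < Cin; ++c) {
        const double* xb = x + ((R_xlen_t)b * Cin + c) * HW;
        const double* wc = w + (R_xlen_t)co * k2 * Cin + (R_xlen_t)c * k2;
        for (int kk = 0; kk < k2; ++kk) {
          const int s = (kk % k) + (kk / k) * H;
          axpy_q(ye, xb + s, wc[kk], Qlen);
        }
      }
      double* yp = y + ((R_xlen_t)b * Cout + co) * npatch;
      const double bco = bias[co];
      for (int j = 0; j < Wout; ++j)
        for (int i = 0; i < Hout; ++i)
          yp[i + j * Hout] = ye[i + j * H] + bco;
    }
  }
  return Y;
}

// [[Rcpp::export]]
List conv_grad_cb(const NumericMatrix& X, const NumericMatrix& dY,
                  int H, int Wd, int k, int Cin, int Cout, int B) {
  const int Hout = H - k + 1, Wout = Wd - k + 1;
  const int npatch = Hout * Wout, k2 = k * k;
  const R_xlen_t HW = (R_xlen_t)H * Wd;
  const int Qlen = H * (Wout - 1) + Hout;
  NumericMatrix dW((R_xlen_t)k2 * Cin, Cout);
  NumericVector db(Cout);
  std::vector<double> dyext(Qlen);
  const double* x = X.begin();
  const double* dy = dY.begin();
  double* dw = dW.begin();
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < Cout; ++co) {
      const double* dyp = dy + ((R_xlen_t)b * Cout + co) * npatch;
      std::fill(dyext.begin(), dyext.end(), 0.0);
      double acc_b = 0.0;
      for (int j = 0; j < Wout; ++j)
        for (int i = 0; i < Hout; ++i) {
          const double v = dyp[i + j * Hout];
          dyext[i + j * H] = v;
          acc_b += v;
        }
      db[co] += acc_b;
      const double* __restrict__ de = dyext.data();
      for (int c = 0; c < Cin; ++c) {
        const double* xb = x + ((R_xlen_t)b * Cin + c) * HW;
        double* dwc = dw + (R_xlen_t)co * k2 * Cin + (R_xlen_t)c * k2;
        for (int kk = 0; kk < k2; ++kk) {
          const int s = (kk % k) + (kk / k) * H;
          dwc[kk] += dot_q(xb + s, de, Qlen);
        }
      }
    }
  }
  return List::create(_["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
NumericMatrix conv_dx_cb(const NumericMatrix& dY, const NumericMatrix& W,
                         int H, int Wd, int k, int Cin, int Cout, int B) {
  const int Hout = H - k + 1, Wout = Wd - k + 1;
  const int npatch = Hout * Wout, k2 = k * k;
  const R_xlen_t HW = (R_xlen_t)H * Wd;
  const int Qlen = H * (Wout - 1) + Hout;
  NumericMatrix dX(HW, (R_xlen_t)Cin * B);
  std::vector<double> dyext(Qlen);
  const double* dy = dY.begin();
  const double* w = W.begin();
  double* dx = dX.begin();
  for (int b = 0; b < B; ++b) {
    for (int co = 0; co < Cout; ++co) {
      const double* dyp = dy + ((R_xlen_t)b * Cout + co) * npatch;
      std::fill(dyext.begin(), dyext.end(), 0.0);
      for (int j = 0; j < Wout; ++j)
        for (int i = 0; i < Hout; ++i)
          dyext[i + j * H] = dyp[i + j * Hout];
      const double* __restrict__ de = dyext.data();
      for (int c = 0; c < Cin; ++c) {
        double* dxb = dx + ((R_xlen_t)b * Cin + c) * HW;
        const double* wc = w + (R_xlen_t)co * k2 * Cin + (R_xlen_t)c * k2;
        for (int kk = 0; kk < k2; ++kk) {
          const int s = (kk % k) + (kk / k) * H;
          axpy_q(dxb + s, de, wc[kk], Qlen);
        }
      }
    }
  }
  return dX;
}

// `idx` is the precomputed (npool x k2) map from pooled position to flat
// spatial input index (1-based).

// [[Rcpp::export]]
List maxpool_cb(const NumericMatrix& X, const IntegerMatrix& idx) {
  const int npool = idx.nrow(), k2 = idx.ncol();
  const int CB = X.ncol();
  NumericMatrix out(npool, CB);
  IntegerMatrix amax(npool, CB);
  const double* x = X.begin();
  const int* id = idx.begin();
  const R_xlen_t HW = X.nrow();
  for (int cb = 0; cb < CB; ++cb) {
    const double* xc = x + (R_xlen_t)cb * HW;
    for (int pp = 0; pp < npool; ++pp) {
      double m = xc[id[pp] - 1];
      int am = 1;
      for (int kk = 1; kk < k2; ++kk) {
        const double v = xc[id[(R_xlen_t)kk * npool + pp] - 1];
        if (v > m) { m = v; am = kk + 1; }
      }
      out(pp, cb) = m;
      amax(pp, cb) = am;
    }
  }
  return List::create(_["out"] = out, _["amax"] = amax);
}

// [[Rcpp::export]]
NumericMatrix maxpool_bwd_cb(const NumericMatrix& dY, const IntegerMatrix& amax,
                             const IntegerMatrix& idx, int HW) {
  const int npool = idx.nrow();
  const int CB = dY.ncol();
  NumericMatrix dX(HW, CB);
  const int* id = idx.begin();
  for (int cb = 0; cb < CB; ++cb) {
    double* xc = dX.begin() + (R_xlen_t)cb * HW;
    const double* dyc = dY.begin() + (R_xlen_t)cb * npool;
    const int* amc = amax.begin() + (R_xlen_t)cb * npool;
    for (int pp = 0; pp < npool; ++pp) {
      const int kk = amc[pp] - 1;
      xc[id[(R_xlen_t)kk * npool + pp] - 1] += dyc[pp];
    }
  }
  return dX;
}
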