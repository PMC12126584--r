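#include <Rcpp.h>
using namespace Rcpp;

// Apply random convolutional kernels to every channel of every window and
// pool each intermediate series to (PPV, max).
//
// X: array N x C x L (R column-major). Per kernel k with length l, dilation
// d and optional zero padding p = ((l - 1) * d) / 2, the convolution output
// at position t is sum_j w[j] * x[t + j * d] + bias over all positions where
// the dilated span fits inside the (padded) series. PPV counts strictly
// positive outputs.
//
// Returns an N x (2 * K * C) matrix; for kernel k (0-based) and channel c,
// column 2*(k*C + c) holds PPV and the next column the maximum.
// [[Rcpp::export]]
NumericMatrix rocket_transform_cpp(NumericVector X, int N, int C, int L,
                                   NumericVector weights, IntegerVector wstart,
                                   IntegerVector lengths, NumericVector biases,
                                   IntegerVector dilations,
                                   IntegerVector paddings) {
  const int K = lengths.size();
  NumericMatrix out(N, 2 * K * C);
  std::vector<double> series(L);
  for (int n = 0; n < N; n++) {
    for (int c = 0; c < C; c++) {
      for (int t = 0; t < L; t++) {
        series[t] = X[(R_xlen_t)n +
                      (R_xlen_t)N * ((R_xlen_t)c + (R_xlen_t)C * (R_xlen_t)t)];
      }
      for (int k = 0; k < K; k++) {
        const int l = lengths[k];
        const int d = dilations[k];
        const int pad = paddings[k] ? ((l - 1) * d) / 2 : 0;
        const double b = biases[k];
        const double *w = &weights[wstart[k]];
        const int span = (l - 1) * d;
        const int start = -pad;
        const int end = L + pad - span;  // exclusive upper start bound
        double mx = R_NegInf;
        int pos = 0, nout = 0;
        for (int t0 = start; t0 < end; t0++) {
          double s = b;
          for (int j = 0; j < l; j++) {
            const int idx = t0 + j * d;
            if (idx >= 0 && idx < L) s += w[j] * series[idx];
          }
          if (s > 0) pos++;
          if (s > mx) mx = s;
          nout++;
        }
        const int col = 2 * (k * C + c);
        if (nout == 0) {  // unreachable when span <= L, kept defensive
          out(n, col) = 0.0;
          out(n, col + 1) = 0.0;
        } else {
          out(n, col) = (double)pos / nout;
          out(n, col + 1) = mx;
        }
      }
    }
  }
  return out;
}
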