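#include <Rcpp.h>
using namespace Rcpp;

// Global max pooling with ReLU and bias over the length axis of a batched
// valid 1D convolution computed as an im2col matrix product.
//
// Z: (B*T) x F pre-activation matrix (row b + B*t holds window t of sample
// b), column-major as produced by Xcol %*% W. bias: length F, added here so
// the caller can skip materialising a broadcasted bias matrix.
// Returns pooled (B x F) = max_t ReLU(Z + bias) and argmax (B x F, 1-based
// t of the maximising window; gradient flows only there).
// [[Rcpp::export]]
List relu_max_pool(NumericMatrix Z, NumericVector bias, int B) {
  const int F = Z.ncol();
  const R_xlen_t BT = Z.nrow();
  const int T = BT / B;
  if ((R_xlen_t)T * B != BT) stop("nrow(Z) not divisible by batch size");
  NumericMatrix pooled(B, F);
  IntegerMatrix argmax(B, F);
  for (int f = 0; f < F; ++f) {
    const double *z = &Z(0, f);
    const double bf = bias[f];
    double *pool_f = &pooled(0, f);
    int *arg_f = &argmax(0, f);
    for (int b = 0; b < B; ++b) { pool_f[b] = R_NegInf; arg_f[b] = 1; }
    R_xlen_t idx = 0;
    for (int t = 0; t < T; ++t) {
      for (int b = 0; b < B; ++b, ++idx) {
        const double v = z[idx] + bf;
        if (v > pool_f[b]) { pool_f[b] = v; arg_f[b] = t + 1; }
      }
    }
    for (int b = 0; b < B; ++b)
      if (pool_f[b] < 0) pool_f[b] = 0.0;  // ReLU after max (equivalent)
  }
  return List::create(_["pooled"] = pooled, _["argmax"] = argmax);
}

// Backward pass through one convolution branch. Gradient reaches only each
// filter's maximising window, and only where the pooled activation was
// positive (ReLU gate).
//
// X: numeric array dim (B, L, C); W: (s*C) x F with row layout
// (c-1)*s + j; argmax/pooled/dP: (B x F).
// Returns dW ((s*C) x F), db (F), and dX (B, L, C) when need_dx.
// [[Rcpp::export]]
List conv_pool_backward(NumericVector X, NumericMatrix W,
                        IntegerMatrix argmax, NumericMatrix pooled,
                        NumericMatrix dP, int s, bool need_dx) {
  IntegerVector dims = X.attr("dim");
  const int B = dims[0], L = dims[1], C = dims[2];
  const int F = W.ncol();
  NumericMatrix dW(s * C, F);
  NumericVector db(F);
  NumericVector dX(need_dx ? (size_t)B * L * C : 0);
  const double *x = X.begin();
  for (int b = 0; b < B; ++b) {
    for (int f = 0; f < F; ++f) {
      if (pooled(b, f) <= 0) continue;
      const double g = dP(b, f);
      if (g == 0) continue;
      const int t = argmax(b, f) - 1;
      db[f] += g;
      for (int c = 0; c < C; ++c) {
        const double *xc = x + b + (size_t)B * L * c;
        for (int j = 0; j < s; ++j) {
          dW(c * s + j, f) += g * xc[(size_t)B * (t + j)];
          if (need_dx)
            dX[b + (size_t)B * (t + j) + (size_t)B * L * c] += g * W(c * s + j, f);
        }
      }
    }
  }
  if (need_dx) dX.attr("dim") = IntegerVector::create(B, L, C);
  return List::create(_["dW"] = dW, _["db"] = db, _["dX"] = dX);
}
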