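#include <Rcpp.h>
using namespace Rcpp;

// Locally connected ("unshared convolution") primitives on flattened
// retinotopic grids. Images/feature maps are stored one sample per row:
// X is n x P with P = H*W grid positions (column-major pixel order).
//
// nbr is a P x K integer table: nbr(p, k) is the 1-based flat index of the
// k-th tap of position p's receptive field, or 0 where the tap falls outside
// the grid (zero padding). W is P x K: one independent weight vector per
// output position. All loops are single-threaded, so results are bitwise
// reproducible.

// [[Rcpp::export]]
NumericMatrix lc_forward(const NumericMatrix& X, const NumericMatrix& W,
                         const IntegerMatrix& nbr) {
  const int n = X.nrow(), P = nbr.nrow(), K = nbr.ncol();
  NumericMatrix Y(n, P);
  for (int p = 0; p < P; ++p) {
    double* yp = &Y(0, p);
    for (int k = 0; k < K; ++k) {
      const int q = nbr(p, k);
      if (q == 0) continue;
      const double w = W(p, k);
      if (w == 0.0) continue;
      const double* xq = &X(0, q - 1);
      for (int i = 0; i < n; ++i) yp[i] += w * xq[i];
    }
  }
  return Y;
}

// [[Rcpp::export]]
NumericMatrix lc_backward_input(const NumericMatrix& G, const NumericMatrix& W,
                                const IntegerMatrix& nbr) {
  const int n = G.nrow(), P = nbr.nrow(), K = nbr.ncol();
  NumericMatrix dX(n, P);
  for (int p = 0; p < P; ++p) {
    const double* gp = &G(0, p);
    for (int k = 0; k < K; ++k) {
      const int q = nbr(p, k);
      if (q == 0) continue;
      const double w = W(p, k);
      if (w == 0.0) continue;
      double* xq = &dX(0, q - 1);
      for (int i = 0; i < n; ++i) xq[i] += w * gp[i];
    }
  }
  return dX;
}

// [[Rcpp::export]]
NumericMatrix lc_backward_weight(const NumericMatrix& G, const NumericMatrix& X,
                                 const IntegerMatrix& nbr) {
  const int n = G.nrow(), P = nbr.nrow(), K = nbr.ncol();
  NumericMatrix dW(P, K);
  for (int p = 0; p < P; ++p) {
    const double* gp = &G(0, p);
    for (int k = 0; k < K; ++k) {
      const int q = nbr(p, k);
      if (q == 0) continue;
      const double* xq = &X(0, q - 1);
      double acc = 0.0;
      for (int i = 0; i < n; ++i) acc += gp[i] * xq[i];
      dW(p, k) = acc;
    }
  }
  return dW;
}

// Weight-shared (true convolution) variants: one K-vector of taps shared by
// every grid position. Used for the photoreceptor front-end.

// [[Rcpp::export]]
NumericMatrix sc_forward(const NumericMatrix& X, const NumericVector& w,
                         const IntegerMatrix& nbr) {
  const int n = X.nrow(), P = nbr.nrow(), K = nbr.ncol();
  NumericMatrix Y(n, P);
  for (int p = 0; p < P; ++p) {
    double* yp = &Y(0, p);
    for (int k = 0; k < K; ++k) {
      const int q = nbr(p, k);
      if (q == 0 || w[k] == 0.0) continue;
      const double* xq = &X(0, q - 1);
      const double wk = w[k];
      for (int i = 0; i < n; ++i) yp[i] += wk * xq[i];
    }
  }
  return Y;
}

// [[Rcpp::export]]
NumericVector sc_backward_weight(const NumericMatrix& G, const NumericMatrix& X,
                                 const IntegerMatrix& nbr) {
  const int n = G.nrow(), P = nbr.nrow(), K = nbr.ncol();
  NumericVector dw(K);
  for (int p = 0; p < P; ++p) {
    const double* gp = &G(0, p);
    for (int k = 0; k < K; ++k) {
      const int q = nbr(p, k);
      if (q == 0) continue;
      const double* xq = &X(0, q - 1);
      double acc = 0.0;
      for (int i = 0; i < n; ++i) acc += gp[i] * xq[i];
      dw[k] += acc;
    }
  }
  return dw;
}

// fast clamp to [0,1] used heavily by the procedural renderer
// [[Rcpp::export]]
NumericVector clamp01_cpp(NumericVector x) {
  NumericVector y = clone(x);
  const int n = y.size();
  for (int i = 0; i < n; ++i) {
    if (y[i] < 0.0) y[i] = 0.0;
    else if (y[i] > 1.0) y[i] = 1.0;
  }
  return y;
}
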