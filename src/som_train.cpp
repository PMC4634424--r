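#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sequential Kohonen training loop. Weights and data arrive transposed
// (dim x m, dim x n) so each vector is a contiguous column. Shuffle orders
// (0-based, one column per epoch) and per-epoch learning rates are computed
// in R so all randomness stays in R's RNG. Winner ties resolve to the
// lowest neuron index, matching find_winner().
// [[Rcpp::export]]
NumericMatrix som_train_cpp(NumericMatrix tW0, NumericMatrix tX,
                            IntegerVector row, IntegerVector col,
                            IntegerMatrix orders, NumericVector etas,
                            double sigma) {
  NumericMatrix tW = clone(tW0);
  const int d = tW.nrow(), m = tW.ncol(), n = tX.ncol();
  const int E = orders.ncol();
  if (orders.nrow() != n) stop("orders must have one row per sample");
  if (etas.size() != E) stop("one learning rate per epoch required");
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double *W = REAL(tW);
  const double *X = REAL(tX);

  for (int e = 0; e < E; ++e) {
    const double eta = etas[e];
    for (int t = 0; t < n; ++t) {
      const int i = orders(t, e);
      const double *x = X + (size_t)i * d;
      int best = 0;
      double bestd = R_PosInf;
      for (int j = 0; j < m; ++j) {
        const double *w = W + (size_t)j * d;
        double s = 0.0;
        for (int k = 0; k < d; ++k) {
          const double diff = x[k] - w[k];
          s += diff * diff;
        }
        if (s < bestd) { bestd = s; best = j; }
      }
      const int rb = row[best], cb = col[best];
      for (int j = 0; j < m; ++j) {
        const double dr = row[j] - rb, dc = col[j] - cb;
        const double a = eta * std::exp(-(dr * dr + dc * dc) * inv2s2);
        if (a <= 0.0) continue;
        double *w = W + (size_t)j * d;
        for (int k = 0; k < d; ++k) w[k] += a * (x[k] - w[k]);
      }
    }
  }
  return tW;
}
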