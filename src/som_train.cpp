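#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Online Kohonen training of a hexagonal SOM with co-trained per-neuron
// class-label vectors. All randomness (initial weights, presentation order)
// is decided in R; this loop is fully deterministic.
//
// Spectra and weights are passed channels-first (column per sample/neuron)
// so the inner loops run over contiguous memory.
//
// Xt:      training spectra, channels x samples
// onehot:  samples x classes, one-hot class membership
// order:   0-based sample index per update step (length = total iterations)
// W0t:     initial neuron weights, channels x neurons
// L0:      initial label weights, neurons x classes
// hexd:    neurons x neurons hex grid distances
// lr0/lrEnd, sigma0/sigmaEnd: exponential decay schedules
// cosine:  use cosine instead of squared-Euclidean BMU distance
// [[Rcpp::export]]
List som_train_cpp(NumericMatrix Xt, NumericMatrix onehot, IntegerVector order,
                   NumericMatrix W0t, NumericMatrix L0, NumericMatrix hexd,
                   double lr0, double lrEnd, double sigma0, double sigmaEnd,
                   bool cosine) {
  const int p = Xt.nrow();
  const int m = W0t.ncol();
  const int k = onehot.ncol();
  const int T = order.size();
  NumericMatrix W = clone(W0t);
  NumericMatrix L = clone(L0);

  for (int t = 0; t < T; ++t) {
    const double frac = (T > 1) ? (double)t / (double)(T - 1) : 0.0;
    const double lr = lr0 * std::pow(lrEnd / lr0, frac);
    const double sigma = sigma0 * std::pow(sigmaEnd / sigma0, frac);
    const int i = order[t];
    const double *x = &Xt(0, i);

    // best-matching unit; strict '<' keeps the lowest index on ties
    int bmu = 0;
    double best = R_PosInf;
    for (int u = 0; u < m; ++u) {
      const double *wu = &W(0, u);
      double d;
      if (cosine) {
        double dot = 0, nw = 0, ns = 0;
        for (int j = 0; j < p; ++j) {
          dot += wu[j] * x[j];
          nw += wu[j] * wu[j];
          ns += x[j] * x[j];
        }
        const double den = std::sqrt(nw * ns);
        d = (den > 0) ? 1.0 - dot / den : 1.0;
      } else {
        d = 0;
        for (int j = 0; j < p; ++j) {
          const double df = wu[j] - x[j];
          d += df * df;
        }
      }
      if (d < best) { best = d; bmu = u; }
    }

    const double twoSigma2 = 2.0 * sigma * sigma;
    for (int u = 0; u < m; ++u) {
      const double hd = hexd(u, bmu);
      const double h = std::exp(-(hd * hd) / twoSigma2);
      const double a = lr * h;
      if (a < 1e-9) continue;  // kernel tail: no measurable update
      double *wu = &W(0, u);
      for (int j = 0; j < p; ++j) wu[j] += a * (x[j] - wu[j]);
      for (int c = 0; c < k; ++c) L(u, c) += a * (onehot(i, c) - L(u, c));
    }
  }
  return List::create(_["weights"] = W, _["labelWeights"] = L);
}
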