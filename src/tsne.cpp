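// Exact (O(n^2)) t-SNE, following the standard reference algorithm:
// Gaussian input affinities calibrated per point to a target perplexity by
// binary search, Student-t output affinities, gradient descent with early
// exaggeration, momentum switching and per-parameter gains. The initial
// embedding Y0 is supplied from R (drawn with R's RNG) so runs are
// deterministic under set.seed().
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix tsne_embed_cpp(NumericMatrix X, NumericMatrix Y0,
                             double perplexity, int max_iter,
                             double eta, double exaggeration,
                             int exag_iter) {
  const int n = X.nrow(), d = X.ncol();
  const int outd = Y0.ncol();

  // pairwise squared distances in input space
  std::vector<double> D(static_cast<size_t>(n) * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        const double diff = X(i, k) - X(j, k);
        s += diff * diff;
      }
      D[i * n + j] = s;
      D[j * n + i] = s;
    }
  }

  // conditional affinities: binary-search beta_i for the target perplexity
  std::vector<double> P(static_cast<size_t>(n) * n, 0.0);
  const double logU = std::log(perplexity);
  for (int i = 0; i < n; ++i) {
    double beta = 1.0, betamin = -1e300, betamax = 1e300;
    for (int it = 0; it < 64; ++it) {
      double sumP = 0.0, sumDP = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double pij = std::exp(-beta * D[i * n + j]);
        sumP += pij;
        sumDP += beta * D[i * n + j] * pij;
      }
      if (sumP < 1e-300) sumP = 1e-300;
      const double H = std::log(sumP) + sumDP / sumP;
      const double diff = H - logU;
      if (std::fabs(diff) < 1e-7) break;
      if (diff > 0) {
        betamin = beta;
        beta = (betamax > 1e299) ? beta * 2.0 : (beta + betamax) / 2.0;
      } else {
        betamax = beta;
        beta = (betamin < -1e299) ? beta / 2.0 : (beta + betamin) / 2.0;
      }
    }
    double sumP = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      P[i * n + j] = std::exp(-beta * D[i * n + j]);
      sumP += P[i * n + j];
    }
    if (sumP < 1e-300) sumP = 1e-300;
    for (int j = 0; j < n; ++j) P[i * n + j] /= sumP;
  }

  // symmetrise, normalise, early-exaggerate
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double pij = (P[i * n + j] + P[j * n + i]) / (2.0 * n);
      if (pij < 1e-12) pij = 1e-12;
      P[i * n + j] = pij * exaggeration;
      P[j * n + i] = pij * exaggeration;
    }
  }

  NumericMatrix Y = clone(Y0);
  std::vector<double> dY(static_cast<size_t>(n) * outd, 0.0);
  std::vector<double> iY(static_cast<size_t>(n) * outd, 0.0);
  std::vector<double> gains(static_cast<size_t>(n) * outd, 1.0);
  std::vector<double> Q(static_cast<size_t>(n) * n, 0.0);

  for (int iter = 0; iter < max_iter; ++iter) {
    // Student-t output affinities
    double sumQ = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double s = 0.0;
        for (int k = 0; k < outd; ++k) {
          const double diff = Y(i, k) - Y(j, k);
          s += diff * diff;
        }
        const double q = 1.0 / (1.0 + s);
        Q[i * n + j] = q;
        Q[j * n + i] = q;
        sumQ += 2.0 * q;
      }
    }
    if (sumQ < 1e-300) sumQ = 1e-300;

    // gradient
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < outd; ++k) dY[i * outd + k] = 0.0;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        const double q = Q[i * n + j];
        const double mult = (P[i * n + j] - q / sumQ) * q;
        for (int k = 0; k < outd; ++k) {
          dY[i * outd + k] += 4.0 * mult * (Y(i, k) - Y(j, k));
        }
      }
    }

    const double momentum = (iter < 250) ? 0.5 : 0.8;
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < outd; ++k) {
        const size_t idx = static_cast<size_t>(i) * outd + k;
        const bool same_sign = (dY[idx] > 0.0) == (iY[idx] > 0.0);
        gains[idx] = same_sign ? gains[idx] * 0.8 : gains[idx] + 0.2;
        if (gains[idx] < 0.01) gains[idx] = 0.01;
        iY[idx] = momentum * iY[idx] - eta * gains[idx] * dY[idx];
        Y(i, k) += iY[idx];
      }
    }
    // re-centre
    for (int k = 0; k < outd; ++k) {
      double m = 0.0;
      for (int i = 0; i < n; ++i) m += Y(i, k);
      m /= n;
      for (int i = 0; i < n; ++i) Y(i, k) -= m;
    }
    // end of early exaggeration
    if (iter == exag_iter - 1 && exaggeration != 1.0) {
      for (size_t idx = 0; idx < P.size(); ++idx) P[idx] /= exaggeration;
    }
  }
  return Y;
}
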