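#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Scaled forward-backward for a 2-state HMM over concatenated chromosome
// sequences. logB holds per-bin emission log-probabilities (L x 2); pi and A
// are in probability space. seq_len gives the length of each independent
// sequence (chromosome) in order; transitions never cross sequence ends.
// Returns per-bin posteriors, pooled expected transition counts, the summed
// posterior at sequence starts (for the initial-distribution update), and the
// total log-likelihood.
// [[Rcpp::export]]
List fb_cpp(NumericMatrix logB, NumericVector pi, NumericMatrix A,
            IntegerVector seq_len) {
  const int L = logB.nrow();
  NumericMatrix gamma(L, 2);
  NumericMatrix alpha(L, 2);
  NumericMatrix beta(L, 2);
  NumericMatrix xi(2, 2);
  NumericVector gfirst(2);
  double loglik = 0.0;

  int offset = 0;
  for (int s = 0; s < seq_len.size(); ++s) {
    const int T = seq_len[s];
    if (T == 0) continue;

    // forward pass with per-step normalisation
    double rm = std::max(logB(offset, 0), logB(offset, 1));
    double b0 = std::exp(logB(offset, 0) - rm);
    double b1 = std::exp(logB(offset, 1) - rm);
    double a0 = pi[0] * b0, a1 = pi[1] * b1;
    double csum = a0 + a1;
    alpha(offset, 0) = a0 / csum;
    alpha(offset, 1) = a1 / csum;
    loglik += std::log(csum) + rm;
    for (int t = 1; t < T; ++t) {
      const int i = offset + t;
      rm = std::max(logB(i, 0), logB(i, 1));
      b0 = std::exp(logB(i, 0) - rm);
      b1 = std::exp(logB(i, 1) - rm);
      const double p0 = alpha(i - 1, 0) * A(0, 0) + alpha(i - 1, 1) * A(1, 0);
      const double p1 = alpha(i - 1, 0) * A(0, 1) + alpha(i - 1, 1) * A(1, 1);
      a0 = p0 * b0;
      a1 = p1 * b1;
      csum = a0 + a1;
      alpha(i, 0) = a0 / csum;
      alpha(i, 1) = a1 / csum;
      loglik += std::log(csum) + rm;
    }

    // backward pass, renormalised each step (absolute scale cancels in
    // gamma and xi)
    beta(offset + T - 1, 0) = 1.0;
    beta(offset + T - 1, 1) = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      const int i = offset + t;
      rm = std::max(logB(i + 1, 0), logB(i + 1, 1));
      b0 = std::exp(logB(i + 1, 0) - rm);
      b1 = std::exp(logB(i + 1, 1) - rm);
      const double v0 = A(0, 0) * b0 * beta(i + 1, 0) + A(0, 1) * b1 * beta(i + 1, 1);
      const double v1 = A(1, 0) * b0 * beta(i + 1, 0) + A(1, 1) * b1 * beta(i + 1, 1);
      const double norm = v0 + v1;
      beta(i, 0) = v0 / norm;
      beta(i, 1) = v1 / norm;
    }

    for (int t = 0; t < T; ++t) {
      const int i = offset + t;
      const double g0 = alpha(i, 0) * beta(i, 0);
      const double g1 = alpha(i, 1) * beta(i, 1);
      const double gs = g0 + g1;
      gamma(i, 0) = g0 / gs;
      gamma(i, 1) = g1 / gs;
    }
    gfirst[0] += gamma(offset, 0);
    gfirst[1] += gamma(offset, 1);

    for (int t = 0; t < T - 1; ++t) {
      const int i = offset + t;
      rm = std::max(logB(i + 1, 0), logB(i + 1, 1));
      b0 = std::exp(logB(i + 1, 0) - rm);
      b1 = std::exp(logB(i + 1, 1) - rm);
      const double x00 = alpha(i, 0) * A(0, 0) * b0 * beta(i + 1, 0);
      const double x01 = alpha(i, 0) * A(0, 1) * b1 * beta(i + 1, 1);
      const double x10 = alpha(i, 1) * A(1, 0) * b0 * beta(i + 1, 0);
      const double x11 = alpha(i, 1) * A(1, 1) * b1 * beta(i + 1, 1);
      const double xs = x00 + x01 + x10 + x11;
      xi(0, 0) += x00 / xs;
      xi(0, 1) += x01 / xs;
      xi(1, 0) += x10 / xs;
      xi(1, 1) += x11 / xs;
    }

    offset += T;
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["gamma_first"] = gfirst, _["loglik"] = loglik);
}
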