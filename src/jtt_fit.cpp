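// Maximum-likelihood pairwise distance under the JTT model with an optional
// discrete-Gamma rate mixture. The likelihood uses the symmetric
// eigendecomposition prepared in R:
//   with D = diag(pi), B = D^{1/2} Q D^{-1/2} = V diag(lambda) V',
//   pi_a * P_ab(t) = sqrtpi_a * sqrtpi_b * [V exp(lambda t) V']_ab.
// Only the 20x20 table of aligned residue-pair counts enters the likelihood,
// so one evaluation is O(20^3) regardless of sequence length.

#include <Rcpp.h>
#include <cmath>
#include <cfloat>
using namespace Rcpp;

static double pair_loglik(double t,
                          const NumericMatrix& counts,
                          const NumericVector& values,
                          const NumericMatrix& vectors,
                          const NumericVector& sqrtpi,
                          const NumericVector& rates) {
  const int n = 20;
  const int K = rates.size();
  double mix[20][20];
  for (int a = 0; a < n; ++a)
    for (int b = 0; b < n; ++b) mix[a][b] = 0.0;
  double w[20];
  for (int k = 0; k < K; ++k) {
    for (int j = 0; j < n; ++j) w[j] = std::exp(values[j] * t * rates[k]);
    // M = V diag(w) V' accumulated into mix
    for (int a = 0; a < n; ++a) {
      for (int b = 0; b <= a; ++b) {
        double m = 0.0;
        for (int j = 0; j < n; ++j) m += vectors(a, j) * w[j] * vectors(b, j);
        mix[a][b] += m;
        if (a != b) mix[b][a] += m;
      }
    }
  }
  double ll = 0.0;
  const double invK = 1.0 / (double)K;
  for (int a = 0; a < n; ++a) {
    for (int b = 0; b < n; ++b) {
      double c = counts(a, b);
      if (c > 0.0) {
        double f = sqrtpi[a] * sqrtpi[b] * mix[a][b] * invK;
        if (f < DBL_MIN) f = DBL_MIN;
        ll += c * std::log(f);
      }
    }
  }
  return ll;
}

// [[Rcpp::export]]
double jtt_pair_loglik_cpp(double t, NumericMatrix counts,
                           NumericVector values, NumericMatrix vectors,
                           NumericVector sqrtpi, NumericVector rates) {
  return pair_loglik(t, counts, values, vectors, sqrtpi, rates);
}

// Brent's localmin (Brent 1973) on the negative log-likelihood.
// [[Rcpp::export]]
double jtt_fit_cpp(NumericMatrix counts,
                   NumericVector values, NumericMatrix vectors,
                   NumericVector sqrtpi, NumericVector rates,
                   double lower, double upper, double tol) {
  const double golden = 0.5 * (3.0 - std::sqrt(5.0));
  double a = lower, b = upper;
  double x = a + golden * (b - a);
  double wpt = x, v = x;
  double fx = -pair_loglik(x, counts, values, vectors, sqrtpi, rates);
  double fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  const double eps = std::sqrt(DBL_EPSILON);
  for (int iter = 0; iter < 200; ++iter) {
    double m = 0.5 * (a + b);
    double tol1 = eps * std::fabs(x) + tol / 3.0;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - m) <= tol2 - 0.5 * (b - a)) break;
    double p = 0.0, q = 0.0, r = 0.0;
    bool parabolic = false;
    if (std::fabs(e) > tol1) {
      r = (x - wpt) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - wpt) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p; else q = -q;
      if (std::fabs(p) < std::fabs(0.5 * q * e) &&
          p > q * (a - x) && p < q * (b - x)) {
        e = d;
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (x < m) ? tol1 : -tol1;
        parabolic = true;
      }
    }
    if (!parabolic) {
      e = (x < m) ? (b - x) : (a - x);
      d = golden * e;
    }
    double u = (std::fabs(d) >= tol1) ? (x + d) : (x + ((d > 0) ? tol1 : -tol1));
    double fu = -pair_loglik(u, counts, values, vectors, sqrtpi, rates);
    if (fu <= fx) {
      if (u < x) b = x; else a = x;
      v = wpt; fv = fw; wpt = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || wpt == x) {
        v = wpt; fv = fw; wpt = u; fw = fu;
      } else if (fu <= fv || v == x || v == wpt) {
        v = u; fv = fu;
      }
    }
  }
  return x;
}
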