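#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static const double LN_SQRT_2PI = 0.918938533204672741780329736406;

// normal log-density with the log(sd) term precomputed by the caller
static inline double ldnorm(double x, double mu, double inv_s, double log_s) {
  double z = (x - mu) * inv_s;
  return -LN_SQRT_2PI - log_s - 0.5 * z * z;
}

// log(exp(a) + exp(b)) without overflow
static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// EM for a two-component normal mixture on raw (already log10-transformed)
// values. Returns the loglik trace so monotonicity can be audited.
// [[Rcpp::export]]
List cpp_em2(NumericVector x, double mu1, double mu2, double s1, double s2,
             double w1, double tol, int maxit, double sd_floor) {
  const int n = x.size();
  std::vector<double> trace;
  trace.reserve(128);
  double ll_old = R_NegInf, ll = R_NegInf;
  bool converged = false, collapsed = false;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    double sw1 = 0.0, sx1 = 0.0, sx2 = 0.0, sxx1 = 0.0, sxx2 = 0.0;
    ll = 0.0;
    const double lw1 = std::log(w1), lw2 = std::log1p(-w1);
    const double is1 = 1.0 / s1, is2 = 1.0 / s2;
    const double ls1 = std::log(s1), ls2 = std::log(s2);
    for (int i = 0; i < n; ++i) {
      double l1 = lw1 + ldnorm(x[i], mu1, is1, ls1);
      double l2 = lw2 + ldnorm(x[i], mu2, is2, ls2);
      double li = lse2(l1, l2);
      ll += li;
      double r1 = std::exp(l1 - li);
      sw1 += r1;
      sx1 += r1 * x[i];
      sx2 += (1.0 - r1) * x[i];
      sxx1 += r1 * x[i] * x[i];
      sxx2 += (1.0 - r1) * x[i] * x[i];
    }
    trace.push_back(ll);
    if (it > 1 && std::fabs(ll - ll_old) <
          tol * (std::fabs(ll_old) + 1e-300)) {
      converged = true;
      break;
    }
    ll_old = ll;
    // M-step
    double sw2 = n - sw1;
    if (sw1 < 1e-10 || sw2 < 1e-10) { collapsed = true; break; }
    double nmu1 = sx1 / sw1, nmu2 = sx2 / sw2;
    double v1 = sxx1 / sw1 - nmu1 * nmu1;
    double v2 = sxx2 / sw2 - nmu2 * nmu2;
    mu1 = nmu1; mu2 = nmu2;
    s1 = std::sqrt(std::max(v1, 0.0));
    s2 = std::sqrt(std::max(v2, 0.0));
    w1 = sw1 / n;
    if (s1 < sd_floor || s2 < sd_floor || w1 < 1e-8 || w1 > 1.0 - 1e-8) {
      collapsed = true;
      break;
    }
  }
  return List::create(
    _["mu1"] = mu1, _["mu2"] = mu2, _["s1"] = s1, _["s2"] = s2,
    _["w1"] = w1, _["loglik"] = ll, _["n_iter"] = (int)trace.size(),
    _["converged"] = converged, _["collapsed"] = collapsed,
    _["trace"] = NumericVector(trace.begin(), trace.end()));
}

// [[Rcpp::export]]
double cpp_mix2_loglik(NumericVector x, double w1, double mu1, double s1,
                       double mu2, double s2) {
  const int n = x.size();
  const double lw1 = std::log(w1), lw2 = std::log1p(-w1);
  const double is1 = 1.0 / s1, is2 = 1.0 / s2;
  const double ls1 = std::log(s1), ls2 = std::log(s2);
  double ll = 0.0;
  for (int i = 0; i < n; ++i)
    ll += lse2(lw1 + ldnorm(x[i], mu1, is1, ls1),
               lw2 + ldnorm(x[i], mu2, is2, ls2));
  return ll;
}

// Sign of the mixture density derivative at interior points, computed in log
// space so it stays exact even where the density itself underflows.
// All stationary points of a two-normal mixture lie strictly between the
// component means, and the derivative is positive just right of the lower
// mean and negative just left of the upper mean; each local maximum is one
// (+ -> -) sign change.
// [[Rcpp::export]]
int cpp_nmodes2(double w1, double mu1, double s1, double mu2, double s2) {
  if (mu1 > mu2) {
    std::swap(mu1, mu2); std::swap(s1, s2); w1 = 1.0 - w1;
  }
  double sep = mu2 - mu1;
  double smax = std::max(s1, s2), smin = std::min(s1, s2);
  if (sep <= 1e-12 * smax) return 1;
  int m = (int)std::ceil(sep / (smin / 200.0));
  m = std::max(m, 400);
  m = std::min(m, 60000);
  const double lw1 = std::log(w1), lw2 = std::log1p(-w1);
  const double ls1 = std::log(s1), ls2 = std::log(s2);
  const double is1 = 1.0 / s1, is2 = 1.0 / s2;
  const double l2s1 = 2.0 * ls1, l2s2 = 2.0 * ls2;
  const double eps = sep * 1e-9;
  // f'(mu1) > 0 and f'(mu2) < 0 analytically; modes can sit exponentially
  // close to the component means, so those endpoint signs are pinned
  // rather than sampled.
  int sign_prev = 1, n_down = 0;
  for (int i = 0; i <= m; ++i) {
    double x = mu1 + eps + (sep - 2.0 * eps) * (double)i / (double)m;
    // positive part: upper component pulls density up left of mu2
    double lpos = lw2 + ldnorm(x, mu2, is2, ls2) + std::log(mu2 - x) - l2s2;
    double lneg = lw1 + ldnorm(x, mu1, is1, ls1) + std::log(x - mu1) - l2s1;
    int s = (lpos >= lneg) ? 1 : -1;
    if (sign_prev == 1 && s == -1) ++n_down;
    sign_prev = s;
  }
  if (sign_prev == 1) ++n_down;  // closing -: f'(mu2) < 0
  return n_down >= 2 ? 2 : 1;
}

// Log mixture density on a uniform grid over [mu1, mu2]; used for the dip
// penalty of the constrained unimodal fit.
static double dip_depth(double w1, double mu1, double s1, double mu2,
                        double s2) {
  if (mu1 > mu2) {
    std::swap(mu1, mu2); std::swap(s1, s2); w1 = 1.0 - w1;
  }
  const int m = 240;
  const double lw1 = std::log(w1), lw2 = std::log1p(-w1);
  const double is1 = 1.0 / s1, is2 = 1.0 / s2;
  const double ls1 = std::log(s1), ls2 = std::log(s2);
  std::vector<double> lf(m + 1);
  for (int i = 0; i <= m; ++i) {
    double x = mu1 + (mu2 - mu1) * (double)i / (double)m;
    lf[i] = lse2(lw1 + ldnorm(x, mu1, is1, ls1),
                 lw2 + ldnorm(x, mu2, is2, ls2));
  }
  // local maxima on the grid (endpoints included: modes can sit at a mean)
  std::vector<int> peaks;
  for (int i = 0; i <= m; ++i) {
    double left = (i > 0) ? lf[i - 1] : R_NegInf;
    double right = (i < m) ? lf[i + 1] : R_NegInf;
    if (lf[i] >= left && lf[i] >= right) peaks.push_back(i);
  }
  if (peaks.size() < 2) return 0.0;
  // two highest peaks, valley between them
  int p1 = peaks[0], p2 = peaks[0];
  for (int p : peaks) if (lf[p] > lf[p1]) { p2 = p1; p1 = p; }
    else if (p != p1 && (p2 == p1 || lf[p] > lf[p2])) p2 = p;
  if (p1 == p2) return 0.0;
  int lo = std::min(p1, p2), hi = std::max(p1, p2);
  double valley = lf[lo];
  for (int i = lo; i <= hi; ++i) valley = std::min(valley, lf[i]);
  double dip = std::min(lf[p1], lf[p2]) - valley;
  return dip > 0.0 ? dip : 0.0;
}

// Negative log-likelihood of a two-component normal mixture, plus a penalty
// that activates when the mixture is bimodal. par = (mu1, mu2, log s1,
// log s2, logit w1). The jump keeps optimizers on the unimodal side of the
// boundary; lambda scales the dip of the log-density between the two modes.
// [[Rcpp::export]]
double cpp_negll_unimodal(NumericVector par, NumericVector x, double jump,
                          double lambda) {
  double mu1 = par[0], mu2 = par[1];
  double s1 = std::exp(par[2]), s2 = std::exp(par[3]);
  double w1 = 1.0 / (1.0 + std::exp(-par[4]));
  if (!std::isfinite(mu1) || !std::isfinite(mu2) || !std::isfinite(s1) ||
      !std::isfinite(s2) || s1 < 1e-6 || s2 < 1e-6 || s1 > 1e6 || s2 > 1e6 ||
      w1 < 1e-12 || w1 > 1.0 - 1e-12)
    return 1e12;
  double nll = -cpp_mix2_loglik(x, w1, mu1, s1, mu2, s2);
  if (!std::isfinite(nll)) return 1e12;
  if (cpp_nmodes2(w1, mu1, s1, mu2, s2) == 2)
    nll += jump + lambda * dip_depth(w1, mu1, s1, mu2, s2);
  return nll;
}
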