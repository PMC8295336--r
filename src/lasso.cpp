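#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// L1-penalized logistic regression along a decreasing lambda path by
// proximal Newton: an outer IRLS loop forms the local weighted quadratic
// approximation of the logistic deviance, an inner cyclic coordinate
// descent (restricted to a sequential strong-rule screened set, with
// active-set iteration) solves the penalized quadratic, and a
// backtracking line search toward the previous iterate guarantees the
// penalized objective is non-increasing at every recorded trace point.
// Screening is made exact by a full KKT check over all features at each
// lambda. The intercept is unpenalized. The objective is
//   (1/n) sum_i [log(1+exp(eta_i)) - y_i * eta_i] + lambda * ||beta||_1 .
// When devRatioMax < 1, the path stops once the fitted model explains
// that fraction of the null deviance (the overfit tail of the path);
// remaining path columns repeat the last fitted solution and are flagged
// in 'saturated'.

static inline double log1pexp_(double a) {
  if (a > 0) return a + std::log1p(std::exp(-a));
  return std::log1p(std::exp(a));
}

static inline double soft_(double u, double t) {
  if (u > t) return u - t;
  if (u < -t) return u + t;
  return 0.0;
}

// [[Rcpp::export(name = ".cd_lasso_logistic")]]
List cd_lasso_logistic(const NumericMatrix& X, const NumericVector& y,
                       const NumericVector& lambdas, double tol, int maxit,
                       bool trace, double devRatioMax = 1.0,
                       double devFracMin = 0.0) {
  const int n = X.nrow(), p = X.ncol(), nl = lambdas.size();
  const double wmin = 1e-5;
  const double* Xp = X.begin();
  std::vector<double> beta(p, 0.0), eta(n, 0.0);
  double alpha = 0.0;

  std::vector<double> w(n), e(n), betaq(p), grad(p), cj(p);
  std::vector<double> betaNew(p), etaNew(n);
  std::vector<int> screen;
  std::vector<char> inScreen(p, 0);

  auto devianceAt = [&](const std::vector<double>& et) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += log1pexp_(et[i]) - y[i] * et[i];
    return s / n;
  };
  auto objective = [&](const std::vector<double>& et,
                       const std::vector<double>& b, double lam) {
    double b1 = 0.0;
    for (int j = 0; j < p; ++j) b1 += std::fabs(b[j]);
    return devianceAt(et) + lam * b1;
  };

  // null deviance (intercept-only), for the saturation rule
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar /= n;
  double nullDev = R_PosInf;
  if (ybar > 0 && ybar < 1) {
    double a0 = std::log(ybar / (1.0 - ybar));
    nullDev = log1pexp_(a0) - ybar * a0;
  }

  // full gradient of the smooth part at the current iterate
  auto fullGradient = [&]() {
    std::vector<double> pmy(n);
    for (int i = 0; i < n; ++i)
      pmy[i] = 1.0 / (1.0 + std::exp(-eta[i])) - y[i];
    for (int j = 0; j < p; ++j) {
      const double* xj = Xp + (size_t)j * n;
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += xj[i] * pmy[i];
      grad[j] = s / n;
    }
  };

  NumericVector out_alpha(nl), out_obj(nl);
  NumericMatrix out_beta(p, nl);
  IntegerVector out_iter(nl);
  LogicalVector out_conv(nl), out_sat(nl);

  List out_trace(trace ? nl : 0);
  int lastFitted = -1;
  double prevDev = R_PosInf;

  for (int l = 0; l < nl; ++l) {
    const double lam = lambdas[l];
    const double lamPrev = (l == 0) ? lambdas[0] : lambdas[l - 1];
    std::vector<double> tr;
    double obj = objective(eta, beta, lam);
    if (trace) tr.push_back(obj);
    bool converged = false;
    int outer = 0;

    // sequential strong rule at the warm start
    fullGradient();
    screen.clear();
    std::fill(inScreen.begin(), inScreen.end(), 0);
    const double srThresh = 2.0 * lam - lamPrev;
    for (int j = 0; j < p; ++j) {
      if (beta[j] != 0.0 || std::fabs(grad[j]) >= srThresh - 1e-12) {
        screen.push_back(j);
        inScreen[j] = 1;
      }
    }

    for (;;) {  // screening loop: solve on screened set, then check KKT
      while (outer < maxit) {
        ++outer;
        // weighted quadratic approximation at the current iterate
        double sw = 0.0;
        for (int i = 0; i < n; ++i) {
          double pi = 1.0 / (1.0 + std::exp(-eta[i]));
          double wi = pi * (1.0 - pi);
          if (wi < wmin) wi = wmin;
          w[i] = wi;
          sw += wi;
          e[i] = (y[i] - pi) / wi;  // working residual z_i - eta_i
        }
        for (int j : screen) {
          const double* xj = Xp + (size_t)j * n;
          double s = 0.0;
          for (int i = 0; i < n; ++i) s += w[i] * xj[i] * xj[i];
          cj[j] = std::max(s / n, 1e-12);
          betaq[j] = beta[j];
        }
        double alphaq = alpha;

        auto qstep = [&](int j) {
          const double* xj = Xp + (size_t)j * n;
          double g = 0.0;
          for (int i = 0; i < n; ++i) g += w[i] * xj[i] * e[i];
          g /= n;
          double bn = soft_(g + cj[j] * betaq[j], lam) / cj[j];
          double d = bn - betaq[j];
          if (d != 0.0) {
            betaq[j] = bn;
            for (int i = 0; i < n; ++i) e[i] -= d * xj[i];
          }
          return cj[j] * d * d;
        };
        auto qstep0 = [&]() {
          double g = 0.0;
          for (int i = 0; i < n; ++i) g += w[i] * e[i];
          double d = g / sw;
          if (d != 0.0) {
            alphaq += d;
            for (int i = 0; i < n; ++i) e[i] -= d;
          }
          return 0.25 * d * d;
        };

        // inner CD on the penalized quadratic, screened set only
        double firstMaxd = -1.0;
        int inner = 0;
        while (inner < 1000) {
          double maxd = qstep0();
          for (int j : screen) {
            double d = qstep(j);
            if (d > maxd) maxd = d;
          }
          ++inner;
          if (firstMaxd < 0) firstMaxd = maxd;
          if (maxd < tol) break;
          while (inner < 1000) {  // active-set sweeps
            double mda = qstep0();
            for (int j : screen) {
              if (betaq[j] == 0.0) continue;
              double d = qstep(j);
              if (d > mda) mda = d;
            }
            ++inner;
            if (mda < tol) break;
          }
        }
        if (firstMaxd < tol) { converged = true; break; }

        // backtracking toward the previous point; the proximal-Newton
        // direction is a descent direction, so this terminates with a
        // non-increasing objective
        double step = 1.0, objNew = 0.0, alphaNew = 0.0;
        for (int half = 0; half < 40; ++half) {
          alphaNew = alpha + step * (alphaq - alpha);
          betaNew = beta;
          for (int j : screen)
            betaNew[j] = beta[j] + step * (betaq[j] - beta[j]);
          std::fill(etaNew.begin(), etaNew.end(), alphaNew);
          for (int j = 0; j < p; ++j) {
            double b = betaNew[j];
            if (b == 0.0) continue;
            const double* xj = Xp + (size_t)j * n;
            for (int i = 0; i < n; ++i) etaNew[i] += b * xj[i];
          }
          objNew = objective(etaNew, betaNew, lam);
          if (objNew <= obj + 1e-14) break;
          step *= 0.5;
        }
        if (objNew > obj + 1e-14) {  // at the numerical optimum
          converged = true;
          break;
        }
        double drop = obj - objNew;
        beta = betaNew;
        alpha = alphaNew;
        eta = etaNew;
        obj = objNew;
        if (trace) tr.push_back(obj);
        if (drop < tol * 1e-2) { converged = true; break; }
      }
      // KKT check over excluded features; admit violators and resolve
      fullGradient();
      bool violation = false;
      for (int j = 0; j < p; ++j) {
        if (!inScreen[j] && std::fabs(grad[j]) > lam + 1e-9) {
          screen.push_back(j);
          inScreen[j] = 1;
          violation = true;
        }
      }
      if (!violation || outer >= maxit) break;
      converged = false;
    }

    out_alpha[l] = alpha;
    for (int j = 0; j < p; ++j) out_beta(j, l) = beta[j];
    out_iter[l] = outer;
    out_conv[l] = converged;
    out_sat[l] = false;
    out_obj[l] = obj;
    if (trace) out_trace[l] = NumericVector(tr.begin(), tr.end());
    lastFitted = l;

    if ((devRatioMax < 1.0 || devFracMin > 0.0) && R_finite(nullDev) &&
        nullDev > 0) {
      double dev = devianceAt(eta);
      if (1.0 - dev / nullDev >= devRatioMax) break;
      // flat-tail stop: successive lambda steps no longer improve the fit
      if (devFracMin > 0.0 && l > 0) {
        if (prevDev - dev < devFracMin * nullDev) break;
        prevDev = dev;
      } else if (devFracMin > 0.0) {
        prevDev = dev;
      }
    }
  }

  // pad a saturated path with the last fitted solution
  for (int l = lastFitted + 1; l < nl; ++l) {
    out_alpha[l] = out_alpha[lastFitted];
    for (int j = 0; j < p; ++j) out_beta(j, l) = out_beta(j, lastFitted);
    out_iter[l] = 0;
    out_conv[l] = out_conv[lastFitted];
    out_sat[l] = true;
    out_obj[l] = out_obj[lastFitted];
    if (trace) out_trace[l] = NumericVector(0);
  }

  List res = List::create(
    _["alpha"] = out_alpha, _["beta"] = out_beta, _["iterations"] = out_iter,
    _["converged"] = out_conv, _["saturated"] = out_sat,
    _["objective"] = out_obj);
  if (trace) res["trace"] = out_trace;
  return res;
}

// Linear predictors for a coefficient vector: eta = X beta + alpha.
// [[Rcpp::export(name = ".xbeta")]]
NumericVector xbeta(const NumericMatrix& X, const NumericVector& beta,
                    double alpha) {
  const int n = X.nrow(), p = X.ncol();
  NumericVector eta(n, alpha);
  for (int j = 0; j < p; ++j) {
    double b = beta[j];
    if (b == 0.0) continue;
    for (int i = 0; i < n; ++i) eta[i] += b * X(i, j);
  }
  return eta;
}
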