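#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cox partial log-likelihood for a single covariate with a fixed per-sample
// offset, plus its first two derivatives in the scalar coefficient b.
//
// Inputs must be pre-sorted by increasing observed time (the R wrappers do
// this once per outcome).  Risk sets are right-continuous: a subject with
// observed time t is at risk for an event at time t, and censored subjects
// tied with an event time remain in that event's risk set.  Ties among
// event times are handled by Efron's correction (efron = true) or Breslow's.
//
// All exp() terms are computed after subtracting max(eta); the partial
// log-likelihood is invariant to a constant shift of the linear predictor,
// so the returned value is unchanged while overflow is avoided.

struct CoxEval {
  double loglik;
  double grad;
  double hess;   // d2 loglik / db2 (negative of the observed information)
};

static CoxEval cox_eval(const NumericVector& time,
                        const IntegerVector& status,
                        const double* x,
                        const NumericVector& offset,
                        double b, bool efron) {
  const int n = time.size();
  double mx = -INFINITY;
  std::vector<double> eta(n);
  for (int i = 0; i < n; i++) {
    eta[i] = b * x[i] + offset[i];
    if (eta[i] > mx) mx = eta[i];
  }
  double S = 0.0, Sx = 0.0, Sxx = 0.0;
  double ll = 0.0, g = 0.0, h = 0.0;
  int i = n - 1;
  while (i >= 0) {
    int j = i;
    while (j >= 0 && time[j] == time[i]) j--;
    // subjects (j, i] share one observed time; all enter the risk set now
    double Sd = 0.0, Sdx = 0.0, Sdxx = 0.0, sum_eta = 0.0, sum_x = 0.0;
    int dk = 0;
    for (int k = i; k > j; k--) {
      double e = std::exp(eta[k] - mx);
      double xe = x[k] * e;
      S += e; Sx += xe; Sxx += x[k] * xe;
      if (status[k] == 1) {
        dk++;
        Sd += e; Sdx += xe; Sdxx += x[k] * xe;
        sum_eta += eta[k] - mx;
        sum_x += x[k];
      }
    }
    if (dk > 0) {
      ll += sum_eta;
      g += sum_x;
      for (int r = 0; r < dk; r++) {
        double f = efron ? (double) r / dk : 0.0;
        double D = S - f * Sd;
        double Dx = Sx - f * Sdx;
        double Dxx = Sxx - f * Sdxx;
        double u = Dx / D;
        ll -= std::log(D);
        g -= u;
        h -= (Dxx / D - u * u);
      }
    }
    i = j;
  }
  CoxEval out; out.loglik = ll; out.grad = g; out.hess = h;
  return out;
}

// [[Rcpp::export(name = ".cox_eval_cpp")]]
NumericVector cox_eval_cpp(NumericVector time, IntegerVector status,
                           NumericVector x, NumericVector offset,
                           double b, bool efron) {
  CoxEval e = cox_eval(time, status, REAL(x), offset, b, efron);
  return NumericVector::create(e.loglik, e.grad, e.hess);
}

// Newton-Raphson maximization of the univariate partial likelihood for each
// column of X, with step-halving on likelihood decrease and a cap on |b|
// (complete separation).  Returns a p x 7 matrix with columns
// bhat, se, loglik_mle, loglik_null, converged, degenerate, n_iter.
// [[Rcpp::export(name = ".cox_univariate_batch_cpp")]]
NumericMatrix cox_univariate_batch_cpp(NumericVector time, IntegerVector status,
                                       NumericMatrix X, NumericVector offset,
                                       bool efron, double tol, int max_iter,
                                       double b_cap) {
  const int p = X.ncol();
  NumericMatrix out(p, 7);
  // null partial log-likelihood does not depend on the covariate
  std::vector<double> zero(time.size(), 0.0);
  CoxEval e0 = cox_eval(time, status, zero.data(), offset, 0.0, efron);
  const double ll0 = e0.loglik;

  for (int jcol = 0; jcol < p; jcol++) {
    const double* x = &X(0, jcol);
    CoxEval e = cox_eval(time, status, x, offset, 0.0, efron);
    double info0 = -e.hess;
    // zero within-risk-set variance => the covariate carries no information
    if (!(info0 > 1e-12)) {
      out(jcol, 0) = 0.0;
      out(jcol, 1) = R_PosInf;
      out(jcol, 2) = ll0;
      out(jcol, 3) = ll0;
      out(jcol, 4) = 1.0;
      out(jcol, 5) = 1.0;
      out(jcol, 6) = 0.0;
      continue;
    }
    double b = 0.0;
    bool converged = false, capped = false;
    int it = 0;
    while (it < max_iter) {
      it++;
      if (std::fabs(e.grad) < tol) { converged = true; break; }
      double info = -e.hess;
      double step = (info > 0) ? e.grad / info : ((e.grad > 0) ? 1.0 : -1.0);
      // stop once the proposed step is at the floating-point noise floor:
      // the gradient cannot be driven lower from here
      if (std::fabs(step) < 1e-10 * (1.0 + std::fabs(b))) {
        converged = true;
        break;
      }
      // step-halving on likelihood decrease, with a tolerance scaled to
      // the loglik magnitude so rounding noise does not annihilate steps
      double ll_tol = 1e-9 * (1.0 + std::fabs(e.loglik));
      double bnew = b + step;
      CoxEval enew = cox_eval(time, status, x, offset, bnew, efron);
      int halvings = 0;
      while (enew.loglik < e.loglik - ll_tol && halvings < 30) {
        step *= 0.5;
        bnew = b + step;
        enew = cox_eval(time, status, x, offset, bnew, efron);
        halvings++;
      }
      b = bnew; e = enew;
      if (std::fabs(b) >= b_cap) {
        b = (b > 0) ? b_cap : -b_cap;
        e = cox_eval(time, status, x, offset, b, efron);
        capped = true;
        break;
      }
    }
    if (capped) converged = false;
    double info = -e.hess;
    double se = (info > 0) ? 1.0 / std::sqrt(info) : R_PosInf;
    out(jcol, 0) = b;
    out(jcol, 1) = se;
    out(jcol, 2) = e.loglik;
    out(jcol, 3) = ll0;
    out(jcol, 4) = converged ? 1.0 : 0.0;
    out(jcol, 5) = 0.0;
    out(jcol, 6) = it;
  }
  return out;
}
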