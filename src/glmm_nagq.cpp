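// Marginal log-likelihood of the binomial logit mixed model
//
//   wild_i ~ Binomial(total_i, plogis(x_i'beta + u_{g(i)} + v_i))
//   u_g ~ N(0, sigma_g^2)   (genotype)
//   v_i ~ N(0, sigma_r^2)   (observation-level / biological replicate)
//
// integrated by nested adaptive Gauss-Hermite quadrature: the inner
// observation-level integral is a 1-d function of the linear predictor,
// centred at its conditional mode (Newton), and the outer genotype integral
// is centred likewise, so cost is linear in the number of rows.
//
// The gradient is computed with the adaptive centres held fixed; because the
// quadrature is near-exact at the default node counts this matches the
// objective's gradient to optimizer precision.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double LOG2PI = 1.8378770664093454836;

static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}
static inline double plogis_(double x) {
  if (x >= 0) { double e = std::exp(-x); return 1.0 / (1.0 + e); }
  double e = std::exp(x); return e / (1.0 + e);
}

struct InnerOut {
  double logF;   // log \int N(v;0,sr^2) Binom(w | n, plogis(eta+v)) dv
  double d1;     // d logF / d eta     (fixed nodes)
  double d2;     // d^2 logF / d eta^2 (fixed nodes)
  double gb;     // d logF / d log sr  (fixed nodes)
};

// One observation's inner integral at linear predictor eta.
static InnerOut inner_eval(double eta, double w, double n, double lch,
                           double sr, const NumericVector &z, const NumericVector &lwt,
                           bool need2, bool needgb) {
  InnerOut out;
  if (sr <= 0.0) {
    double p = plogis_(eta);
    out.logF = lch + w * eta - n * log1pexp_(eta);
    out.d1 = w - n * p;
    out.d2 = -n * p * (1.0 - p);
    out.gb = 0.0;
    return out;
  }
  const double isr2 = 1.0 / (sr * sr);
  // Newton for the conditional mode of v (strictly concave objective)
  double v = 0.0, q2 = 0.0;
  for (int it = 0; it < 60; ++it) {
    double p = plogis_(eta + v);
    double q1 = w - n * p - v * isr2;
    q2 = -n * p * (1.0 - p) - isr2;
    double step = q1 / q2;
    v -= step;
    if (std::fabs(step) < 1e-10) break;
  }
  {
    double p = plogis_(eta + v);
    q2 = -n * p * (1.0 - p) - isr2;
  }
  const double shat = 1.0 / std::sqrt(-q2);
  const double base = std::log(M_SQRT2 * shat) - std::log(sr) - 0.5 * LOG2PI + lch;
  const int M = z.size();
  double mx = R_NegInf;
  std::vector<double> lt(M), sm(M), pm(M), vm(M);
  for (int m = 0; m < M; ++m) {
    double vv = v + M_SQRT2 * shat * z[m];
    double x = eta + vv;
    double lq = w * x - n * log1pexp_(x) - 0.5 * vv * vv * isr2;
    double t = base + lwt[m] + z[m] * z[m] + lq;
    lt[m] = t;
    vm[m] = vv;
    pm[m] = plogis_(x);
    if (t > mx) mx = t;
  }
  double s0 = 0.0;
  for (int m = 0; m < M; ++m) { sm[m] = std::exp(lt[m] - mx); s0 += sm[m]; }
  out.logF = mx + std::log(s0);
  double d1 = 0.0, d2a = 0.0, gb = 0.0;
  for (int m = 0; m < M; ++m) {
    double pi_m = sm[m] / s0;
    double s = w - n * pm[m];
    d1 += pi_m * s;
    if (need2) d2a += pi_m * (s * s - n * pm[m] * (1.0 - pm[m]));
    if (needgb) gb += pi_m * (vm[m] * vm[m] * isr2 - 1.0);
  }
  out.d1 = d1;
  out.d2 = need2 ? (d2a - d1 * d1) : 0.0;
  out.gb = gb;
  return out;
}

// rows must be ordered by genotype; gstart has G+1 offsets (0-based) into rows.
// [[Rcpp::export]]
List glmm_nagq_eval(NumericVector beta, double sigma_g, double sigma_r,
                    bool has_g_re, bool has_r_re,
                    NumericVector w, NumericVector n, NumericVector lch,
                    NumericMatrix X, IntegerVector gstart,
                    NumericVector z_out, NumericVector lwt_out,
                    NumericVector z_in, NumericVector lwt_in,
                    bool grad) {
  const int N = w.size(), P = X.ncol(), G = gstart.size() - 1;
  const int K = z_out.size();
  const double sr = has_r_re ? sigma_r : 0.0;
  std::vector<double> eta0(N);
  for (int i = 0; i < N; ++i) {
    double e = 0.0;
    for (int p = 0; p < P; ++p) e += X(i, p) * beta[p];
    eta0[i] = e;
  }
  double ll = 0.0;
  NumericVector gbeta(P);
  double ga = 0.0, gb = 0.0;

  if (!has_g_re) {
    for (int i = 0; i < N; ++i) {
      InnerOut io = inner_eval(eta0[i], w[i], n[i], lch[i], sr, z_in, lwt_in,
                               false, grad && has_r_re);
      ll += io.logF;
      if (grad) {
        for (int p = 0; p < P; ++p) gbeta[p] += io.d1 * X(i, p);
        gb += io.gb;
      }
    }
  } else {
    const double sg = sigma_g, isg2 = 1.0 / (sg * sg);
    for (int g = 0; g < G; ++g) {
      const int i0 = gstart[g], i1 = gstart[g + 1];
      // Newton for the outer mode
      double u = 0.0, H2 = 0.0;
      for (int it = 0; it < 60; ++it) {
        double H1 = -u * isg2;
        H2 = -isg2;
        for (int i = i0; i < i1; ++i) {
          InnerOut io = inner_eval(eta0[i] + u, w[i], n[i], lch[i], sr,
                                   z_in, lwt_in, true, false);
          H1 += io.d1;
          H2 += io.d2;
        }
        if (H2 > -1e-12) H2 = -1e-12;
        double step = H1 / H2;
        u -= step;
        if (std::fabs(step) < 1e-9) break;
      }
      const double shat = 1.0 / std::sqrt(-H2);
      const double base = std::log(M_SQRT2 * shat) - std::log(sg) - 0.5 * LOG2PI;
      double mx = R_NegInf;
      std::vector<double> lt(K), dba, da(K), db(K);
      if (grad) dba.assign((size_t)K * P, 0.0);
      for (int k = 0; k < K; ++k) {
        double uk = u + M_SQRT2 * shat * z_out[k];
        double hk = base + lwt_out[k] + z_out[k] * z_out[k] - 0.5 * uk * uk * isg2;
        double dbk = 0.0;
        for (int i = i0; i < i1; ++i) {
          InnerOut io = inner_eval(eta0[i] + uk, w[i], n[i], lch[i], sr,
                                   z_in, lwt_in, false, grad && has_r_re);
          hk += io.logF;
          if (grad) {
            for (int p = 0; p < P; ++p) dba[(size_t)k * P + p] += io.d1 * X(i, p);
            dbk += io.gb;
          }
        }
        lt[k] = hk;
        da[k] = uk * uk * isg2 - 1.0;
        db[k] = dbk;
        if (hk > mx) mx = hk;
      }
      double s0 = 0.0;
      std::vector<double> ex(K);
      for (int k = 0; k < K; ++k) { ex[k] = std::exp(lt[k] - mx); s0 += ex[k]; }
      ll += mx + std::log(s0);
      if (grad) {
        for (int k = 0; k < K; ++k) {
          double rho = ex[k] / s0;
          for (int p = 0; p < P; ++p) gbeta[p] += rho * dba[(size_t)k * P + p];
          ga += rho * da[k];
          gb += rho * db[k];
        }
      }
    }
  }
  if (!grad) return List::create(_["loglik"] = ll);
  return List::create(_["loglik"] = ll, _["gbeta"] = gbeta,
                      _["glog_sigma_g"] = ga, _["glog_sigma_r"] = gb);
}
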