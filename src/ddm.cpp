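#include <Rcpp.h>
using namespace Rcpp;

// First-passage-time machinery for the two-boundary diffusion decision model.
// Everything is computed on the unit-diffusion scale: a, v, eta are divided by
// the diffusion constant s before entering these routines; time stays in
// seconds.

// Defective FPT density at the LOWER boundary for a zero-drift unit-diffusion
// process with boundary separation 1, relative start w, at scaled time
// tau = t / a^2.  Small-time and large-time series with adaptive truncation:
// the representation needing fewer terms for tolerance eps is used.
static double wfpt_f1(double tau, double w, double eps) {
  if (tau <= 0.0) return 0.0;

  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * tau) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tau *
                         std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tau)));
    ks = std::max(ks, std::sqrt(tau) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * tau * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tau * eps) / (M_PI * M_PI * tau));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tau)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tau));
  }

  double f = 0.0;
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    for (int k = -K; k <= K; k++) {
      double x = w + 2.0 * k;
      f += x * std::exp(-x * x / (2.0 * tau));
    }
    f /= std::sqrt(2.0 * M_PI * tau * tau * tau);
  } else {
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; k++) {
      f += k * std::exp(-k * k * M_PI * M_PI * tau / 2.0) *
           std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return f > 0.0 ? f : 0.0;
}

// Defective density of absorption at one boundary at decision time td, for
// drift v toward the upper boundary, boundary separation a, relative start w,
// diffusion s.  Gaussian intertrial drift variability eta is integrated
// analytically (the exponential drift factor is itself Gaussian in v).
static double dens_one(double td, int upper, double v, double eta, double a,
                       double w, double s, double eps) {
  if (td <= 0.0) return 0.0;
  double as = a / s, vs = v / s, es = eta / s;
  double ww = upper ? 1.0 - w : w;
  double vv = upper ? -vs : vs;
  double tau = td / (as * as);
  double f1 = wfpt_f1(tau, ww, eps);
  if (f1 <= 0.0) return 0.0;
  double b = as * ww;
  double mult;
  if (es > 0.0) {
    double d = 1.0 + es * es * td;
    mult = std::exp((es * es * b * b - 2.0 * vv * b - vv * vv * td) /
                    (2.0 * d)) /
           std::sqrt(d);
  } else {
    mult = std::exp(-vv * b - vv * vv * td / 2.0);
  }
  return f1 * mult / (as * as);
}

// Full defective density at observed RT t: uniform starting-point and
// nondecision-time variability integrated by Gauss-Legendre quadrature
// (nodes gx on [-1,1] with weights gw summing to 2).  Degenerate ranges
// (sz = 0, st = 0) collapse to single-node evaluation and reduce the result
// exactly to the plain density.
static double dens_trial(double t, int upper, double v, double eta, double a,
                         double w, double sz, double ter, double st, double s,
                         const NumericVector &gx, const NumericVector &gw,
                         double eps) {
  int nq = gx.size();
  int nz = (sz > 0.0) ? nq : 1;
  int nt = (st > 0.0) ? nq : 1;
  double out = 0.0;
  for (int j = 0; j < nt; j++) {
    double td = t - ter - ((st > 0.0) ? 0.5 * st * gx[j] : 0.0);
    double wt_t = (st > 0.0) ? 0.5 * gw[j] : 1.0;
    if (td <= 0.0) continue;
    for (int i = 0; i < nz; i++) {
      double wi = w + ((sz > 0.0) ? 0.5 * sz * gx[i] / a : 0.0);
      double wt_z = (sz > 0.0) ? 0.5 * gw[i] : 1.0;
      if (wi <= 0.0 || wi >= 1.0) continue;
      out += wt_t * wt_z * dens_one(td, upper, v, eta, a, wi, s, eps);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector ddm_density_cpp(NumericVector t, IntegerVector upper,
                              NumericVector v, NumericVector eta,
                              NumericVector a, NumericVector w,
                              NumericVector sz, NumericVector ter,
                              NumericVector st, double s, NumericVector gx,
                              NumericVector gw, double eps) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    out[i] = dens_trial(t[i], upper[i], v[i], eta[i], a[i], w[i], sz[i],
                        ter[i], st[i], s, gx, gw, eps);
  }
  return out;
}

// Summed negative log-likelihood with a density floor: trials whose density
// underflows (or falls before the nondecision support) contribute
// log(dfloor) instead of -Inf so the simplex search stays finite.
// [[Rcpp::export]]
double ddm_nll_cpp(NumericVector t, IntegerVector upper, NumericVector v,
                   NumericVector eta, NumericVector a, NumericVector w,
                   NumericVector sz, NumericVector ter, NumericVector st,
                   double s, NumericVector gx, NumericVector gw, double eps,
                   double dfloor) {
  int n = t.size();
  double nll = 0.0;
  for (int i = 0; i < n; i++) {
    double d = dens_trial(t[i], upper[i], v[i], eta[i], a[i], w[i], sz[i],
                          ter[i], st[i], s, gx, gw, eps);
    if (d < dfloor) d = dfloor;
    nll -= std::log(d);
  }
  return nll;
}

// Euler-Maruyama simulator.  Per trial: drift ~ N(v, eta), start ~
// U(z - sz/2, z + sz/2), nondecision ~ U(ter - st/2, ter + st/2); the
// accumulator steps with increment drift*dt + s*sqrt(dt)*N(0,1) until it
// crosses 0 or a.  Non-absorbed paths (t > max_t) are redrawn and counted.
// Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
List ddm_sim_cpp(NumericVector v, NumericVector eta, NumericVector a,
                 NumericVector z, NumericVector sz, NumericVector ter,
                 NumericVector st, double s, double dt, double max_t) {
  int n = v.size();
  NumericVector rt(n);
  IntegerVector up(n);
  int n_redraw = 0;
  double sq = s * std::sqrt(dt);
  for (int i = 0; i < n; i++) {
    bool done = false;
    while (!done) {
      double drift = (eta[i] > 0.0) ? R::rnorm(v[i], eta[i]) : v[i];
      double x = z[i] + ((sz[i] > 0.0) ? R::runif(-0.5 * sz[i], 0.5 * sz[i])
                                       : 0.0);
      double t0 = ter[i] + ((st[i] > 0.0) ? R::runif(-0.5 * st[i], 0.5 * st[i])
                                          : 0.0);
      double tt = 0.0;
      while (tt < max_t) {
        x += drift * dt + sq * R::norm_rand();
        tt += dt;
        if (x >= a[i]) {
          rt[i] = tt + t0;
          up[i] = 1;
          done = true;
          break;
        }
        if (x <= 0.0) {
          rt[i] = tt + t0;
          up[i] = 0;
          done = true;
          break;
        }
      }
      if (!done) n_redraw++;
    }
  }
  return List::create(_["rt"] = rt, _["upper"] = up, _["n_redraw"] = n_redraw);
}
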