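// Drift diffusion core: Wiener first-passage-time density (small/large-time
// series with automatic switch), closed-form integration over normal
// trial-to-trial drift variability, trial-level log-likelihood, and an
// Euler-Maruyama simulator with Brownian-bridge boundary-crossing correction.
//
// Conventions: diffusion coefficient 1; boundary separation a > 0; relative
// starting point w = z / a in (0, 1); upper boundary codes the correct
// response (accuracy coding). Densities are for decision time t - t0.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double SERIES_EPS = 1e-7;   // truncation error bound for the series
static const double TWO_PI = 6.283185307179586;

// Standardized (v = 0, a = 1) first-passage density at the LOWER boundary,
// at normalized time tau = t / a^2, start w. Chooses the series (small- vs
// large-time) needing fewer terms for truncation error < SERIES_EPS.
static double fpt_std(double tau, double w) {
  if (tau <= 0.0) return 0.0;

  // terms needed, Navarro-Fuss style bounds
  double ks, kl;
  if (TWO_PI * tau * SERIES_EPS < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tau * SERIES_EPS) / (M_PI * M_PI * tau));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tau)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tau));
  }
  double tmp = 2.0 * std::sqrt(TWO_PI * tau) * SERIES_EPS;
  if (tmp < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tau * std::log(tmp));
    ks = std::max(ks, std::sqrt(tau) + 1.0);
  } else {
    ks = 2.0;
  }

  double dens = 0.0;
  if (ks < kl) {
    // small-time expansion
    int K = (int)std::ceil(ks);
    int lo = -((K - 1) / 2), hi = K / 2 + ((K % 2) ? 0 : 0);
    // symmetric range covering ceil(ks) terms
    lo = -(int)std::floor((K - 1) / 2.0);
    hi = (int)std::ceil(K / 2.0);
    for (int k = lo; k <= hi; ++k) {
      double x = w + 2.0 * k;
      dens += x * std::exp(-x * x / (2.0 * tau));
    }
    dens /= std::sqrt(TWO_PI * tau * tau * tau);
  } else {
    // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      dens += k * std::exp(-k * k * M_PI * M_PI * tau / 2.0) *
              std::sin(k * M_PI * w);
    }
    dens *= M_PI;
  }
  return dens > 0.0 ? dens : 0.0;
}

// Log density of first passage at the LOWER boundary at decision time t
// (already t0-subtracted), drift v, boundary a, relative start w, drift SD sv.
// The normal mixture over drifts has a closed form: integrating
// exp(-u*a*w - u^2 t / 2) against N(u; v, sv^2) gives
//   (1 + sv^2 t)^(-1/2) * exp((sv^2 a^2 w^2 - 2 a w v - v^2 t) / (2 (1 + sv^2 t))).
static double wfpt_log_lower(double t, double v, double a, double w, double sv) {
  if (t <= 0.0 || a <= 0.0 || w <= 0.0 || w >= 1.0) return R_NegInf;
  double tau = t / (a * a);
  double base = fpt_std(tau, w);
  if (base <= 0.0) return R_NegInf;
  double lg = std::log(base) - 2.0 * std::log(a);
  double s2t = 1.0 + sv * sv * t;
  lg += (sv * sv * a * a * w * w - 2.0 * a * w * v - v * v * t) / (2.0 * s2t) -
        0.5 * std::log(s2t);
  return lg;
}

// boundary: 1 = upper, 0 = lower. Upper-boundary density is the lower-boundary
// density under (v -> -v, w -> 1 - w).
static double wfpt_log_one(double t, int upper, double v, double a, double z,
                           double sv) {
  double w = z / a;
  if (upper) return wfpt_log_lower(t, -v, a, 1.0 - w, sv);
  return wfpt_log_lower(t, v, a, w, sv);
}

// [[Rcpp::export(name = ".wfpt_density_cpp")]]
NumericVector wfpt_density_cpp(NumericVector t, int upper, double v, double a,
                               double z, double t0, double sv) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double ti = t[i];
    if (!R_finite(ti)) stop("non-finite time value");
    double td = ti - t0;
    out[i] = (td <= 0.0) ? 0.0 : std::exp(wfpt_log_one(td, upper, v, a, z, sv));
  }
  return out;
}

// Summed log-likelihood over trials with per-trial parameters (accuracy
// coding: response[i] == 1 means upper boundary). Returns -Inf on any
// invalid trial (rt <= t0, a <= 0, t0 < 0).
// [[Rcpp::export(name = ".ddm_loglik_cpp")]]
double ddm_loglik_cpp(NumericVector rt, IntegerVector response,
                      NumericVector v, NumericVector a, NumericVector t0,
                      double sv) {
  int n = rt.size();
  if (sv < 0.0) return R_NegInf;
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    if (a[i] <= 0.0 || t0[i] < 0.0) return R_NegInf;
    double td = rt[i] - t0[i];
    if (td <= 0.0) return R_NegInf;
    double lg = wfpt_log_one(td, response[i], v[i], a[i], a[i] / 2.0, sv);
    if (!R_finite(lg)) return R_NegInf;
    ll += lg;
  }
  return ll;
}

// ---- xoshiro256++ RNG (own stream so huge simulations are cheap and the
// seed contract is independent of R's generator state) ----
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9E3779B97f4A7C15ULL;
      uint64_t zv = x;
      zv = (zv ^ (zv >> 30)) * 0xBF58476D1CE4E5B9ULL;
      zv = (zv ^ (zv >> 27)) * 0x94D049BB133111EBULL;
      s[i] = zv ^ (zv >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  bool have_spare = false;
  double spare = 0.0;
  double norm() {  // Box-Muller
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = TWO_PI * u2;
    spare = r * std::sin(th);
    have_spare = true;
    return r * std::cos(th);
  }
};

// Euler-Maruyama first-passage simulation with per-step Brownian-bridge
// crossing correction (removes the leading-order discretization bias).
// Per-trial drift is drawn from Normal(v, sv). Returns rt (decision time +
// t0) and accuracy (1 = upper boundary).
// [[Rcpp::export(name = ".ddm_simulate_cpp")]]
List ddm_simulate_cpp(int n, double v, double a, double z, double t0,
                      double sv, double dt, double tmax, double seed) {
  Xoshiro rng((uint64_t)seed);
  NumericVector rt(n);
  IntegerVector acc(n);
  double sdt = std::sqrt(dt);
  for (int i = 0; i < n; ++i) {
    double vi = sv > 0.0 ? v + sv * rng.norm() : v;
    double x = z, t = 0.0;
    int hit = -1;
    while (t < tmax) {
      double xn = x + vi * dt + sdt * rng.norm();
      t += dt;
      if (xn >= a) { hit = 1; break; }
      if (xn <= 0.0) { hit = 0; break; }
      // bridge probability of an unobserved crossing inside the step
      double pu = std::exp(-2.0 * (a - x) * (a - xn) / dt);
      if (rng.unif() < pu) { hit = 1; break; }
      double pl = std::exp(-2.0 * x * xn / dt);
      if (rng.unif() < pl) { hit = 0; break; }
      x = xn;
    }
    if (hit < 0) {  // censored at tmax: assign nearest boundary, flag rt NA
      rt[i] = NA_REAL;
      acc[i] = x >= a / 2.0 ? 1 : 0;
    } else {
      rt[i] = t + t0;
      acc[i] = hit;
    }
  }
  return List::create(_["rt"] = rt, _["accuracy"] = acc);
}
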