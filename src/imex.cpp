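#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One-step IMEX update of the coupled F-actin / length / ATP system.
//
// All linear terms are discretized implicitly; the switching functions K(c)
// and H(c) are evaluated explicitly at the previous state, which keeps every
// sub-update linear and unconditionally stable on the stiff parts
// (sigma/phi is O(10)/s, k + K is O(1e3)/s).  Update order within a step is
// a -> L -> c, each sub-update using the freshest neighbor value.
//
// The hysteresis relay: H follows the rising branch f1 while ATP recharges
// and the falling branch f2 while it drains.  The branch trips when the ATP
// drive dc/dt = lam*(c_h - c) - S_max*R*H under the *current* branch crosses
// a small rate tolerance tol_drive.  The rising branch possesses a stable
// production/release balance point just below c_h (f1 opens continuously),
// so a strict sign-change rule would let the state creep into that balance
// and never trip; tripping at |dc/dt| <= tol_drive instead makes the relay
// turn over at the crest/trough of the charge cycle in a time-step- and
// precision-independent way.  tol_drive is several orders of magnitude below
// every physical rate in the model (the slowest drives are ~1e-5 mM/s).

static inline double K_of(double c, double k1, double k2, double M2,
                          double c_h) {
  if (c >= c_h) return k2;
  return (k1 - k2) * std::exp(-c / (M2 * (c_h - c))) + k2;
}

static inline double sigma_of(double a, double psi, double a_sat) {
  return psi * a * a * std::exp(-a / a_sat);
}

static inline double R_of(double L, double L_min, double M1, double xi) {
  double base = 1.0 - std::exp(-M1 * (L / L_min - xi));
  if (base < 0.0) base = 0.0;
  if (base > 1.0) base = 1.0;
  return base * base * base;
}

static inline double H_of(double c, int branch, double c_L, double c_eq,
                          double c_h, double M3) {
  if (branch == 1) {  // rising: f1
    if (c <= c_eq) return 0.0;
    if (c >= c_h) return 1.0;
    return std::exp(-(c_h - c) / (M3 * (c - c_eq) * (c - c_eq)));
  }
  // falling: f2
  if (c <= c_L) return 0.0;
  if (c >= c_eq) return 1.0;
  return std::exp(-(c_eq - c) / (M3 * (c - c_L) * (c - c_L)));
}

// [[Rcpp::export(name = ".sim_imex")]]
List sim_imex(NumericVector par, double a0, double L0, double c0, int branch0,
              double dt, double n_steps_d, int record_every,
              bool stochastic, double noise_scale, double tol_drive) {
  const double k = par["k"], a_h = par["a_h"], k1 = par["k1"], k2 = par["k2"],
    M1 = par["M1"], M2 = par["M2"], M3 = par["M3"], c_h = par["c_h"],
    c_L = par["c_L"], c_eq = par["c_eq"], lam = par["lam"],
    S_max = par["S_max"], v_p = par["v_p"], phi = par["phi"],
    psi = par["psi"], a_sat = par["a_sat"], beta = par["beta"],
    L_min = par["L_min"];

  const long long n_steps = (long long)n_steps_d;
  const long long n_rec = n_steps / record_every + 1;
  NumericVector tv(n_rec), av(n_rec), Lv(n_rec), cv(n_rec);
  IntegerVector bv(n_rec);

  double a = a0, L = L0, c = c0;
  int branch = branch0;
  const double sqdt = std::sqrt(dt);

  RNGScope scope;  // safe also in deterministic mode (no draws made)

  long long j = 0;
  tv[j] = 0.0; av[j] = a; Lv[j] = L; cv[j] = c; bv[j] = branch; ++j;

  for (long long i = 1; i <= n_steps; ++i) {
    // F-actin, implicit linear part, explicit K(c^n)
    const double K = K_of(c, k1, k2, M2, c_h);
    const double an = (a + dt * k * a_h) / (1.0 + dt * (k + K));

    // length, implicit contraction with the fresh a, Euler-Maruyama noise
    const double sig = sigma_of(an, psi, a_sat);
    double dW = 0.0, xi = 1.0;
    if (stochastic) {
      dW = sqdt * norm_rand();
      if (noise_scale > 0.0) xi = 1.0 + noise_scale * norm_rand();
    }
    const double Ln = (L + dt * v_p / phi + beta * dW) /
                      (1.0 + dt * sig / phi);

    // ATP, implicit production, explicit gate H(c^n) with fresh length in R
    const double R = R_of(Ln, L_min, M1, xi);
    const double H = H_of(c, branch, c_L, c_eq, c_h, M3);
    const double drive = lam * (c_h - c) - S_max * R * H;
    const double cn = (c + dt * (lam * c_h - S_max * R * H)) /
                      (1.0 + dt * lam);

    // relay trip at the crest/trough of the charge cycle
    if (branch == 1 && drive <= tol_drive) branch = 2;
    else if (branch == 2 && drive >= -tol_drive) branch = 1;

    a = an; L = Ln; c = cn;

    if (!(std::isfinite(a) && std::isfinite(L) && std::isfinite(c))) {
      const char *var = !std::isfinite(a) ? "a" : (!std::isfinite(L) ? "L" : "c");
      stop("numerical blow-up in state variable '%s' at t = %g s", var, i * dt);
    }

    if (i % record_every == 0) {
      tv[j] = i * dt; av[j] = a; Lv[j] = L; cv[j] = c; bv[j] = branch; ++j;
    }
  }

  return List::create(_["t"] = tv, _["a"] = av, _["L"] = Lv, _["c"] = cv,
                      _["branch"] = bv);
}
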