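// Hybrid ODE/SDE core for the lineage cell-cycle simulator.
//
// The ODE right-hand sides live here together with a fixed-step RK4 stepper
// and the exact/Euler Ornstein-Uhlenbeck updates for the transcription-rate
// noise channels.  Noise is held constant across the RK4 substeps of each
// noise step dt (operator splitting).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Parameter and state layout (must match R/model.R)
// ---------------------------------------------------------------------------
// mRNA-variant state: CycBm CycB Cdc20m Cdc20T Cdc20A Cdhm Cdht Cdh1 IEP X
// protein-variant state: CycB Cdc20T Cdc20A Cdht Cdh1 IEP X

enum P {
  k1m, Kmm, keff, k1dm, k1, k2a, k2b,
  k5am, k5bm, k5cm, J5c, J5, nH, k5dm,
  k5a, k6, k7, J7, k8, J8, Mad,
  k3m, k3dm, k3a, k3dt, k3, k3b, J3, J4, k4,
  k9, k10, k11, k12, k13, GF, thr,
  NPAR
};

struct Clamp { long n = 0; };

// transcription term with additive OU noise, clamped at zero
static inline double txn(double base, double eps, Clamp &cl) {
  double v = base + eps;
  if (v < 0.0) { cl.n++; return 0.0; }
  return v;
}

// x^n with an integer fast path (the Hill coefficient is almost always 4)
static inline double hpow(double x, double n) {
  int ni = (int)n;
  if ((double)ni == n && ni >= 1 && ni <= 8) {
    double r = x;
    for (int i = 1; i < ni; ++i) r *= x;
    return r;
  }
  return std::pow(x, n);
}

// mRNA-variant right-hand side (10 states)
static inline void rhs_mrna(const double *y, const double *p,
                            const double *eps, const double *mult,
                            double *dy, Clamp &cl) {
  const double g = p[GF] / (p[Kmm] + p[keff] * p[GF]);
  const double cb = y[1];
  const double cbn = hpow(cb, p[nH]);
  const double hill = cbn / (hpow(p[J5], p[nH]) + cbn);
  const double mod = p[J5c] / (p[k5cm] + p[GF]);

  dy[0] = txn(mult[0] * p[k1m], eps[0], cl) * g - p[k1dm] * y[0];
  dy[1] = p[k1] * y[0] - p[k2a] * cb - p[k2b] * cb * y[7];
  dy[2] = txn(mult[1] * p[k5am], eps[1], cl) +
          txn(mult[1] * p[k5bm], eps[2], cl) * mod * hill - p[k5dm] * y[2];
  dy[3] = p[k5a] * y[2] - p[k6] * y[3];
  dy[4] = p[k7] * y[8] * (y[3] - y[4]) / (p[J7] + y[3] - y[4]) -
          p[k8] * p[Mad] * y[4] / (p[J8] + y[4]) - p[k6] * y[4];
  dy[5] = txn(mult[2] * p[k3m], eps[3], cl) - p[k3dm] * y[5];
  dy[6] = p[k3a] * y[5] - p[k3dt] * y[6];
  dy[7] = (p[k3] + p[k3b] * y[4]) * (y[6] - y[7]) / (p[J3] + y[6] - y[7]) -
          p[k4] * cb * y[7] / (p[J4] + y[7]) - p[k3dt] * y[7];
  dy[8] = p[k9] * cb * (1.0 - y[8]) - p[k10] * y[8];
  dy[9] = p[k11] - p[k12] * cb * y[9] - p[k13] * y[9];
}

// protein-noise variant (7 states): mRNA equations removed, OU noise and the
// inherited multipliers act directly on the protein production terms.  The
// production constants are the quasi-steady synthesis fluxes of the mRNA
// variant: k1 * k1m / k1dm etc., precomputed on the R side and stored in the
// k1m / k5am / k5bm / k3m slots of the parameter vector.
static inline void rhs_protein(const double *y, const double *p,
                               const double *eps, const double *mult,
                               double *dy, Clamp &cl) {
  const double g = p[GF] / (p[Kmm] + p[keff] * p[GF]);
  const double cb = y[0];
  const double cbn = hpow(cb, p[nH]);
  const double hill = cbn / (hpow(p[J5], p[nH]) + cbn);
  const double mod = p[J5c] / (p[k5cm] + p[GF]);

  dy[0] = txn(mult[0] * p[k1m], eps[0], cl) * g - p[k2a] * cb - p[k2b] * cb * y[4];
  dy[1] = txn(mult[1] * p[k5am], eps[1], cl) +
          txn(mult[1] * p[k5bm], eps[2], cl) * mod * hill - p[k6] * y[1];
  dy[2] = p[k7] * y[5] * (y[1] - y[2]) / (p[J7] + y[1] - y[2]) -
          p[k8] * p[Mad] * y[2] / (p[J8] + y[2]) - p[k6] * y[2];
  dy[3] = txn(mult[2] * p[k3m], eps[3], cl) - p[k3dt] * y[3];
  dy[4] = (p[k3] + p[k3b] * y[2]) * (y[3] - y[4]) / (p[J3] + y[3] - y[4]) -
          p[k4] * cb * y[4] / (p[J4] + y[4]) - p[k3dt] * y[4];
  dy[5] = p[k9] * cb * (1.0 - y[5]) - p[k10] * y[5];
  dy[6] = p[k11] - p[k12] * cb * y[6] - p[k13] * y[6];
}

static inline int nstate(int variant) { return variant == 0 ? 10 : 7; }
static inline int icycb(int variant) { return variant == 0 ? 1 : 0; }
static inline int ix(int variant) { return variant == 0 ? 9 : 6; }
// IEP is the active fraction of a pool normalised to total 1: equal
// distribution of content between daughters leaves a fraction unchanged,
// so division-by-halving skips it
static inline int iiep(int variant) { return variant == 0 ? 8 : 5; }

static inline void rhs(const double *y, const double *p, const double *eps,
                       const double *mult, double *dy, Clamp &cl, int variant) {
  if (variant == 0) rhs_mrna(y, p, eps, mult, dy, cl);
  else rhs_protein(y, p, eps, mult, dy, cl);
}

// one RK4 step of size h with frozen noise; negative concentrations produced
// by discretisation overshoot are clipped to zero
static void rk4_step(double *y, const double *p, const double *eps,
                     const double *mult, double h, Clamp &cl, int variant) {
  const int ns = nstate(variant);
  double k1v[10], k2v[10], k3v[10], k4v[10], tmp[10];
  rhs(y, p, eps, mult, k1v, cl, variant);
  for (int i = 0; i < ns; ++i) tmp[i] = y[i] + 0.5 * h * k1v[i];
  rhs(tmp, p, eps, mult, k2v, cl, variant);
  for (int i = 0; i < ns; ++i) tmp[i] = y[i] + 0.5 * h * k2v[i];
  rhs(tmp, p, eps, mult, k3v, cl, variant);
  for (int i = 0; i < ns; ++i) tmp[i] = y[i] + h * k3v[i];
  rhs(tmp, p, eps, mult, k4v, cl, variant);
  for (int i = 0; i < ns; ++i) {
    y[i] += h / 6.0 * (k1v[i] + 2.0 * k2v[i] + 2.0 * k3v[i] + k4v[i]);
    if (y[i] < 0.0) y[i] = 0.0;
  }
}

// ---------------------------------------------------------------------------
// RNG: splitmix64 seed expansion + xoshiro-free normal draws via mt19937_64
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t &s) {
  uint64_t z = (s += 0x9E3779B97f4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// Small self-contained generator: 64-bit state, polar normal draws.  Using a
// fixed algorithm (not std::normal_distribution) keeps streams bit-identical
// across standard libraries.
struct Rng {
  uint64_t s;
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : s(seed) {
    for (int i = 0; i < 4; ++i) splitmix64(s);  // warm up
  }
  double unif() {
    // 53-bit uniform in (0,1)
    uint64_t u = splitmix64(s);
    return ((u >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, r2;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      r2 = u * u + v * v;
    } while (r2 >= 1.0 || r2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(r2) / r2);
    spare = v * f;
    have_spare = true;
    return u * f;
  }
};

static inline uint64_t cell_seed(int master, int run_index, int cell_index) {
  uint64_t s = (uint64_t)(uint32_t)master;
  s = s * 0x9E3779B97f4A7C15ULL + (uint64_t)(uint32_t)run_index;
  splitmix64(s);
  s += (uint64_t)(uint32_t)cell_index;
  splitmix64(s);
  return s;
}

// OU update, exact (mode 0) or Euler-Maruyama (mode 1)
static inline double ou_update(double v, double tau, double Dprime, double dt,
                               int mode, Rng &rng) {
  if (mode == 0) {
    const double a = std::exp(-dt / tau);
    const double sd = std::sqrt((Dprime / tau) * (1.0 - a * a));
    return v * a + sd * rng.norm();
  }
  return v * (1.0 - dt / tau) + std::sqrt(2.0 * Dprime * dt) / tau * rng.norm();
}

// ---------------------------------------------------------------------------
// Exported routines
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cc_rhs")]]
NumericVector cc_rhs(NumericVector y, NumericVector p, NumericVector eps,
                     NumericVector mult, int variant) {
  if (p.size() != NPAR) stop("parameter vector has wrong length");
  const int ns = nstate(variant);
  if (y.size() != ns) stop("state vector has wrong length");
  for (int i = 0; i < ns; ++i)
    if (!std::isfinite(y[i])) stop("non-finite state");
  for (int i = 0; i < NPAR; ++i)
    if (!std::isfinite(p[i])) stop("non-finite parameter");
  NumericVector dy(ns);
  Clamp cl;
  rhs(REAL(y), REAL(p), REAL(eps), REAL(mult), REAL(dy), cl, variant);
  dy.attr("clamped") = (double)cl.n;
  return dy;
}

// deterministic fixed-step integration; records every `every`-th step
// [[Rcpp::export(name = ".cc_integrate")]]
List cc_integrate(NumericVector p, NumericVector y0, double t0, double horizon,
                  double dt, int nsub, int variant, int every) {
  const int ns = nstate(variant);
  if (y0.size() != ns) stop("state vector has wrong length");
  const long nstep = (long)std::ceil((horizon - t0) / dt - 1e-9);
  const long nrec = nstep / every + 1;
  NumericMatrix out(nrec, ns + 1);
  std::vector<double> y(REAL(y0), REAL(y0) + ns);
  double eps[4] = {0, 0, 0, 0};
  double mult[3] = {1, 1, 1};
  Clamp cl;
  const double h = dt / nsub;
  long r = 0;
  out(r, 0) = t0;
  for (int i = 0; i < ns; ++i) out(r, i + 1) = y[i];
  r++;
  for (long s = 1; s <= nstep; ++s) {
    for (int k = 0; k < nsub; ++k) rk4_step(y.data(), REAL(p), eps, mult, h, cl, variant);
    for (int i = 0; i < ns; ++i)
      if (!std::isfinite(y[i]))
        stop("integration failure (non-finite state) at t = %f", t0 + s * dt);
    if (s % every == 0) {
      out(r, 0) = t0 + s * dt;
      for (int i = 0; i < ns; ++i) out(r, i + 1) = y[i];
      r++;
    }
  }
  return List::create(_["trajectory"] = out, _["clamped"] = (double)cl.n);
}

// stochastic propagation of a single cell from birth to division (or horizon);
// Dprime is per noise channel (length 4) so variants can scale channels
// [[Rcpp::export(name = ".cc_propagate")]]
List cc_propagate(NumericVector p, NumericVector y0, NumericVector mult,
                  NumericVector ou0, double tau, NumericVector Dprime, double dt,
                  int nsub, double t0, double horizon, int master, int run_index,
                  int cell_index, int ou_mode, int variant, double arm_factor) {
  const int ns = nstate(variant);
  if (y0.size() != ns) stop("state vector has wrong length");
  const int icb = icycb(variant), iX = ix(variant);
  const double threshold = p[thr];
  const double arm_level = arm_factor * threshold;
  std::vector<double> y(REAL(y0), REAL(y0) + ns);
  double eps[4] = {ou0[0], ou0[1], ou0[2], ou0[3]};
  double mlt[3] = {mult[0], mult[1], mult[2]};
  Rng rng(cell_seed(master, run_index, cell_index));
  Clamp cl;
  const double h = dt / nsub;

  bool armed = false;
  double t_div = NA_REAL, t_g1 = NA_REAL;
  double x_pp = y[iX], x_p = y[iX];  // two previous X samples for peak detection
  long step = 0;
  const long max_steps = (long)std::ceil((horizon - t0) / dt - 1e-9);

  std::vector<double> ydiv(ns, NA_REAL), yprev(ns);
  double oudiv[4] = {NA_REAL, NA_REAL, NA_REAL, NA_REAL};

  while (step < max_steps) {
    for (int c = 0; c < 4; ++c) eps[c] = ou_update(eps[c], tau, Dprime[c], dt, ou_mode, rng);
    for (int i = 0; i < ns; ++i) yprev[i] = y[i];
    for (int k = 0; k < nsub; ++k) rk4_step(y.data(), REAL(p), eps, mlt, h, cl, variant);
    step++;
    const double t = t0 + step * dt;
    for (int i = 0; i < ns; ++i)
      if (!std::isfinite(y[i]))
        stop("integration failure (non-finite state) at t = %f", t);

    // G1 end: first local maximum of X (three-point rule on the dt grid)
    if (!R_finite(t_g1) && step >= 2 && x_p > x_pp && x_p >= y[iX]) {
      t_g1 = t - dt;
    }
    x_pp = x_p;
    x_p = y[iX];

    if (!armed && y[icb] > arm_level) armed = true;
    if (armed && yprev[icb] > threshold && y[icb] <= threshold) {
      // locate the crossing within the step by linear interpolation and
      // hand daughters the interpolated division state
      const double f = (yprev[icb] - threshold) / (yprev[icb] - y[icb]);
      t_div = t - dt + f * dt;
      for (int i = 0; i < ns; ++i) ydiv[i] = yprev[i] + f * (y[i] - yprev[i]);
      ydiv[icb] = threshold;
      for (int c = 0; c < 4; ++c) oudiv[c] = eps[c];
      break;
    }
  }

  return List::create(
    _["t_div"] = t_div, _["t_g1"] = t_g1,
    _["y_div"] = NumericVector(ydiv.begin(), ydiv.end()),
    _["ou_div"] = NumericVector(oudiv, oudiv + 4),
    _["y_end"] = NumericVector(y.begin(), y.end()),
    _["clamped"] = (double)cl.n);
}

// deterministic generational map: from a division-point state, halve all
// variables, integrate to the next armed downward threshold crossing, and
// repeat; the converged inter-division interval is the cycle duration of
// the division protocol.  Also returns the state `lead` hours before the
// final division (founder initialisation).
// [[Rcpp::export(name = ".cc_generation_map")]]
List cc_generation_map(NumericVector p, NumericVector y0, double dt, int nsub,
                       int variant, int n_gens, double arm_factor, double lead,
                       double max_gen_horizon, bool halve) {
  const int ns = nstate(variant);
  if (y0.size() != ns) stop("state vector has wrong length");
  const int icb = icycb(variant), iX = ix(variant);
  const double threshold = p[thr];
  const double arm_level = arm_factor * threshold;
  const double eps[4] = {0, 0, 0, 0};
  const double mlt[3] = {1, 1, 1};
  const double h = dt / nsub;
  const long max_steps = (long)std::ceil(max_gen_horizon / dt);

  std::vector<double> y(REAL(y0), REAL(y0) + ns);
  NumericVector durations(n_gens, NA_REAL), g1s(n_gens, NA_REAL);
  NumericVector ylead(ns, NA_REAL), ydiv(ns, NA_REAL);
  Clamp cl;
  std::vector<double> trajbuf;

  const int iep_idx = iiep(variant);
  for (int g = 0; g < n_gens; ++g) {
    if (halve)
      for (int i = 0; i < ns; ++i)
        if (i != iep_idx) y[i] *= 0.5;
    const bool record = (g == n_gens - 1) && lead > 0;
    if (record) {
      trajbuf.clear();
      trajbuf.reserve((size_t)(max_steps + 1) * ns);
      for (int i = 0; i < ns; ++i) trajbuf.push_back(y[i]);
    }
    bool armed = false;
    double t_div = NA_REAL, t_g1 = NA_REAL;
    double x_pp = y[iX], x_p = y[iX];
    long step = 0;
    std::vector<double> yprev(ns);
    while (step < max_steps) {
      for (int i = 0; i < ns; ++i) yprev[i] = y[i];
      for (int k = 0; k < nsub; ++k)
        rk4_step(y.data(), REAL(p), eps, mlt, h, cl, variant);
      step++;
      const double t = step * dt;
      for (int i = 0; i < ns; ++i)
        if (!std::isfinite(y[i]))
          stop("integration failure (non-finite state) at generation %d", g + 1);
      if (record)
        for (int i = 0; i < ns; ++i) trajbuf.push_back(y[i]);
      if (!R_finite(t_g1) && step >= 2 && x_p > x_pp && x_p >= y[iX])
        t_g1 = t - dt;
      x_pp = x_p;
      x_p = y[iX];
      if (!armed && y[icb] > arm_level) armed = true;
      if (armed && yprev[icb] > threshold && y[icb] <= threshold) {
        const double f = (yprev[icb] - threshold) / (yprev[icb] - y[icb]);
        t_div = t - dt + f * dt;
        // restart the next generation from the interpolated division state
        for (int i = 0; i < ns; ++i) y[i] = yprev[i] + f * (y[i] - yprev[i]);
        break;
      }
    }
    if (!R_finite(t_div)) {
      // no division this generation: report what we have
      return List::create(_["durations"] = durations, _["g1"] = g1s,
                          _["y_div"] = ydiv, _["y_lead"] = ylead,
                          _["converged"] = false);
    }
    durations[g] = t_div;
    g1s[g] = t_g1;
    if (record && t_div > lead) {
      const double tw = t_div - lead;
      const long j = (long)std::floor(tw / dt);
      const double fr = tw / dt - j;
      for (int i = 0; i < ns; ++i)
        ylead[i] = trajbuf[j * ns + i] * (1 - fr) + trajbuf[(j + 1) * ns + i] * fr;
    }
    y[icb] = threshold;
    for (int i = 0; i < ns; ++i) ydiv[i] = y[i];
  }
  return List::create(_["durations"] = durations, _["g1"] = g1s,
                      _["y_div"] = ydiv, _["y_lead"] = ylead,
                      _["converged"] = true);
}

// standalone OU series for the noise module (n steps, returns the series)
// [[Rcpp::export(name = ".cc_ou_series")]]
NumericVector cc_ou_series(long n, double value0, double tau, double Dprime,
                           double dt, int mode, int master, int stream) {
  NumericVector out(n);
  Rng rng(cell_seed(master, stream, 0));
  double v = value0;
  for (long i = 0; i < n; ++i) {
    v = ou_update(v, tau, Dprime, dt, mode, rng);
    out[i] = v;
  }
  return out;
}

// single OU step used by the R-level OUProcess object
// [[Rcpp::export(name = ".cc_ou_step")]]
double cc_ou_step_export(double value, double tau, double Dprime, double dt,
                         int mode, double gauss) {
  if (mode == 0) {
    const double a = std::exp(-dt / tau);
    return value * a + std::sqrt((Dprime / tau) * (1.0 - a * a)) * gauss;
  }
  return value * (1.0 - dt / tau) + std::sqrt(2.0 * Dprime * dt) / tau * gauss;
}
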