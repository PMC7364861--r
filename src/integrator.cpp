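// Adaptive Dormand-Prince 5(4) integration of the HPA circuit variants.
//
// The system is mildly stiff: hormone removal rates are per-minute
// (fastest eigenvalue ~ w1 = 0.17/min) while gland-mass turnover is
// per-day, a ~2500-fold timescale separation.  An explicit method is
// used with a max step kept inside the DP5 stability interval
// (|h*lambda| < ~3.3), so long horizons cost ~1e5 cheap RHS
// evaluations rather than requiring an implicit solver.
//
// All times are minutes; all rates per minute.  Within one call the
// input u(t) is a single smooth piece (constant or exponential decay
// toward a baseline) and the exogenous-CRH dose is constant; the R
// driver splits scenarios at every discontinuity.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

enum Variant { FULL = 0, CLASSIC = 1, GRRES = 2, SLOWCLEAR = 3 };

struct Pars {
  double w1, w2, w3, wC, wA, KGR, n, wCRHE, wR, wCR, lam;
  double gnorm; // G evaluated at the variant's basal (x3, R); makes baseline exact
};

static inline double hillG(double x3, double R, double KGR, double n) {
  return 1.0 / (1.0 + std::pow(R * x3 / KGR, n));
}

// u(t) on a smooth piece: utype 0 = constant u0; 1 = ubase + (u0-ubase)*exp(-(t-ut0)/utau)
static inline double input_u(double t, int utype, double u0, double ubase,
                             double utau, double ut0) {
  if (utype == 0) return u0;
  return ubase + (u0 - ubase) * std::exp(-(t - ut0) / utau);
}

static inline int state_dim(int variant) {
  switch (variant) {
  case FULL: return 6;      // x1 x2 x3 C A x1E
  case CLASSIC: return 4;   // x1 x2 x3 x1E
  default: return 5;        // + R or C_R
  }
}

static void rhs(int variant, double t, const double *y, double *dy,
                const Pars &p, int utype, double u0, double ubase,
                double utau, double ut0, double dose) {
  const double x1 = y[0], x2 = y[1], x3 = y[2];
  double C = 1.0, A = 1.0, R = 1.0, CR = 1.0;
  int iE = 3;
  switch (variant) {
  case FULL:      C = y[3]; A = y[4]; iE = 5; break;
  case CLASSIC:   break;
  case GRRES:     R = y[4]; break;
  case SLOWCLEAR: CR = y[4]; break;
  }
  const double x1E = y[iE];
  const double u = input_u(t, utype, u0, ubase, utau, ut0);

  const double G = hillG(x3, R, p.KGR, p.n);
  const double g2 = G / p.gnorm;       // baseline-normalized GR feedback
  const double g1 = g2 / x3;           // MR (1/x3) times GR, normalized

  dy[0] = p.w1 * (u * g1 - x1);
  dy[1] = p.w2 * (C * g2 * (x1 + x1E) - x2);
  dy[2] = p.w3 * (A * x2 - (variant == SLOWCLEAR ? x3 / CR : x3));
  if (variant == FULL) {
    dy[3] = p.wC * C * (x1 - 1.0);
    dy[4] = p.wA * A * (x2 - 1.0);
  } else if (variant == GRRES) {
    dy[4] = p.wR * (1.0 - (1.0 + p.lam * x3 * x3) * R);
  } else if (variant == SLOWCLEAR) {
    dy[4] = p.wCR * (x3 - CR);
  }
  dy[iE] = p.wCRHE * (dose - x1E);
}

// Dormand-Prince 5(4) tableau
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// [[Rcpp::export]]
List hpa_integrate_piece(int variant, NumericVector y0, double t0, double t1,
                         int utype, double u0, double ubase, double utau,
                         double ut0, double dose, List pars, double rtol,
                         double atol, double hmax, NumericVector tout) {
  const int d = state_dim(variant);
  if (y0.size() != d) stop("state vector has length %d, expected %d for this variant",
                           (int)y0.size(), d);
  Pars p;
  p.w1 = pars["w1"]; p.w2 = pars["w2"]; p.w3 = pars["w3"];
  p.wC = pars["wC"]; p.wA = pars["wA"];
  p.KGR = pars["K_GR"]; p.n = pars["n"]; p.wCRHE = pars["wCRHE"];
  p.wR = pars["wR"]; p.wCR = pars["wCR"]; p.lam = pars["lam"];
  p.gnorm = pars["gnorm"];

  const double floor_pos = 1e-9;
  const int nout = tout.size();
  NumericMatrix out(nout, d);

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(d), k2(d), k3(d), k4(d), k5(d), k6(d), k7(d),
      ytmp(d), ynew(d), yerr(d);

  double t = t0;
  double h = std::min(hmax, (t1 - t0));
  if (h <= 0) stop("empty integration interval [%g, %g]", t0, t1);
  int iout = 0;
  long nsteps = 0;
  const long max_steps = 50000000L;

  rhs(variant, t, y.data(), k1.data(), p, utype, u0, ubase, utau, ut0, dose);

  while (t < t1 - 1e-12 * std::max(1.0, std::fabs(t1))) {
    if (++nsteps > max_steps) stop("step budget exceeded at t = %g min", t);
    // never straddle the interval end or the next requested output time
    double tstop = t1;
    if (iout < nout && tout[iout] < tstop) tstop = tout[iout];
    if (t + h > tstop) h = tstop - t;

    for (int i = 0; i < d; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
    rhs(variant, t + c2 * h, ytmp.data(), k2.data(), p, utype, u0, ubase, utau, ut0, dose);
    for (int i = 0; i < d; ++i) ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    rhs(variant, t + c3 * h, ytmp.data(), k3.data(), p, utype, u0, ubase, utau, ut0, dose);
    for (int i = 0; i < d; ++i) ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    rhs(variant, t + c4 * h, ytmp.data(), k4.data(), p, utype, u0, ubase, utau, ut0, dose);
    for (int i = 0; i < d; ++i)
      ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    rhs(variant, t + c5 * h, ytmp.data(), k5.data(), p, utype, u0, ubase, utau, ut0, dose);
    for (int i = 0; i < d; ++i)
      ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] + a64 * k4[i] + a65 * k5[i]);
    rhs(variant, t + h, ytmp.data(), k6.data(), p, utype, u0, ubase, utau, ut0, dose);
    for (int i = 0; i < d; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] + b6 * k6[i]);
    rhs(variant, t + h, ynew.data(), k7.data(), p, utype, u0, ubase, utau, ut0, dose);

    double err = 0.0;
    bool bad = false;
    for (int i = 0; i < d; ++i) {
      yerr[i] = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                     e6 * k6[i] + e7 * k7[i]);
      if (!std::isfinite(ynew[i])) { bad = true; break; }
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = yerr[i] / sc;
      err += r * r;
    }
    // x3 must stay positive within a step (M(x3)=1/x3 singularity)
    if (!bad && ynew[2] <= floor_pos) bad = true;
    err = bad ? 1e10 : std::sqrt(err / d);

    if (err <= 1.0) { // accept
      t += h;
      y.swap(ynew);
      std::swap(k1, k7); // FSAL
      // positivity floor on hormones and masses (x1E may be exactly 0)
      for (int i = 0; i < d; ++i) {
        bool isE = (variant == FULL ? i == 5 : i == 3);
        if (!isE && y[i] <= floor_pos)
          stop("state component %d reached the positivity floor at t = %g min", i + 1, t);
      }
      while (iout < nout &&
             tout[iout] <= t + 1e-9 * std::max(1.0, std::fabs(t))) {
        for (int i = 0; i < d; ++i) out(iout, i) = y[i];
        ++iout;
      }
      double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
      h *= std::min(5.0, std::max(0.2, fac));
    } else { // reject
      double fac = 0.9 * std::pow(err, -0.2);
      h *= std::max(0.1, fac);
      if (h < 1e-10)
        stop("step size collapsed below 1e-10 min at t = %g min", t);
    }
    if (h > hmax) h = hmax;
  }
  // any trailing output times equal to t1 (numerical guard)
  while (iout < nout) {
    for (int i = 0; i < d; ++i) out(iout, i) = y[i];
    ++iout;
  }
  return List::create(_["states"] = out,
                      _["yend"] = NumericVector(y.begin(), y.end()),
                      _["nsteps"] = (double)nsteps);
}

// Single RHS evaluation, exposed so the R-level rhs surfaces and the
// compiled integrator share one definition.
// [[Rcpp::export]]
NumericVector hpa_rhs_eval(int variant, double t, NumericVector y, List pars,
                           double u, double dose) {
  const int d = state_dim(variant);
  if (y.size() != d) stop("state vector has length %d, expected %d for this variant",
                          (int)y.size(), d);
  Pars p;
  p.w1 = pars["w1"]; p.w2 = pars["w2"]; p.w3 = pars["w3"];
  p.wC = pars["wC"]; p.wA = pars["wA"];
  p.KGR = pars["K_GR"]; p.n = pars["n"]; p.wCRHE = pars["wCRHE"];
  p.wR = pars["wR"]; p.wCR = pars["wCR"]; p.lam = pars["lam"];
  p.gnorm = pars["gnorm"];
  NumericVector dy(d);
  rhs(variant, t, y.begin(), dy.begin(), p, 0, u, u, 1.0, 0.0, dose);
  return dy;
}
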