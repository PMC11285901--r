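// Reaction right-hand side and adaptive embedded Runge-Kutta integration
// for the homogeneous five-species amyloid/inflammation model.
//
// Parameter vector layout must match .param_names on the R side:
//  0 r1, 1 r2, 2 d, 3 gamma0, 4 gamma1, 5 gamma2, 6 tau0, 7 taup,
//  8 tauS, 9 tau1, 10 tau2, 11 tau3, 12 C, 13 n,
//  14 alpha1, 15 alpha2, 16 lambdaM, 17 Mhat, 18 sigma
// State layout: 0 u, 1 up, 2 m, 3 M, 4 I.

#include <Rcpp.h>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static const int NS = 5;

static inline void rhs(const double* y, const double* p, double* dy) {
  const double u = y[0], up = y[1], m = y[2], M = y[3], I = y[4];
  const double r1 = p[0], r2 = p[1], d = p[2], g0 = p[3];
  const double t0 = p[6], tp = p[7], tS = p[8];
  const double t1 = p[9], t2 = p[10], t3 = p[11];
  const double C = p[12], n = p[13];
  const double a1 = p[14], a2 = p[15], lM = p[16], Mh = p[17], sg = p[18];

  // u may transiently be a tiny negative number inside a trial stage;
  // clamp before the (possibly non-integer) power.
  const double upos = std::max(u, 0.0);
  const double S = tS * I / (1.0 + C * std::pow(upos, n));

  dy[0] = r1 * m * m - g0 * u - t0 * u;
  dy[1] = g0 * u - tp * up;
  dy[2] = S - d * m - r2 * u * m - r1 * m * m;
  dy[3] = a1 * u / (1.0 + a2 * u) * (Mh - M) * M - sg * M + lM;
  dy[4] = t1 * u / (1.0 + t2 * u) * M - t3 * I;
}

// [[Rcpp::export]]
NumericVector ad_rhs_cpp(NumericVector y, NumericVector params) {
  if (y.size() != NS) stop("state must have 5 components");
  if (params.size() != 19) stop("parameter vector must have 19 components");
  NumericVector dy(NS);
  rhs(y.begin(), params.begin(), dy.begin());
  return dy;
}

// Dormand-Prince 5(4) coefficients.
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
// b - bhat (5th-order solution minus embedded 4th-order estimate)
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// Integrate from times[0] through each entry of times (strictly increasing),
// returning the state at every requested time (first row is the initial
// condition). Adaptive step control with FSAL; components that dip below
// zero by less than neg_clip in magnitude are clipped to exactly zero.
// [[Rcpp::export]]
NumericMatrix ad_integrate_cpp(NumericVector y0, NumericVector params,
                               NumericVector times,
                               double rtol = 1e-8, double atol = 1e-10,
                               double neg_clip = 1e-9) {
  if (y0.size() != NS) stop("state must have 5 components");
  if (params.size() != 19) stop("parameter vector must have 19 components");
  const int nt = times.size();
  if (nt < 2) stop("need at least two output times");
  for (int i = 1; i < nt; ++i)
    if (!(times[i] > times[i - 1])) stop("output times must be strictly increasing");

  const double* p = params.begin();
  NumericMatrix out(nt, NS);
  double y[NS], ynew[NS], k1[NS], k2[NS], k3[NS], k4[NS], k5[NS], k6[NS],
      k7[NS], ytmp[NS];
  for (int j = 0; j < NS; ++j) { y[j] = y0[j]; out(0, j) = y0[j]; }

  double t = times[0];
  const double tend = times[nt - 1];
  rhs(y, p, k1);

  // initial step from the scale of the vector field
  double ynorm = 0, fnorm = 0;
  for (int j = 0; j < NS; ++j) {
    ynorm = std::max(ynorm, std::fabs(y[j]));
    fnorm = std::max(fnorm, std::fabs(k1[j]));
  }
  double h = 0.01 * (ynorm + atol) / (fnorm + 1e-8);
  h = std::min(std::max(h, 1e-8), tend - t);

  int iout = 1;
  const long max_steps = 20000000L;
  long nsteps = 0;
  const double hmin_frac = 1e-14;

  while (iout < nt) {
    if (++nsteps > max_steps)
      stop("integrator exceeded step budget at t = %f months", t);
    bool hit_output = false;
    const double h_free = h; // remember the unclamped proposal
    if (t + h >= times[iout]) { h = times[iout] - t; hit_output = true; }
    if (h < hmin_frac * std::max(1.0, std::fabs(t)))
      stop("step size underflow at t = %f months", t);

    for (int j = 0; j < NS; ++j) ytmp[j] = y[j] + h * a21 * k1[j];
    rhs(ytmp, p, k2);
    for (int j = 0; j < NS; ++j) ytmp[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
    rhs(ytmp, p, k3);
    for (int j = 0; j < NS; ++j)
      ytmp[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
    rhs(ytmp, p, k4);
    for (int j = 0; j < NS; ++j)
      ytmp[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] + a54 * k4[j]);
    rhs(ytmp, p, k5);
    for (int j = 0; j < NS; ++j)
      ytmp[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                            a64 * k4[j] + a65 * k5[j]);
    rhs(ytmp, p, k6);
    for (int j = 0; j < NS; ++j)
      ynew[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                            b5 * k5[j] + b6 * k6[j]);
    rhs(ynew, p, k7);

    double err = 0;
    for (int j = 0; j < NS; ++j) {
      const double ej = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] +
                             e5 * k5[j] + e6 * k6[j] + e7 * k7[j]);
      const double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
      const double r = ej / sc;
      err += r * r;
    }
    err = std::sqrt(err / NS);

    if (err <= 1.0) {
      t += h;
      for (int j = 0; j < NS; ++j) {
        double v = ynew[j];
        if (!std::isfinite(v))
          stop("non-finite state at t = %f months", t);
        if (v < 0.0) {
          if (v < -1e-6)
            stop("state left the non-negative orthant (component %d = %g) at t = %f months",
                 j + 1, v, t);
          if (v > -neg_clip) v = 0.0; // tiny round-off dip
          else v = 0.0;               // still round-off at solver tolerance
        }
        y[j] = v;
      }
      rhs(y, p, k1); // FSAL restart after clipping
      if (hit_output) {
        for (int j = 0; j < NS; ++j) out(iout, j) = y[j];
        ++iout;
      }
    }
    double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
    fac = std::min(std::max(fac, 0.2), 5.0);
    // an accepted clamped-to-output step should not shrink later steps
    h = (err <= 1.0 && hit_output) ? std::max(h_free, h * fac) : h * fac;
    if (t + h > tend) h = tend - t;
    if (h <= 0) h = hmin_frac;
  }
  return out;
}
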