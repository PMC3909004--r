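#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Five-compartment right-hand side.  State layout: (X, S, R1, R2, R3).
// infRate[i]  = beta * (1 - cost_i)   transmission coefficient of strain i
// supRate[i]  = sigma * cost_i * beta superinfection takeover of strain i by S
// g[i]        = pharmacodynamic net growth of strain i under the doses in force
// All gains balance losses exactly, so the components always sum to zero.
static inline void rhs(const double *y, const double *g,
                       const double *infRate, const double *supRate,
                       double gamma, bool pin, double *dy) {
  const double x = y[0];
  const double *comp = y + 1;
  const double s = comp[0];
  double inf[4], clr[4], sup[4];
  double infSum = 0.0, clrSum = 0.0, supSum = 0.0;
  for (int i = 0; i < 4; ++i) {
    inf[i] = infRate[i] * x * comp[i];
    clr[i] = (g[i] - gamma) * comp[i];
    sup[i] = supRate[i] * s * comp[i];
    infSum += inf[i];
    clrSum += clr[i];
  }
  supSum = sup[1] + sup[2] + sup[3];
  dy[0] = -infSum - clrSum;
  dy[1] = inf[0] + supSum + clr[0];
  for (int i = 1; i < 4; ++i) dy[1 + i] = inf[i] - sup[i] + clr[i];
  if (pin) dy[2] = dy[3] = dy[4] = 0.0;
}

static inline void rk4_step(double *y, const double *g,
                            const double *infRate, const double *supRate,
                            double gamma, bool pin, double dt) {
  double k1[5], k2[5], k3[5], k4[5], tmp[5];
  rhs(y, g, infRate, supRate, gamma, pin, k1);
  for (int i = 0; i < 5; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
  rhs(tmp, g, infRate, supRate, gamma, pin, k2);
  for (int i = 0; i < 5; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
  rhs(tmp, g, infRate, supRate, gamma, pin, k3);
  for (int i = 0; i < 5; ++i) tmp[i] = y[i] + dt * k3[i];
  rhs(tmp, g, infRate, supRate, gamma, pin, k4);
  for (int i = 0; i < 5; ++i)
    y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

static inline double drift_of(const double *y) {
  return std::fabs(y[0] + y[1] + y[2] + y[3] + y[4] - 1.0);
}

static void check_finite(const double *y, double t) {
  for (int i = 0; i < 5; ++i)
    if (!std::isfinite(y[i]))
      stop("non-finite state encountered at model time %.6g", t);
}

// Integrate under constant doses until the one-step sup-norm change drops
// below `tol`, or `maxSteps` is exhausted.
// [[Rcpp::export(name = ".engineStatic")]]
List engineStatic(NumericVector y0, NumericVector g, NumericVector infRate,
                  NumericVector supRate, double gamma, double dt, double tol,
                  double maxSteps, bool pin) {
  double y[5], yPrev[5];
  for (int i = 0; i < 5; ++i) y[i] = y0[i];
  bool converged = false;
  double steps = 0.0, maxDrift = drift_of(y);
  const double *gp = REAL(g), *ir = REAL(infRate), *sr = REAL(supRate);
  while (steps < maxSteps) {
    for (int i = 0; i < 5; ++i) yPrev[i] = y[i];
    rk4_step(y, gp, ir, sr, gamma, pin, dt);
    steps += 1.0;
    if (((long long)steps) % 1000 == 0) check_finite(y, steps * dt);
    double d = drift_of(y);
    if (d > maxDrift) maxDrift = d;
    double ch = 0.0;
    for (int i = 0; i < 5; ++i) {
      double a = std::fabs(y[i] - yPrev[i]);
      if (a > ch) ch = a;
    }
    if (ch < tol) { converged = true; break; }
  }
  check_finite(y, steps * dt);
  return List::create(_["state"] = NumericVector(y, y + 5),
                      _["steps"] = steps, _["converged"] = converged,
                      _["drift"] = maxDrift);
}

// Periodically forced run: growth alternates gA (first half-cycle) / gB
// (second half-cycle), each held for `stepsPerPeriod` steps.  Convergence is
// declared when the per-compartment envelope (running min/max within a full
// cycle) changes by less than `tol` between consecutive cycles.  The state is
// then time-averaged over `avgPeriods` further half-cycles, together with the
// population recovery flux z = -sum_i (g_i - gamma) * strain_i.
// [[Rcpp::export(name = ".enginePeriodic")]]
List enginePeriodic(NumericVector y0, NumericVector gA, NumericVector gB,
                    NumericVector infRate, NumericVector supRate, double gamma,
                    double dt, int stepsPerPeriod, double maxCycles, double tol,
                    int avgPeriods) {
  double y[5];
  for (int i = 0; i < 5; ++i) y[i] = y0[i];
  const double *ga = REAL(gA), *gb = REAL(gB);
  const double *ir = REAL(infRate), *sr = REAL(supRate);
  double envPrev[10], env[10];
  bool havePrev = false, converged = false;
  double cycles = 0.0, maxDrift = drift_of(y);

  while (cycles < maxCycles) {
    for (int i = 0; i < 5; ++i) { env[i] = y[i]; env[5 + i] = y[i]; }
    for (int half = 0; half < 2; ++half) {
      const double *g = (half == 0) ? ga : gb;
      for (int s = 0; s < stepsPerPeriod; ++s) {
        rk4_step(y, g, ir, sr, gamma, false, dt);
        for (int i = 0; i < 5; ++i) {
          if (y[i] < env[i]) env[i] = y[i];
          if (y[i] > env[5 + i]) env[5 + i] = y[i];
        }
      }
      check_finite(y, 0.0);
    }
    cycles += 1.0;
    double d = drift_of(y);
    if (d > maxDrift) maxDrift = d;
    if (havePrev) {
      double ch = 0.0;
      for (int i = 0; i < 10; ++i) {
        double a = std::fabs(env[i] - envPrev[i]);
        if (a > ch) ch = a;
      }
      if (ch < tol) { converged = true; break; }
    }
    for (int i = 0; i < 10; ++i) envPrev[i] = env[i];
    havePrev = true;
  }

  // Cycle averaging, phase-aligned with the first (gA) half-cycle.
  double acc[5] = {0, 0, 0, 0, 0};
  double zAcc = 0.0, nAcc = 0.0;
  for (int p = 0; p < avgPeriods; ++p) {
    const double *g = (p % 2 == 0) ? ga : gb;
    for (int s = 0; s < stepsPerPeriod; ++s) {
      rk4_step(y, g, ir, sr, gamma, false, dt);
      for (int i = 0; i < 5; ++i) acc[i] += y[i];
      double z = 0.0;
      for (int i = 0; i < 4; ++i) z -= (g[i] - gamma) * y[1 + i];
      zAcc += z;
      nAcc += 1.0;
    }
    check_finite(y, 0.0);
  }
  double avg[5];
  for (int i = 0; i < 5; ++i) avg[i] = acc[i] / nAcc;
  double d = drift_of(y);
  if (d > maxDrift) maxDrift = d;
  return List::create(_["avgState"] = NumericVector(avg, avg + 5),
                      _["zBar"] = zAcc / nAcc, _["cycles"] = cycles,
                      _["converged"] = converged,
                      _["finalState"] = NumericVector(y, y + 5),
                      _["drift"] = maxDrift);
}

// Record every step of a constant-dose segment (used by the trajectory
// recorder, which stitches segments across period boundaries in R).
// [[Rcpp::export(name = ".engineRecord")]]
NumericMatrix engineRecord(NumericVector y0, NumericVector g,
                           NumericVector infRate, NumericVector supRate,
                           double gamma, double dt, int nSteps, bool pin) {
  NumericMatrix out(nSteps + 1, 5);
  double y[5];
  for (int i = 0; i < 5; ++i) { y[i] = y0[i]; out(0, i) = y[i]; }
  const double *gp = REAL(g), *ir = REAL(infRate), *sr = REAL(supRate);
  for (int s = 1; s <= nSteps; ++s) {
    rk4_step(y, gp, ir, sr, gamma, pin, dt);
    for (int i = 0; i < 5; ++i) out(s, i) = y[i];
  }
  check_finite(y, nSteps * dt);
  return out;
}
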