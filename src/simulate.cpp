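#include <Rcpp.h>
using namespace Rcpp;

// Fast inner loop for the discrete-time mutualism model. Mirrors the R
// reference step (bv_step) exactly: synchronous update of the four
// abundances and four traits from time-t values, trait clamping keeping
// carrying capacities positive, equilibrium detection over a trailing
// window, and a runaway-abundance guard.

static const double CAP_EPS = 1e-6;

struct Params {
  double r1, r2, rP, rX, c1, c2, f1, f2, fP1, fP2;
  double s1, s2, sP1, sP2;  // genetic variances
  double k1, k2, kP, d1, d2, th1, th2, thP1, thP2, a01, a02;
};

static Params unpack(const List& p) {
  Params q;
  q.r1 = p["r1"]; q.r2 = p["r2"]; q.rP = p["rP"]; q.rX = p["rX"];
  q.c1 = p["c1"]; q.c2 = p["c2"];
  q.f1 = p["f1"]; q.f2 = p["f2"]; q.fP1 = p["fP1"]; q.fP2 = p["fP2"];
  q.s1 = p["sigma1_sq"]; q.s2 = p["sigma2_sq"];
  q.sP1 = p["sigmaP1_sq"]; q.sP2 = p["sigmaP2_sq"];
  q.k1 = p["k1"]; q.k2 = p["k2"]; q.kP = p["kP"];
  q.d1 = p["d1"]; q.d2 = p["d2"];
  q.th1 = p["theta1"]; q.th2 = p["theta2"];
  q.thP1 = p["thetaP1"]; q.thP2 = p["thetaP2"];
  q.a01 = p["a01"]; q.a02 = p["a02"];
  return q;
}

// state layout: P, X, N1, N2, u1, u2, v1, v2
static inline void one_step(double* s, const Params& q,
                            bool plant_ev, bool poll_ev, long step_idx) {
  const double P = s[0], X = s[1], N1 = s[2], N2 = s[3];
  const double u1 = s[4], u2 = s[5], v1 = s[6], v2 = s[7];

  const double bP = q.kP - q.fP1 * u1 - q.fP2 * u2;
  const double b1 = q.k1 - q.f1 * v1;
  const double b2 = q.k2 - q.f2 * v2;
  if (bP <= 0.0 || b1 <= 0.0 || b2 <= 0.0)
    stop("degenerate state at step %d: nonpositive carrying capacity",
         (int)step_idx);

  const double w1 = v1 + q.d1 * u1 + 1.0;  // log arguments, >= 1
  const double w2 = v2 + q.d2 * u2 + 1.0;
  const double a1 = std::log(w1) / (q.a01 + P);
  const double a2 = std::log(w2) / (q.a02 + P);

  // ecological maps
  const double gP = q.rP - (q.rP / bP) * P + q.thP1 * a1 * N1 + q.thP2 * a2 * N2;
  const double g1 = q.r1 - (q.r1 / b1) * (N1 + q.c1 * N2) + q.th1 * a1 * X;
  const double g2 = q.r2 - (q.r2 / b2) * (N2 + q.c2 * N1) + q.th2 * a2 * X;
  s[0] = (P > 0.0) ? P * std::exp(gP) : 0.0;
  s[1] = q.rX * P + X * std::exp(-(a1 * N1 + a2 * N2));
  s[2] = (N1 > 0.0) ? N1 * std::exp(g1) : 0.0;
  s[3] = (N2 > 0.0) ? N2 * std::exp(g2) : 0.0;

  // quantitative-genetics trait maps (selection gradient of log fitness
  // times genetic variance), from time-t abundances
  if (plant_ev) {
    const double bP2 = bP * bP;
    double nu1 = u1 + q.sP1 * (-q.rP * P * q.fP1 / bP2 +
                               q.thP1 * N1 * q.d1 / (w1 * (q.a01 + P)));
    double nu2 = u2 + q.sP2 * (-q.rP * P * q.fP2 / bP2 +
                               q.thP2 * N2 * q.d2 / (w2 * (q.a02 + P)));
    if (nu1 < 0.0) nu1 = 0.0;
    if (nu2 < 0.0) nu2 = 0.0;
    if (q.fP1 > 0.0 && nu1 > (q.kP - CAP_EPS) / q.fP1)
      nu1 = (q.kP - CAP_EPS) / q.fP1;
    if (q.fP2 > 0.0 && nu2 > (q.kP - CAP_EPS) / q.fP2)
      nu2 = (q.kP - CAP_EPS) / q.fP2;
    const double cost = q.fP1 * nu1 + q.fP2 * nu2;
    if (cost > q.kP - CAP_EPS) {
      const double sc = (q.kP - CAP_EPS) / cost;
      nu1 *= sc; nu2 *= sc;
    }
    s[4] = nu1; s[5] = nu2;
  }
  if (poll_ev) {
    double nv1 = v1 + q.s1 * (-q.r1 * (N1 + q.c1 * N2) * q.f1 / (b1 * b1) +
                              q.th1 * X / (w1 * (q.a01 + P)));
    double nv2 = v2 + q.s2 * (-q.r2 * (N2 + q.c2 * N1) * q.f2 / (b2 * b2) +
                              q.th2 * X / (w2 * (q.a02 + P)));
    if (nv1 < 0.0) nv1 = 0.0;
    if (nv2 < 0.0) nv2 = 0.0;
    if (q.f1 > 0.0 && nv1 > (q.k1 - CAP_EPS) / q.f1)
      nv1 = (q.k1 - CAP_EPS) / q.f1;
    if (q.f2 > 0.0 && nv2 > (q.k2 - CAP_EPS) / q.f2)
      nv2 = (q.k2 - CAP_EPS) / q.f2;
    s[6] = nv1; s[7] = nv2;
  }
}

// [[Rcpp::export]]
List simulate_loop_cpp(NumericVector init, List params,
                       bool plant_evolves, bool pollinators_evolve,
                       int max_steps, int record_stride,
                       int eq_window, double eq_tol,
                       double max_abundance, int t0) {
  if (init.size() != 8) stop("init must have 8 elements");
  if (max_steps < 1) stop("max_steps must be >= 1");
  if (record_stride < 1) stop("record_stride must be >= 1");
  Params q = unpack(params);

  double s[8], snap[8];
  for (int i = 0; i < 8; ++i) s[i] = init[i];

  const int cap = max_steps / record_stride + 2;
  NumericMatrix rec(cap, 9);
  int nrec = 0;
  rec(nrec, 0) = t0;
  for (int i = 0; i < 8; ++i) rec(nrec, i + 1) = s[i];
  ++nrec;

  for (int i = 0; i < 8; ++i) snap[i] = s[i];
  bool converged = false, unbounded = false;
  long steps_done = 0;

  for (long t = 1; t <= max_steps; ++t) {
    one_step(s, q, plant_evolves, pollinators_evolve, t);
    steps_done = t;

    if (s[0] > max_abundance || s[1] > max_abundance ||
        s[2] > max_abundance || s[3] > max_abundance) {
      unbounded = true;
    }

    const bool at_end = (t == max_steps) || unbounded;
    if (t % record_stride == 0 && !at_end) {
      rec(nrec, 0) = t0 + t;
      for (int i = 0; i < 8; ++i) rec(nrec, i + 1) = s[i];
      ++nrec;
    }

    if (eq_window > 0 && t % eq_window == 0) {
      double relmax = 0.0;
      for (int i = 0; i < 8; ++i) {
        const double den = std::max(std::fabs(s[i]), 1e-9);
        const double rel = std::fabs(s[i] - snap[i]) / den;
        if (rel > relmax) relmax = rel;
      }
      if (relmax < eq_tol) converged = true;
      for (int i = 0; i < 8; ++i) snap[i] = s[i];
    }

    if (converged || at_end) {
      if (rec(nrec - 1, 0) != (double)(t0 + t)) {
        rec(nrec, 0) = t0 + t;
        for (int i = 0; i < 8; ++i) rec(nrec, i + 1) = s[i];
        ++nrec;
      }
      break;
    }
  }

  NumericMatrix out(nrec, 9);
  for (int r = 0; r < nrec; ++r)
    for (int cidx = 0; cidx < 9; ++cidx) out(r, cidx) = rec(r, cidx);
  colnames(out) = CharacterVector::create("t", "P", "X", "N1", "N2",
                                          "u1", "u2", "v1", "v2");

  NumericVector fin(8);
  for (int i = 0; i < 8; ++i) fin[i] = s[i];

  return List::create(_["record"] = out,
                      _["final"] = fin,
                      _["steps"] = (double)steps_done,
                      _["converged"] = converged,
                      _["unbounded"] = unbounded);
}
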