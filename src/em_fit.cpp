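#define SEED_DIAG 1
// Fast engine for the EM fit of (q, D).  Mirrors the reference R
// implementation in R/likelihood-em.R exactly (same E-step weights, same
// closed-form coordinate-wise M-step in (Q, R) coordinates, same
// convergence rule); the two are cross-checked in the test suite.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double clog(double x) {
  return std::log(x > 1e-320 ? x : 1e-320);
}

// Weighted objective sum_ij c_ij log g_ij in (Q, R) coordinates; cv is the
// row-flattened weight matrix (c11..c13, c21..c23, c31..c33).
static double G_QR(double Q, double R, const double *cv) {
  const double g[9] = {Q * Q, 2 * Q * (1 - Q), (1 - Q) * (1 - Q),
                       Q * R, Q + R - 2 * Q * R, (1 - Q) * (1 - R),
                       R * R, 2 * R * (1 - R), (1 - R) * (1 - R)};
  double s = 0;
  for (int i = 0; i < 9; ++i) s += cv[i] * clog(g[i]);
  return s;
}

// Exact concave 1-D maximisation: real roots of the quadratic score
// equation inside [lo, hi], plus the endpoints.
static double coord_max(double other, double A, double B, double c22,
                        double lo, double hi, bool isQ, double fixed,
                        const double *cv) {
  const double k = 1 - 2 * other;
  const double a2 = -k * (A + B + c22);
  const double a1 = A * (k - other) - B * other + c22 * k;
  const double a0 = A * other;
  double roots[2];
  int nr = 0;
  if (std::fabs(a2) > 1e-14) {
    const double disc = a1 * a1 - 4 * a2 * a0;
    if (disc >= 0) {
      const double s = std::sqrt(disc);
      roots[nr++] = (-a1 - s) / (2 * a2);
      roots[nr++] = (-a1 + s) / (2 * a2);
    }
  } else if (std::fabs(a1) > 1e-14) {
    roots[nr++] = -a0 / a1;
  }
  double bx = lo;
  double bv = isQ ? G_QR(lo, fixed, cv) : G_QR(fixed, lo, cv);
  double v = isQ ? G_QR(hi, fixed, cv) : G_QR(fixed, hi, cv);
  if (v > bv) { bv = v; bx = hi; }
  for (int i = 0; i < nr; ++i) {
    const double x = roots[i];
    if (x > lo && x < hi) {
      v = isQ ? G_QR(x, fixed, cv) : G_QR(fixed, x, cv);
      if (v > bv) { bv = v; bx = x; }
    }
  }
  return bx;
}

struct MStep { double Q, R, value; };

static MStep run_branch(double Qlo, double Qhi, double Rlo, double Rhi,
                        double Q, double R, double A_Q, double B_Q,
                        double A_R, double B_R, double c22,
                        const double *cv) {
  if (Q < Qlo) Q = Qlo;
  if (Q > Qhi) Q = Qhi;
  if (R < Rlo) R = Rlo;
  if (R > Rhi) R = Rhi;
  // seed with a coarse scan of the branch diagonal: pure coordinate
  // ascent can be trapped at the D = 0 corner (Q = R = p), where moving
  // either coordinate alone decreases the objective although moving
  // both helps
  double val = G_QR(Q, R, cv);
  for (double t = 0.05; t < 0.96 && SEED_DIAG; t += 0.06) {
    const double Qd = Qlo + t * (Qhi - Qlo);
    const double Rd = Rhi - t * (Rhi - Rlo);
    const double vd = G_QR(Qd, Rd, cv);
    if (std::isfinite(vd) && vd > val) { val = vd; Q = Qd; R = Rd; }
  }
  for (int s = 0; s < 30; ++s) {
    Q = coord_max(R, A_Q, B_Q, c22, Qlo, Qhi, true, R, cv);
    R = coord_max(Q, A_R, B_R, c22, Rlo, Rhi, false, Q, cv);
    const double val_new = G_QR(Q, R, cv);
    if (!std::isfinite(val_new) || val_new - val < 1e-11) {
      if (std::isfinite(val_new) && val_new > val) val = val_new;
      break;
    }
    val = val_new;
  }
  MStep m; m.Q = Q; m.R = R; m.value = val;
  return m;
}

static MStep mstep_QR(double p, const double *cv, double Q0, double R0) {
  const double A_Q = 2 * cv[0] + cv[1] + cv[3];
  const double B_Q = cv[1] + 2 * cv[2] + cv[5];
  const double A_R = 2 * cv[6] + cv[7] + cv[3];
  const double B_R = cv[7] + 2 * cv[8] + cv[5];
  const double c22 = cv[4];
  MStep pos = run_branch(p, 1, 0, p, Q0 > p ? Q0 : p, R0 < p ? R0 : p,
                         A_Q, B_Q, A_R, B_R, c22, cv);
  MStep neg = run_branch(0, p, p, 1, Q0 < p ? Q0 : p, R0 > p ? R0 : p,
                         A_Q, B_Q, A_R, B_R, c22, cv);
  return pos.value >= neg.value ? pos : neg;
}

// E-step from the haplotype-conditional frequencies hQ = Pr(A | M hap),
// hR = Pr(A | m hap); returns false (with j_bad/arm_bad set) when a
// marker genotype with positive count has zero probability in an arm.
static bool estep_cv(double hQ, double hR, const double *f,
                     const double *n1, const double *n2, double *cv,
                     int *j_bad, int *arm_bad) {
  const double h[9] = {hQ * hQ, 2 * hQ * (1 - hQ), (1 - hQ) * (1 - hQ),
                       hQ * hR, hQ + hR - 2 * hQ * hR,
                       (1 - hQ) * (1 - hR),
                       hR * hR, 2 * hR * (1 - hR), (1 - hR) * (1 - hR)};
  // block j (size 3) holds Pr(X = i | Y = j) for i = AA, Aa, aa
  for (int j = 0; j < 3; ++j) {
    double dw = 0, dv = 0;
    for (int i = 0; i < 3; ++i) {
      dw += f[i] * h[3 * j + i];
      dv += (1 - f[i]) * h[3 * j + i];
    }
    if (dw <= 0 && n1[j] > 0) { *j_bad = j; *arm_bad = 0; return false; }
    if (dv <= 0 && n2[j] > 0) { *j_bad = j; *arm_bad = 1; return false; }
    const double aw = dw > 0 ? n1[j] / dw : 0;
    const double av = dv > 0 ? n2[j] / dv : 0;
    for (int i = 0; i < 3; ++i)
      cv[3 * i + j] = f[i] * h[3 * j + i] * aw +
                      (1 - f[i]) * h[3 * j + i] * av;
  }
  return true;
}

// q and the haplotype-conditional frequencies implied by a point in
// (Q, R) space; on the D = 0 ridge (Q = R) q is unidentified and the
// fallback is kept.
static void hq_of(double p, double Q, double R, double q_fb, double *q,
                  double *hQ, double *hR) {
  if (std::fabs(Q - R) < 1e-10) { *q = q_fb; *hQ = q_fb; *hR = q_fb; return; }
  double qq = (p - R) / (Q - R);
  if (qq < 0) qq = 0;
  if (qq > 1) qq = 1;
  double a = qq * Q / p, b = qq * (1 - Q) / (1 - p);
  if (a < 0) a = 0;
  if (a > 1) a = 1;
  if (b < 0) b = 0;
  if (b > 1) b = 1;
  *q = qq; *hQ = a; *hR = b;
}

// [[Rcpp::export(name = ".em_fit_engine_cpp")]]
List em_fit_engine_cpp(NumericVector n1, NumericVector n2, NumericVector f,
                       double p, NumericMatrix starts, double tol,
                       int max_iter) {
  const char *geno[3] = {"MM", "Mm", "mm"};
  double best_ll = R_NegInf, best_q = NA_REAL, best_D = NA_REAL;
  int best_it = 0;
  bool best_conv = false, have_interior = false;
  std::vector<double> best_trace;
  for (int s = 0; s < starts.nrow(); ++s) {
    double q_fb = starts(s, 0), Dc = starts(s, 1);
    if (q_fb < 1e-6) q_fb = 1e-6;
    if (q_fb > 1 - 1e-6) q_fb = 1 - 1e-6;
    bool converged = false;
    int it = 0;
    std::vector<double> trace;
    double cv[9];
    int j_bad = -1, arm_bad = -1;
    double Qc = p + Dc / q_fb, Rc = p - Dc / (1 - q_fb);
    double q_cur, hQ, hR;
    hq_of(p, Qc, Rc, q_fb, &q_cur, &hQ, &hR);
    q_fb = q_cur;
    if (!estep_cv(hQ, hR, f.begin(), n1.begin(), n2.begin(), cv,
                  &j_bad, &arm_bad))
      stop("marker genotype %s has zero probability among %s but positive count",
           geno[j_bad], arm_bad == 0 ? "cases" : "controls");
    double ll = G_QR(Qc, Rc, cv);
    trace.push_back(ll);
    double ll_prev2 = NA_REAL;
    double checkpoint = ll;
    double alpha = 1;  // damping; halved when the iteration cycles
    while (it < max_iter) {
      ++it;
      const MStep m = mstep_QR(p, cv, Qc, Rc);
      // fixed-point step (damped if needed); an infeasible trial point
      // is pulled back towards the incumbent until feasible
      double step = alpha;
      double cvt[9];
      bool feasible = false;
      double Qt = Qc, Rt = Rc, qt = q_fb;
      for (int h = 0; h < 8; ++h) {
        Qt = Qc + step * (m.Q - Qc);
        Rt = Rc + step * (m.R - Rc);
        hq_of(p, Qt, Rt, q_fb, &qt, &hQ, &hR);
        if (estep_cv(hQ, hR, f.begin(), n1.begin(), n2.begin(), cvt,
                     &j_bad, &arm_bad)) {
          feasible = true;
          break;
        }
        step /= 2;
      }
      if (!feasible) {
        // boxed in on the feasibility boundary: the incumbent is the
        // constrained fixed point
        converged = true;
        break;
      }
      const double llt = G_QR(Qt, Rt, cvt);
      q_fb = qt; Qc = Qt; Rc = Rt;
      std::copy(cvt, cvt + 9, cv);
      trace.push_back(llt);
      // stop when the objective plateaus (the convergence monitor of the
      // underlying algorithm); cycle damping below guards the rare
      // oscillating trajectories
      if (std::fabs(llt - ll) < tol) {
        converged = true;
        ll = llt;
        break;
      }
      if (alpha == 1 && R_finite(ll_prev2) &&
          std::fabs(llt - ll_prev2) < 1e-9)
        alpha = 0.5;  // period-2 oscillation: damp the iteration
      ll_prev2 = ll;
      ll = llt;
      if (it % 40 == 0) {
        // longer-period cycling: progressively damp when a whole window
        // has made no net progress
        if (std::fabs(ll - checkpoint) < 1e-7 && alpha > 1.0 / 16)
          alpha /= 2;
        checkpoint = ll;
      }
    }
    double q_hat = q_fb;
    if (q_hat < 1e-12) q_hat = 1e-12;
    if (q_hat > 1 - 1e-12) q_hat = 1 - 1e-12;
    double D_hat = q_hat * (Qc - p);
    const double lo = std::max(-p * q_hat, -(1 - p) * (1 - q_hat));
    const double hi = std::min(p * (1 - q_hat), (1 - p) * q_hat);
    if (D_hat < lo) D_hat = lo;
    if (D_hat > hi) D_hat = hi;
    // solutions with q at the edge of (0, 1) are degenerate; prefer the
    // best interior solution (root-selection rule: 0 < q < 1)
    const bool interior = q_hat > 0.01 && q_hat < 0.99;
    const bool better = interior
      ? (!have_interior || ll > best_ll)
      : (!have_interior && (ll > best_ll || !R_finite(best_q)));
    if (better) {
      best_ll = ll; best_q = q_hat; best_D = D_hat; best_it = it;
      best_conv = converged; best_trace = trace;
      if (interior) have_interior = true;
    }
  }
  return List::create(_["q_hat"] = best_q, _["D_hat"] = best_D,
                      _["loglik"] = best_ll,
                      _["loglik_trace"] = NumericVector(best_trace.begin(),
                                                        best_trace.end()),
                      _["iterations"] = best_it,
                      _["converged"] = best_conv);
}
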