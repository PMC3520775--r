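#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// phi1(lam, h) = (exp(lam h) - 1)/lam, series-safe near 0
static inline double phi1(double lam, double h) {
  double x = lam * h;
  if (std::fabs(x) < 1e-7) return h * (1.0 + x / 2.0 + x * x / 6.0);
  return (std::exp(x) - 1.0) / lam;
}

// phi2(lam, h) = (exp(lam h) - 1 - lam h)/lam^2
static inline double phi2(double lam, double h) {
  double x = lam * h;
  if (std::fabs(x) < 1e-5) return h * h * (0.5 + x / 6.0 + x * x / 24.0);
  return (std::exp(x) - 1.0 - x) / (lam * lam);
}

// Exact propagation of the two-compartment brain system (amount form)
// across forcing-grid nodes with piecewise-linear plasma forcing and a
// piecewise-constant inhibitor effect D. Returns 2 x m amounts.
// [[Rcpp::export(name = ".brain_propagate_cpp")]]
NumericMatrix brain_propagate_cpp(double Vbr1, double Vbr2, double Qin,
                                  double Qout, double Qbr, int on_qin,
                                  NumericVector grid, NumericVector cc,
                                  NumericVector Dseg) {
  const int m = grid.size();
  NumericMatrix A(2, m);
  double z1 = 0.0, z2 = 0.0;          // state in eigenbasis
  double P11 = 1, P12 = 0, P21 = 0, P22 = 1;
  double I11 = 1, I12 = 0, I21 = 0, I22 = 1;  // P^{-1}
  double lam1 = 0, lam2 = 0, binfac = 0;
  double cachedD = -1.0;
  bool havebasis = false;
  for (int s = 0; s < m - 1; ++s) {
    double D = Dseg[s];
    if (!havebasis || D != cachedD) {
      double m_in = on_qin ? D : 1.0;
      double m_out = on_qin ? 1.0 : D;
      double a = -(m_out * Qout + Qbr) / Vbr1;
      double b = Qbr / Vbr2;
      double c = Qbr / Vbr1;
      double d = -Qbr / Vbr2;
      double disc = std::sqrt(((a - d) / 2.0) * ((a - d) / 2.0) + b * c);
      lam1 = (a + d) / 2.0 + disc;
      lam2 = (a + d) / 2.0 - disc;
      // current amounts before the basis change
      double A1 = havebasis ? P11 * z1 + P12 * z2 : 0.0;
      double A2 = havebasis ? P21 * z1 + P22 * z2 : 0.0;
      P11 = b; P12 = b; P21 = lam1 - a; P22 = lam2 - a;
      double det = P11 * P22 - P12 * P21;
      I11 = P22 / det; I12 = -P12 / det;
      I21 = -P21 / det; I22 = P11 / det;
      z1 = I11 * A1 + I12 * A2;
      z2 = I21 * A1 + I22 * A2;
      binfac = m_in * Qin;
      cachedD = D;
      havebasis = true;
    }
    double h = grid[s + 1] - grid[s];
    double f0 = binfac * cc[s];
    double slope = binfac * (cc[s + 1] - cc[s]) / h;
    z1 = std::exp(lam1 * h) * z1 + I11 * f0 * phi1(lam1, h) +
         I11 * slope * phi2(lam1, h);
    z2 = std::exp(lam2 * h) * z2 + I21 * f0 * phi1(lam2, h) +
         I21 * slope * phi2(lam2, h);
    A(0, s + 1) = P11 * z1 + P12 * z2;
    A(1, s + 1) = P21 * z1 + P22 * z2;
  }
  return A;
}

// Exact solution of dA/dt = M A + b(t) for an n-dim linear system with
// piecewise-constant input, given the (real) eigendecomposition of M.
// breaks: s+1 segment boundaries; beta: n x s inputs in eigenbasis;
// times: sorted output times. Returns n x k states (eigen coords applied).
// [[Rcpp::export(name = ".lin_const_solve_cpp")]]
NumericMatrix lin_const_solve_cpp(NumericVector lam, NumericMatrix P,
                                  NumericMatrix beta, NumericVector breaks,
                                  NumericVector times) {
  const int n = lam.size();
  const int ns = breaks.size() - 1;
  const int k = times.size();
  NumericMatrix out(n, k);
  std::vector<double> z(n, 0.0), zt(n);
  int j = 0;
  while (j < k && times[j] <= breaks[0]) ++j;  // states are zero before start
  for (int s = 0; s < ns; ++s) {
    double t0 = breaks[s], t1 = breaks[s + 1];
    while (j < k && times[j] > t0 && times[j] <= t1 + 1e-12) {
      double h = times[j] - t0;
      for (int i = 0; i < n; ++i)
        zt[i] = std::exp(lam[i] * h) * z[i] + phi1(lam[i], h) * beta(i, s);
      for (int r = 0; r < n; ++r) {
        double acc = 0.0;
        for (int i = 0; i < n; ++i) acc += P(r, i) * zt[i];
        out(r, j) = acc;
      }
      ++j;
    }
    double h = t1 - t0;
    for (int i = 0; i < n; ++i)
      z[i] = std::exp(lam[i] * h) * z[i] + phi1(lam[i], h) * beta(i, s);
  }
  return out;
}

// Central-compartment concentration of the three-compartment mammillary
// plasma model under piecewise-constant central infusion, via the analytic
// eigendecomposition (real spectrum; the system is symmetrizable).
// rates: central input rate (kBq/min) per segment; breaks: s+1 boundaries.
// [[Rcpp::export(name = ".plasma_conc_cpp")]]
NumericVector plasma_conc_cpp(double Vc, double Vp1, double Vp2, double CL,
                              double Q1, double Q2, NumericVector breaks,
                              NumericVector rates, NumericVector times) {
  const double k10 = CL / Vc, k12 = Q1 / Vc, k21 = Q1 / Vp1;
  const double k13 = Q2 / Vc, k31 = Q2 / Vp2;
  // characteristic cubic lam^3 + a2 lam^2 + a1 lam + a0 = 0
  const double s = k10 + k12 + k13;
  const double a2 = s + k21 + k31;
  const double a1 = s * (k21 + k31) + k21 * k31 - k12 * k21 - k13 * k31;
  const double a0 = s * k21 * k31 - k12 * k21 * k31 - k13 * k31 * k21;
  // three real roots (trigonometric method); eigenvalues are -roots' sign
  const double p = a1 - a2 * a2 / 3.0;
  const double q = 2.0 * a2 * a2 * a2 / 27.0 - a2 * a1 / 3.0 + a0;
  double lam[3];
  double mfac = 2.0 * std::sqrt(std::max(-p / 3.0, 1e-300));
  double arg = 3.0 * q / (p * mfac);
  if (arg > 1.0) arg = 1.0;
  if (arg < -1.0) arg = -1.0;
  double theta = std::acos(arg) / 3.0;
  for (int i = 0; i < 3; ++i)
    lam[i] = mfac * std::cos(theta - 2.0 * M_PI * i / 3.0) - a2 / 3.0;
  // roots of char poly in lam are the (negative) eigenvalues directly
  // eigenvector for lam: [1, k12/(lam + k21), k13/(lam + k31)]
  double P[3][3];
  for (int i = 0; i < 3; ++i) {
    double d1 = lam[i] + k21, d2 = lam[i] + k31;
    if (std::fabs(d1) < 1e-12) d1 = (d1 < 0 ? -1e-12 : 1e-12);
    if (std::fabs(d2) < 1e-12) d2 = (d2 < 0 ? -1e-12 : 1e-12);
    P[0][i] = 1.0;
    P[1][i] = k12 / d1;
    P[2][i] = k13 / d2;
  }
  // beta = P^{-1} e1 (input enters the central compartment only): solve P x = e1
  double det = 0.0;
  double C[3][3]; // cofactors
  C[0][0] = P[1][1] * P[2][2] - P[1][2] * P[2][1];
  C[0][1] = -(P[1][0] * P[2][2] - P[1][2] * P[2][0]);
  C[0][2] = P[1][0] * P[2][1] - P[1][1] * P[2][0];
  det = P[0][0] * C[0][0] + P[0][1] * C[0][1] + P[0][2] * C[0][2];
  double beta1[3]; // first column of P^{-1}
  beta1[0] = C[0][0] / det;
  beta1[1] = C[0][1] / det;
  beta1[2] = C[0][2] / det;
  const int ns = breaks.size() - 1;
  const int k = times.size();
  NumericVector out(k);
  double z[3] = {0.0, 0.0, 0.0};
  int j = 0;
  while (j < k && times[j] <= breaks[0]) ++j;
  for (int sgm = 0; sgm < ns; ++sgm) {
    double t0 = breaks[sgm], t1 = breaks[sgm + 1];
    double r = rates[sgm];
    while (j < k && times[j] > t0 && times[j] <= t1 + 1e-12) {
      double h = times[j] - t0;
      double ac = 0.0;
      for (int i = 0; i < 3; ++i)
        ac += std::exp(lam[i] * h) * z[i] + phi1(lam[i], h) * beta1[i] * r;
      out[j] = ac / Vc;  // row 1 of P is all ones
      ++j;
    }
    double h = t1 - t0;
    for (int i = 0; i < 3; ++i)
      z[i] = std::exp(lam[i] * h) * z[i] + phi1(lam[i], h) * beta1[i] * r;
  }
  return out;
}
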