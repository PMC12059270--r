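#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-voxel IVIM (segmented + bounded Levenberg-Marquardt refinement) and
// DKI (log-linear init + bounded LM) fits. Signal units are arbitrary;
// diffusivities are in mm^2/s. The IVIM model is
//   S(b) = S0 [ (1 - f) exp(-b D) + f exp(-b (D + D*)) ]
// and the DKI model is
//   S(b) = S0 exp(-b MD + b^2 MD^2 MK / 6),
// with S0 fixed at the measured b = 0 signal.

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static double sse_ivim(const double *S, const double *b, int nb, double s0,
                       double D, double Ds, double f) {
  double sse = 0.0;
  for (int k = 0; k < nb; ++k) {
    double m = s0 * ((1.0 - f) * std::exp(-b[k] * D) +
                     f * std::exp(-b[k] * (D + Ds)));
    double r = S[k] - m;
    sse += r * r;
  }
  return sse;
}

static double r2_of(const double *S, const double *pred, int nb) {
  double mean = 0.0;
  for (int k = 0; k < nb; ++k) mean += S[k];
  mean /= nb;
  double ssr = 0.0, sst = 0.0;
  for (int k = 0; k < nb; ++k) {
    ssr += (S[k] - pred[k]) * (S[k] - pred[k]);
    sst += (S[k] - mean) * (S[k] - mean);
  }
  if (sst <= 0.0) return NA_REAL;
  return 1.0 - ssr / sst;
}

// golden-section minimization of the IVIM SSE over log(D*)
static double golden_ds(const double *S, const double *b, int nb, double s0,
                        double D, double f, double lo, double hi) {
  const double gr = 0.6180339887498949;
  double a = std::log(lo), c = std::log(hi);
  double x1 = c - gr * (c - a), x2 = a + gr * (c - a);
  double f1 = sse_ivim(S, b, nb, s0, D, std::exp(x1), f);
  double f2 = sse_ivim(S, b, nb, s0, D, std::exp(x2), f);
  for (int it = 0; it < 80 && (c - a) > 1e-10; ++it) {
    if (f1 < f2) {
      c = x2; x2 = x1; f2 = f1;
      x1 = c - gr * (c - a);
      f1 = sse_ivim(S, b, nb, s0, D, std::exp(x1), f);
    } else {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (c - a);
      f2 = sse_ivim(S, b, nb, s0, D, std::exp(x2), f);
    }
  }
  return std::exp(0.5 * (a + c));
}

// solve (A + lam*diag) d = g for p params (p <= 3), returns false if singular
static bool lm_solve(double A[3][3], double g[3], double lam, int p,
                     double d[3]) {
  double M[3][3];
  for (int i = 0; i < p; ++i) {
    for (int j = 0; j < p; ++j) M[i][j] = A[i][j];
    M[i][i] = A[i][i] > 0.0 ? A[i][i] * (1.0 + lam) : 1.0;
  }
  if (p == 2) {
    double det = M[0][0] * M[1][1] - M[0][1] * M[1][0];
    if (std::abs(det) < 1e-300) return false;
    d[0] = (g[0] * M[1][1] - g[1] * M[0][1]) / det;
    d[1] = (M[0][0] * g[1] - M[1][0] * g[0]) / det;
    return true;
  }
  double det = M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
               M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
               M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
  if (std::abs(det) < 1e-300) return false;
  double inv[3][3];
  inv[0][0] = (M[1][1] * M[2][2] - M[1][2] * M[2][1]) / det;
  inv[0][1] = (M[0][2] * M[2][1] - M[0][1] * M[2][2]) / det;
  inv[0][2] = (M[0][1] * M[1][2] - M[0][2] * M[1][1]) / det;
  inv[1][0] = (M[1][2] * M[2][0] - M[1][0] * M[2][2]) / det;
  inv[1][1] = (M[0][0] * M[2][2] - M[0][2] * M[2][0]) / det;
  inv[1][2] = (M[0][2] * M[1][0] - M[0][0] * M[1][2]) / det;
  inv[2][0] = (M[1][0] * M[2][1] - M[1][1] * M[2][0]) / det;
  inv[2][1] = (M[0][1] * M[2][0] - M[0][0] * M[2][1]) / det;
  inv[2][2] = (M[0][0] * M[1][1] - M[0][1] * M[1][0]) / det;
  for (int i = 0; i < 3; ++i)
    d[i] = inv[i][0] * g[0] + inv[i][1] * g[1] + inv[i][2] * g[2];
  return true;
}

// [[Rcpp::export]]
List ivim_fit_cpp(NumericMatrix S, NumericVector b, double split_b,
                  NumericVector bd, NumericVector bds, NumericVector bf,
                  bool refine, int max_iter, double tol) {
  const int nv = S.nrow(), nb = S.ncol();
  NumericVector Dv(nv), Dsv(nv), Fv(nv), R2(nv);
  LogicalVector valid(nv), conv(nv);
  std::vector<double> sig(nb), pred(nb);
  std::vector<int> hi_idx;
  for (int k = 0; k < nb; ++k)
    if (b[k] >= split_b) hi_idx.push_back(k);
  const int nh = hi_idx.size();

  for (int v = 0; v < nv; ++v) {
    bool ok = true;
    for (int k = 0; k < nb; ++k) {
      sig[k] = S(v, k);
      if (!(sig[k] > 0.0) || !R_finite(sig[k])) ok = false;
    }
    double s0 = sig[0];
    if (!ok || nh < 2) {
      Dv[v] = Dsv[v] = Fv[v] = R2[v] = NA_REAL;
      valid[v] = false;
      conv[v] = false;
      continue;
    }
    // segmented init: log-linear over the diffusion regime
    double sx = 0, sy = 0, sxx = 0, sxy = 0;
    for (int q = 0; q < nh; ++q) {
      double xb = b[hi_idx[q]], yl = std::log(sig[hi_idx[q]]);
      sx += xb; sy += yl; sxx += xb * xb; sxy += xb * yl;
    }
    double denom = nh * sxx - sx * sx;
    double slope = (nh * sxy - sx * sy) / denom;
    double inter = (sy - slope * sx) / nh;
    double D = clampd(-slope, bd[0], bd[1]);
    double f = clampd(1.0 - std::exp(inter) / s0, bf[0], bf[1]);
    double ds_lo = std::max(bds[0], D);
    double Ds = golden_ds(sig.data(), b.begin(), nb, s0, D, f, ds_lo, bds[1]);
    bool converged = true;

    if (refine) {
      converged = false;
      double p[3] = {D, Ds, f};
      double sse = sse_ivim(sig.data(), b.begin(), nb, s0, p[0], p[1], p[2]);
      double lam = 1e-3;
      for (int it = 0; it < max_iter; ++it) {
        double A[3][3] = {{0}}, g[3] = {0};
        for (int k = 0; k < nb; ++k) {
          double E1 = std::exp(-b[k] * p[0]);
          double E2 = std::exp(-b[k] * (p[0] + p[1]));
          double m = s0 * ((1.0 - p[2]) * E1 + p[2] * E2);
          double r = sig[k] - m;
          double J0 = -b[k] * m;
          double J1 = -s0 * p[2] * b[k] * E2;
          double J2 = s0 * (E2 - E1);
          A[0][0] += J0 * J0; A[0][1] += J0 * J1; A[0][2] += J0 * J2;
          A[1][1] += J1 * J1; A[1][2] += J1 * J2; A[2][2] += J2 * J2;
          g[0] += J0 * r; g[1] += J1 * r; g[2] += J2 * r;
        }
        A[1][0] = A[0][1]; A[2][0] = A[0][2]; A[2][1] = A[1][2];
        double d[3];
        if (!lm_solve(A, g, lam, 3, d)) { lam *= 10.0; continue; }
        double pn[3] = {clampd(p[0] + d[0], bd[0], bd[1]),
                        clampd(p[1] + d[1], bds[0], bds[1]),
                        clampd(p[2] + d[2], bf[0], bf[1])};
        double ssen = sse_ivim(sig.data(), b.begin(), nb, s0, pn[0], pn[1], pn[2]);
        if (ssen <= sse) {
          double step = 0.0;
          for (int i = 0; i < 3; ++i) {
            double sc = std::abs(p[i]) + 1e-12;
            step = std::max(step, std::abs(pn[i] - p[i]) / sc);
          }
          p[0] = pn[0]; p[1] = pn[1]; p[2] = pn[2];
          sse = ssen;
          lam = std::max(lam / 3.0, 1e-14);
          if (step < tol) { converged = true; break; }
        } else {
          lam *= 5.0;
          if (lam > 1e12) break;
        }
      }
      D = p[0]; Ds = p[1]; f = p[2];
    }
    if (Ds < D) Ds = D;  // pseudodiffusion cannot be slower than diffusion
    for (int k = 0; k < nb; ++k)
      pred[k] = s0 * ((1.0 - f) * std::exp(-b[k] * D) +
                      f * std::exp(-b[k] * (D + Ds)));
    Dv[v] = D; Dsv[v] = Ds; Fv[v] = f;
    R2[v] = r2_of(sig.data(), pred.data(), nb);
    valid[v] = true;
    conv[v] = converged;
  }
  return List::create(_["d"] = Dv, _["dstar"] = Dsv, _["f"] = Fv,
                      _["r2"] = R2, _["valid"] = valid,
                      _["converged"] = conv);
}

// [[Rcpp::export]]
List dki_fit_cpp(NumericMatrix S, NumericVector b, NumericVector bmd,
                 NumericVector bmk, bool refine, int max_iter, double tol) {
  const int nv = S.nrow(), nb = S.ncol();
  NumericVector MDv(nv), MKv(nv), R2(nv);
  LogicalVector valid(nv), conv(nv);
  std::vector<double> sig(nb), pred(nb);

  for (int v = 0; v < nv; ++v) {
    bool ok = true;
    for (int k = 0; k < nb; ++k) {
      sig[k] = S(v, k);
      if (!(sig[k] > 0.0) || !R_finite(sig[k])) ok = false;
    }
    double s0 = sig[0];
    if (!ok) {
      MDv[v] = MKv[v] = R2[v] = NA_REAL;
      valid[v] = false; conv[v] = false;
      continue;
    }
    // linear init: ln(S/S0) = -b c1 + b^2 c2
    double a11 = 0, a12 = 0, a22 = 0, g1 = 0, g2 = 0;
    for (int k = 0; k < nb; ++k) {
      double x1 = -b[k], x2 = b[k] * b[k], y = std::log(sig[k] / s0);
      a11 += x1 * x1; a12 += x1 * x2; a22 += x2 * x2;
      g1 += x1 * y; g2 += x2 * y;
    }
    double det = a11 * a22 - a12 * a12;
    double c1 = (g1 * a22 - g2 * a12) / det;
    double c2 = (a11 * g2 - a12 * g1) / det;
    if (!(c1 > 0.0)) {
      MDv[v] = MKv[v] = R2[v] = NA_REAL;
      valid[v] = false; conv[v] = false;
      continue;
    }
    double MD = clampd(c1, bmd[0], bmd[1]);
    double MK = clampd(6.0 * c2 / (c1 * c1), bmk[0], bmk[1]);
    bool converged = true;

    if (refine) {
      converged = false;
      double p[2] = {MD, MK};
      auto sse_dki = [&](double md, double mk) {
        double s = 0.0;
        for (int k = 0; k < nb; ++k) {
          double u = -b[k] * md + b[k] * b[k] * md * md * mk / 6.0;
          double m = s0 * std::exp(u);
          double r = sig[k] - m;
          s += r * r;
        }
        return s;
      };
      double sse = sse_dki(p[0], p[1]);
      double lam = 1e-3;
      for (int it = 0; it < max_iter; ++it) {
        double A[3][3] = {{0}}, g[3] = {0};
        for (int k = 0; k < nb; ++k) {
          double u = -b[k] * p[0] + b[k] * b[k] * p[0] * p[0] * p[1] / 6.0;
          double m = s0 * std::exp(u);
          double r = sig[k] - m;
          double J0 = m * (-b[k] + b[k] * b[k] * p[0] * p[1] / 3.0);
          double J1 = m * (b[k] * b[k] * p[0] * p[0] / 6.0);
          A[0][0] += J0 * J0; A[0][1] += J0 * J1; A[1][1] += J1 * J1;
          g[0] += J0 * r; g[1] += J1 * r;
        }
        A[1][0] = A[0][1];
        double d[3];
        if (!lm_solve(A, g, lam, 2, d)) { lam *= 10.0; continue; }
        double pn[2] = {clampd(p[0] + d[0], bmd[0], bmd[1]),
                        clampd(p[1] + d[1], bmk[0], bmk[1])};
        double ssen = sse_dki(pn[0], pn[1]);
        if (ssen <= sse) {
          double step = 0.0;
          for (int i = 0; i < 2; ++i) {
            double sc = std::abs(p[i]) + 1e-12;
            step = std::max(step, std::abs(pn[i] - p[i]) / sc);
          }
          p[0] = pn[0]; p[1] = pn[1];
          sse = ssen;
          lam = std::max(lam / 3.0, 1e-14);
          if (step < tol) { converged = true; break; }
        } else {
          lam *= 5.0;
          if (lam > 1e12) break;
        }
      }
      MD = p[0]; MK = p[1];
    }
    for (int k = 0; k < nb; ++k) {
      double u = -b[k] * MD + b[k] * b[k] * MD * MD * MK / 6.0;
      pred[k] = s0 * std::exp(u);
    }
    MDv[v] = MD; MKv[v] = MK;
    R2[v] = r2_of(sig.data(), pred.data(), nb);
    valid[v] = true;
    conv[v] = converged;
  }
  return List::create(_["md"] = MDv, _["mk"] = MKv, _["r2"] = R2,
                      _["valid"] = valid, _["converged"] = conv);
}
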