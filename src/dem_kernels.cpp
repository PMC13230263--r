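// Compiled kernels for the DEM phase: RBC closure evaluation, soft-sphere
// Hertz contacts with cell-list neighbour search, and the velocity-Verlet
// substep loop with semi-implicit drag. Kept free of R allocations in the
// inner loops; everything is deterministic.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Guards {
  double di_floor, di_ceil, re_min, re_max, di_floor_lift;
};

// Deformation index correlation in (gamma_plus, u_r_plus); clamped.
inline double di_closure(double g, double ur, const Guards& gu) {
  double den = g * g * g * (10.0 + ur * ur * ur) +
               0.117 * g * g * (ur - ur * ur * ur * ur) + 0.0026;
  double di = (den <= 0.0) ? gu.di_floor : (g * g * g) / den;
  if (di < gu.di_floor) di = gu.di_floor;
  if (di > gu.di_ceil) di = gu.di_ceil;
  return di;
}

inline double cd_closure(double di, double rep) {
  return (169.0 * rep * rep * (di + 1.0) + 0.00146) / (rep * rep * rep);
}

inline double cl_closure(double di, double rep) {
  return -3.19 * di * di * di * di / rep + 2.48 * di / rep +
         0.0008 * rep / (di * di * di);
}

struct Geom {
  int type;          // 0 none, 1 cylinder, 2 planar slot
  double R_c, L, W;
  std::vector<double> h;  // half-height table (planar)
  double dxh;
};

inline double half_height(const Geom& g, double x) {
  if (g.h.empty()) return g.R_c;
  double xx = x - g.L * std::floor(x / g.L);
  double u = xx / g.dxh - 0.5;
  int n = (int)g.h.size();
  int i0 = (int)std::floor(u);
  double w = u - i0;
  int ia = ((i0 % n) + n) % n;
  int ib = ((i0 + 1) % n + n) % n;
  return (1.0 - w) * g.h[ia] + w * g.h[ib];
}

struct ContactWork {
  std::vector<double> F, T;  // 3n force / torque accumulators
  double max_overlap;        // relative to d_p
  std::vector<int> head, nxt;  // reusable cell-list buffers
  std::vector<int> pairs;      // Verlet pair list (i, j) within d_p + skin
};

// Build the candidate pair list with a cell list at cutoff = d_p + skin.
void build_pairs(const std::vector<double>& X, int n, double d_p, double skin,
                 const Geom& geom, ContactWork& w) {
  w.pairs.clear();
  if (n == 0) return;
  double cutoff = d_p + skin;
  double lo[3], hi[3];
  bool per[3] = {false, false, false};
  if (geom.type == 1) {
    lo[0] = -geom.R_c; hi[0] = geom.R_c; lo[1] = -geom.R_c; hi[1] = geom.R_c;
    lo[2] = 0.0; hi[2] = geom.L; per[2] = true;
  } else if (geom.type == 2) {
    lo[0] = 0.0; hi[0] = geom.L; per[0] = true;
    lo[1] = -geom.R_c; hi[1] = geom.R_c;
    lo[2] = -0.5 * geom.W; hi[2] = 0.5 * geom.W; per[2] = (geom.W > 0);
  } else {
    for (int c = 0; c < 3; ++c) { lo[c] = X[c]; hi[c] = X[c]; }
    for (int i = 1; i < n; ++i)
      for (int c = 0; c < 3; ++c) {
        lo[c] = std::min(lo[c], X[3 * i + c]);
        hi[c] = std::max(hi[c], X[3 * i + c]);
      }
    for (int c = 0; c < 3; ++c) { lo[c] -= cutoff; hi[c] += cutoff; }
  }
  int nc[3]; double cs[3];
  for (int c = 0; c < 3; ++c) {
    double ext = std::max(hi[c] - lo[c], cutoff);
    nc[c] = std::max(1, (int)std::floor(ext / cutoff));
    cs[c] = ext / nc[c];
  }
  int ncells = nc[0] * nc[1] * nc[2];
  w.head.assign(ncells, -1);
  w.nxt.assign(n, -1);
  auto cellco = [&](int i, int* ic) {
    for (int c = 0; c < 3; ++c) {
      double u = (X[3 * i + c] - lo[c]) / cs[c];
      int k = (int)std::floor(u);
      if (per[c]) k = ((k % nc[c]) + nc[c]) % nc[c];
      else k = std::max(0, std::min(nc[c] - 1, k));
      ic[c] = k;
    }
  };
  for (int i = 0; i < n; ++i) {
    int ic[3]; cellco(i, ic);
    int cell = ic[0] + nc[0] * (ic[1] + nc[1] * ic[2]);
    w.nxt[i] = w.head[cell]; w.head[cell] = i;
  }
  double cut2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    int ic[3]; cellco(i, ic);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int cc[3] = {ic[0] + dx, ic[1] + dy, ic[2] + dz};
          bool skip = false;
          for (int c = 0; c < 3; ++c) {
            if (per[c]) cc[c] = ((cc[c] % nc[c]) + nc[c]) % nc[c];
            else if (cc[c] < 0 || cc[c] >= nc[c]) { skip = true; break; }
          }
          if (skip) continue;
          int cell = cc[0] + nc[0] * (cc[1] + nc[1] * cc[2]);
          for (int j = w.head[cell]; j >= 0; j = w.nxt[j]) {
            if (j <= i) continue;
            double d[3];
            for (int c = 0; c < 3; ++c) {
              d[c] = X[3 * j + c] - X[3 * i + c];
              if (per[c]) {
                double Lc = hi[c] - lo[c];
                d[c] -= Lc * std::round(d[c] / Lc);
              }
            }
            double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
            if (r2 < cut2) { w.pairs.push_back(i); w.pairs.push_back(j); }
          }
        }
  }
}

// Hertz + damping + regularised Coulomb friction for one contact.
// n points from body A toward body B; overlap delta > 0.
inline void contact_pair(double delta, const double n[3],
                         const double va[3], const double oa[3],
                         const double vb[3], const double ob[3],
                         double a_cont, double R_eff, double m_eff,
                         double Estar, double beta_damp, double mu_f,
                         double* FA, double* TA, double* FB, double* TB) {
  // relative velocity of A's contact point w.r.t. B's
  double vrel[3];
  // omega x (a n) for A; B's lever is -a n
  vrel[0] = va[0] - vb[0] + a_cont * (oa[1] * n[2] - oa[2] * n[1]) +
            a_cont * (ob[1] * n[2] - ob[2] * n[1]);
  vrel[1] = va[1] - vb[1] + a_cont * (oa[2] * n[0] - oa[0] * n[2]) +
            a_cont * (ob[2] * n[0] - ob[0] * n[2]);
  vrel[2] = va[2] - vb[2] + a_cont * (oa[0] * n[1] - oa[1] * n[0]) +
            a_cont * (ob[0] * n[1] - ob[1] * n[0]);
  double vn = vrel[0] * n[0] + vrel[1] * n[1] + vrel[2] * n[2];
  double sq = std::sqrt(R_eff * delta);
  double Fn_el = (4.0 / 3.0) * Estar * sq * delta;       // repulsive magnitude
  double Sn = 2.0 * Estar * sq;
  double cn = 2.0 * std::sqrt(5.0 / 6.0) * beta_damp * std::sqrt(Sn * m_eff);
  double Fn_d = -cn * vn;                                 // opposes approach
  double Fn_tot = -Fn_el + Fn_d;                          // along +n on A
  // tangential: regularised Coulomb on the tangential surface velocity
  double vt[3] = {vrel[0] - vn * n[0], vrel[1] - vn * n[1], vrel[2] - vn * n[2]};
  double vtn = std::sqrt(vt[0] * vt[0] + vt[1] * vt[1] + vt[2] * vt[2]);
  double Ft[3] = {0.0, 0.0, 0.0};
  if (mu_f > 0.0 && vtn > 1e-30) {
    double fmag = mu_f * Fn_el * vtn / (vtn + 1e-5);
    Ft[0] = -fmag * vt[0] / vtn;
    Ft[1] = -fmag * vt[1] / vtn;
    Ft[2] = -fmag * vt[2] / vtn;
  }
  double F[3] = {Fn_tot * n[0] + Ft[0], Fn_tot * n[1] + Ft[1], Fn_tot * n[2] + Ft[2]};
  for (int c = 0; c < 3; ++c) { FA[c] += F[c]; if (FB) FB[c] -= F[c]; }
  // torque from the tangential force, lever a n (A) and -a n (B)
  double tq[3] = {a_cont * (n[1] * Ft[2] - n[2] * Ft[1]),
                  a_cont * (n[2] * Ft[0] - n[0] * Ft[2]),
                  a_cont * (n[0] * Ft[1] - n[1] * Ft[0])};
  for (int c = 0; c < 3; ++c) { TA[c] += tq[c]; if (TB) TB[c] += tq[c]; }
}

// Evaluate contact forces from the prebuilt pair list (w.pairs) plus walls.
void compute_contacts(const std::vector<double>& X, const std::vector<double>& V,
                      const std::vector<double>& O, int n, double d_p, double m_p,
                      double Estar, double beta_damp, double mu_f,
                      const Geom& geom, ContactWork& w) {
  w.F.assign(3 * n, 0.0);
  w.T.assign(3 * n, 0.0);
  w.max_overlap = 0.0;
  if (n == 0) return;
  double a = 0.5 * d_p;
  bool per[3] = {false, false, geom.type == 1};
  double Lp[3] = {0.0, 0.0, 0.0};
  if (geom.type == 1) { Lp[2] = geom.L; }
  if (geom.type == 2) {
    per[0] = true; Lp[0] = geom.L;
    if (geom.W > 0) { per[2] = true; Lp[2] = geom.W; }
  }
  double m_eff_pp = 0.5 * m_p, R_eff_pp = 0.25 * d_p;
  for (size_t q = 0; q + 1 < w.pairs.size(); q += 2) {
    int i = w.pairs[q], j = w.pairs[q + 1];
    double d[3];
    for (int c = 0; c < 3; ++c) {
      d[c] = X[3 * j + c] - X[3 * i + c];
      if (per[c]) d[c] -= Lp[c] * std::round(d[c] / Lp[c]);
    }
    double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
    if (r2 >= d_p * d_p || r2 <= 0.0) continue;
    double r = std::sqrt(r2);
    double nrm[3] = {d[0] / r, d[1] / r, d[2] / r};
    double delta = d_p - r;
    w.max_overlap = std::max(w.max_overlap, delta / d_p);
    contact_pair(delta, nrm, &V[3 * i], &O[3 * i], &V[3 * j], &O[3 * j],
                 a - 0.5 * delta, R_eff_pp, m_eff_pp, Estar, beta_damp,
                 mu_f, &w.F[3 * i], &w.T[3 * i], &w.F[3 * j], &w.T[3 * j]);
  }
  static const double vzero[3] = {0.0, 0.0, 0.0};
  for (int i = 0; i < n; ++i) {
    if (geom.type == 1) {
      double r = std::sqrt(X[3 * i] * X[3 * i] + X[3 * i + 1] * X[3 * i + 1]);
      double delta = r + a - geom.R_c;
      if (delta > 0.0 && r > 1e-30) {
        double nrm[3] = {X[3 * i] / r, X[3 * i + 1] / r, 0.0};  // toward wall
        w.max_overlap = std::max(w.max_overlap, delta / d_p);
        contact_pair(delta, nrm, &V[3 * i], &O[3 * i], vzero, vzero,
                     a - 0.5 * delta, a, m_p, Estar, beta_damp, mu_f,
                     &w.F[3 * i], &w.T[3 * i], nullptr, nullptr);
      }
    } else if (geom.type == 2) {
      double h = half_height(geom, X[3 * i]);
      double delta = std::fabs(X[3 * i + 1]) + a - h;
      if (delta > 0.0) {
        double nrm[3] = {0.0, X[3 * i + 1] >= 0 ? 1.0 : -1.0, 0.0};
        w.max_overlap = std::max(w.max_overlap, delta / d_p);
        contact_pair(delta, nrm, &V[3 * i], &O[3 * i], vzero, vzero,
                     a - 0.5 * delta, a, m_p, Estar, beta_damp, mu_f,
                     &w.F[3 * i], &w.T[3 * i], nullptr, nullptr);
      }
    }
  }
}

}  // namespace

// Kernel deposition of per-particle payload columns onto the (rn, s) grid:
// each particle's payload is distributed over the cells its bounding extent
// overlaps, with weights proportional to the 1D overlap lengths (normalised,
// so each payload column is conserved exactly).
// [[Rcpp::export]]
NumericVector cpp_deposit_fields(NumericVector rn, NumericVector s, double a,
                                 NumericMatrix payload, NumericVector rn_f,
                                 double ds, int n1, int n2, double L) {
  int m = payload.ncol();
  NumericVector out(n1 * n2 * m);
  out.attr("dim") = IntegerVector::create(n1, n2, m);
  double rn_lo = rn_f[0], rn_hi = rn_f[n1];
  double dr = (rn_hi - rn_lo) / n1;
  int n = rn.size();
  std::vector<double> wr(n1 + 2), wz(8);
  for (int q = 0; q < n; ++q) {
    double r0 = std::max(rn[q] - a, rn_lo), r1 = std::min(rn[q] + a, rn_hi);
    int i0 = std::min(std::max((int)std::floor((r0 - rn_lo) / dr), 0), n1 - 1);
    int i1 = std::min(std::max((int)std::ceil((r1 - rn_lo) / dr) - 1, 0), n1 - 1);
    double z0 = s[q] - a, z1 = s[q] + a;
    int k0 = (int)std::floor(z0 / ds), k1 = (int)std::floor(z1 / ds);
    double tot = 0.0;
    for (int i = i0; i <= i1; ++i) {
      double o = std::min(rn_f[i + 1], r1) - std::max(rn_f[i], r0);
      wr[i - i0] = o > 0 ? o : 0.0;
    }
    if ((int)wz.size() < k1 - k0 + 1) wz.resize(k1 - k0 + 1);
    for (int k = k0; k <= k1; ++k)
      wz[k - k0] = std::min((k + 1) * ds, z1) - std::max(k * ds, z0);
    for (int i = i0; i <= i1; ++i)
      for (int k = k0; k <= k1; ++k) tot += wr[i - i0] * wz[k - k0];
    if (tot <= 0) continue;
    for (int i = i0; i <= i1; ++i)
      for (int k = k0; k <= k1; ++k) {
        int kk = ((k % n2) + n2) % n2;
        double wq = wr[i - i0] * wz[k - k0] / tot;
        for (int j = 0; j < m; ++j)
          out[i + n1 * kk + n1 * n2 * j] += payload(q, j) * wq;
      }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_deposit(NumericVector rn, NumericVector s, double a,
                          double V_p, NumericVector rn_f, double ds,
                          int n1, int n2, double L) {
  NumericMatrix solid(n1, n2);
  double rn_lo = rn_f[0], rn_hi = rn_f[n1];
  double dr = (rn_hi - rn_lo) / n1;
  int n = rn.size();
  std::vector<double> wr(n1 + 2), wz(8);
  for (int q = 0; q < n; ++q) {
    double r0 = std::max(rn[q] - a, rn_lo), r1 = std::min(rn[q] + a, rn_hi);
    int i0 = std::min(std::max((int)std::floor((r0 - rn_lo) / dr), 0), n1 - 1);
    int i1 = std::min(std::max((int)std::ceil((r1 - rn_lo) / dr) - 1, 0), n1 - 1);
    double z0 = s[q] - a, z1 = s[q] + a;
    int k0 = (int)std::floor(z0 / ds), k1 = (int)std::floor(z1 / ds);
    double tot = 0.0;
    for (int i = i0; i <= i1; ++i) {
      double o = std::min(rn_f[i + 1], r1) - std::max(rn_f[i], r0);
      wr[i - i0] = o > 0 ? o : 0.0;
    }
    if ((int)wz.size() < k1 - k0 + 1) wz.resize(k1 - k0 + 1);
    for (int k = k0; k <= k1; ++k)
      wz[k - k0] = std::min((k + 1) * ds, z1) - std::max(k * ds, z0);
    for (int i = i0; i <= i1; ++i)
      for (int k = k0; k <= k1; ++k) tot += wr[i - i0] * wz[k - k0];
    if (tot <= 0) continue;
    for (int i = i0; i <= i1; ++i)
      for (int k = k0; k <= k1; ++k) {
        int kk = ((k % n2) + n2) % n2;
        solid(i, kk) += V_p * wr[i - i0] * wz[k - k0] / tot;
      }
  }
  return solid;
}

// [[Rcpp::export]]
NumericMatrix cpp_closures(NumericVector gamma_plus, NumericVector u_r_plus,
                           NumericVector re_p, NumericVector guards) {
  Guards gu{guards[0], guards[1], guards[2], guards[3], guards[4]};
  int n = gamma_plus.size();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double di = di_closure(gamma_plus[i], u_r_plus[i], gu);
    double rep = std::min(std::max(re_p[i], gu.re_min), gu.re_max);
    out(i, 0) = di;
    out(i, 1) = cd_closure(di, rep);
    out(i, 2) = cl_closure(std::max(di, gu.di_floor_lift), rep);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_contact_forces(NumericMatrix pos, NumericMatrix vel, NumericMatrix omega,
                        double d_p, double m_p, NumericVector cp,
                        int gtype, double R_c, double L, double W,
                        NumericVector h_table, double dx_table) {
  int n = pos.nrow();
  std::vector<double> X(3 * n), V(3 * n), O(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      X[3 * i + c] = pos(i, c); V[3 * i + c] = vel(i, c); O[3 * i + c] = omega(i, c);
    }
  Geom geom{gtype, R_c, L, W,
            std::vector<double>(h_table.begin(), h_table.end()), dx_table};
  double Estar = cp[0] / (2.0 * (1.0 - cp[1] * cp[1]));
  double e = cp[2];
  double le = std::log(e);
  double beta_damp = (e >= 1.0) ? 0.0 : -le / std::sqrt(le * le + M_PI * M_PI);
  ContactWork w;
  build_pairs(X, n, d_p, 0.0, geom, w);
  compute_contacts(X, V, O, n, d_p, m_p, Estar, beta_damp, cp[3], geom, w);
  NumericMatrix F(n, 3), T(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) { F(i, c) = w.F[3 * i + c]; T(i, c) = w.T[3 * i + c]; }
  return List::create(_["F"] = F, _["torque"] = T, _["max_overlap"] = w.max_overlap);
}

// [[Rcpp::export]]
List cpp_dem_substeps(NumericMatrix pos, NumericMatrix vel, NumericMatrix omega,
                      double d_p, double m_p, double I_p,
                      double rho_f, double nu, double u_av, double R_ref,
                      NumericVector guards,
                      NumericMatrix uf, NumericVector shear, NumericMatrix raddir,
                      NumericVector flowdir, NumericMatrix fconst,
                      NumericVector gvec, NumericVector cp,
                      int gtype, double R_c, double L, double W,
                      NumericVector h_table, double dx_table,
                      double dt, int n_sub,
                      bool fluid_on, bool drag_on, bool lift_on,
                      double s_plane, double V_p) {
  int n = pos.nrow();
  Guards gu{guards[0], guards[1], guards[2], guards[3], guards[4]};
  Geom geom{gtype, R_c, L, W,
            std::vector<double>(h_table.begin(), h_table.end()), dx_table};
  double Estar = cp[0] / (2.0 * (1.0 - cp[1] * cp[1]));
  double e = cp[2];
  double le = std::log(e);
  double beta_damp = (e >= 1.0) ? 0.0 : -le / std::sqrt(le * le + M_PI * M_PI);
  std::vector<double> X(3 * n), V(3 * n), O(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      X[3 * i + c] = pos(i, c); V[3 * i + c] = vel(i, c); O[3 * i + c] = omega(i, c);
    }
  int sc = (gtype == 2) ? 0 : 2;                 // streamwise coordinate index
  std::vector<double> drag_acc(3 * n, 0.0), lift_acc(3 * n, 0.0);
  std::vector<double> DI(n, NA_REAL), CD(n, NA_REAL), CL(n, NA_REAL), REP(n, 0.0);
  double crossings = 0.0, max_overlap = 0.0;
  ContactWork w;
  double dt2 = 0.5 * dt;

  // Verlet pair list with a skin of half a diameter, rebuilt once any pair
  // of particles could have closed the skin gap since the last build
  double skin = 0.5 * d_p;
  double drift_bound = 0.0;
  build_pairs(X, n, d_p, skin, geom, w);

  // one force evaluation: fills Fnd (non-drag force), beta (drag lin. coeff)
  std::vector<double> Fnd(3 * n), beta(n), Fl(3 * n);
  auto eval_forces = [&](bool record) {
    if (2.0 * drift_bound > skin) {
      build_pairs(X, n, d_p, skin, geom, w);
      drift_bound = 0.0;
    }
    compute_contacts(X, V, O, n, d_p, m_p, Estar, beta_damp, cp[3], geom, w);
    max_overlap = std::max(max_overlap, w.max_overlap);
    for (int i = 0; i < n; ++i) {
      double slip[3] = {0, 0, 0}, smag = 0.0;
      if (fluid_on) {
        for (int c = 0; c < 3; ++c) slip[c] = V[3 * i + c] - uf(i, c);
        smag = std::sqrt(slip[0] * slip[0] + slip[1] * slip[1] + slip[2] * slip[2]);
      }
      double rep = d_p * smag / nu;
      double rep_eff = std::min(std::max(rep, gu.re_min), gu.re_max);
      double urp = (u_av > 0)
                       ? (slip[0] * flowdir[0] + slip[1] * flowdir[1] +
                          slip[2] * flowdir[2]) / u_av
                       : 0.0;
      double g = shear[i] * R_ref * R_ref / nu;
      double di = di_closure(g, urp, gu);
      double b = 0.0;
      if (fluid_on && drag_on) {
        double cd = cd_closure(di, rep_eff);
        b = 0.125 * cd * rho_f * M_PI * d_p * d_p * smag;
        if (record) { CD[i] = cd; }
      }
      double flv[3] = {0, 0, 0};
      if (fluid_on && lift_on) {
        double cl = cl_closure(std::max(di, gu.di_floor_lift), rep_eff);
        double mag = cl * rho_f * d_p * d_p * d_p * d_p *
                     (shear[i] * shear[i] + smag * smag / (d_p * d_p));
        for (int c = 0; c < 3; ++c) flv[c] = mag * raddir(i, c);
        if (record) { CL[i] = cl; }
      }
      if (record) { DI[i] = di; REP[i] = rep; }
      beta[i] = b;
      for (int c = 0; c < 3; ++c) {
        Fl[3 * i + c] = flv[c];
        Fnd[3 * i + c] = fconst(i, c) + flv[c] + m_p * gvec[c] + w.F[3 * i + c];
      }
    }
  };

  // velocity-Verlet with one force evaluation per substep: the forces
  // computed after the drift serve both the trailing half-kick and the next
  // substep's leading half-kick (velocity-dependent parts lag half a step)
  eval_forces(false);
  for (int step = 0; step < n_sub; ++step) {
    double vmax2 = 0.0;
    for (int i = 0; i < n; ++i) {
      double fac = 1.0 + beta[i] * dt2 / m_p;
      for (int c = 0; c < 3; ++c) {
        double ufl = fluid_on ? uf(i, c) : 0.0;
        V[3 * i + c] = (V[3 * i + c] +
                        (dt2 / m_p) * (Fnd[3 * i + c] + beta[i] * ufl)) / fac;
        O[3 * i + c] += (dt2 / I_p) * w.T[3 * i + c];
      }
      // drift + crossing count
      double s_old = X[3 * i + sc];
      double v2 = V[3 * i] * V[3 * i] + V[3 * i + 1] * V[3 * i + 1] +
                  V[3 * i + 2] * V[3 * i + 2];
      if (v2 > vmax2) vmax2 = v2;
      for (int c = 0; c < 3; ++c) X[3 * i + c] += dt * V[3 * i + c];
      if (s_plane >= 0.0 && L > 0.0) {
        double aofs = s_old - s_plane;
        aofs -= L * std::round(aofs / L);
        double bofs = aofs + dt * V[3 * i + sc];
        if (aofs < 0.0 && bofs >= 0.0) crossings += V_p;
        else if (aofs >= 0.0 && bofs < 0.0) crossings -= V_p;
      }
      // periodic wrapping
      if (gtype == 1) {
        X[3 * i + 2] -= L * std::floor(X[3 * i + 2] / L);
      } else if (gtype == 2) {
        X[3 * i] -= L * std::floor(X[3 * i] / L);
        if (W > 0) {
          double zz = X[3 * i + 2] + 0.5 * W;
          X[3 * i + 2] = zz - W * std::floor(zz / W) - 0.5 * W;
        }
      }
    }
    drift_bound += dt * std::sqrt(vmax2);
    bool last = (step == n_sub - 1);
    eval_forces(last);
    for (int i = 0; i < n; ++i) {
      double fac = 1.0 + beta[i] * dt2 / m_p;
      for (int c = 0; c < 3; ++c) {
        double ufl = fluid_on ? uf(i, c) : 0.0;
        V[3 * i + c] = (V[3 * i + c] +
                        (dt2 / m_p) * (Fnd[3 * i + c] + beta[i] * ufl)) / fac;
        O[3 * i + c] += (dt2 / I_p) * w.T[3 * i + c];
        drag_acc[3 * i + c] += beta[i] * (uf(i, c) - V[3 * i + c]);
        lift_acc[3 * i + c] += Fl[3 * i + c];
      }
    }
  }
  NumericMatrix P(n, 3), Vm(n, 3), Om(n, 3), Fd(n, 3), Flm(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      P(i, c) = X[3 * i + c]; Vm(i, c) = V[3 * i + c]; Om(i, c) = O[3 * i + c];
      Fd(i, c) = n_sub > 0 ? drag_acc[3 * i + c] / n_sub : 0.0;
      Flm(i, c) = n_sub > 0 ? lift_acc[3 * i + c] / n_sub : 0.0;
    }
  return List::create(_["pos"] = P, _["vel"] = Vm, _["omega"] = Om,
                      _["F_drag_mean"] = Fd, _["F_lift_mean"] = Flm,
                      _["DI"] = NumericVector(DI.begin(), DI.end()),
                      _["C_d"] = NumericVector(CD.begin(), CD.end()),
                      _["C_l"] = NumericVector(CL.begin(), CL.end()),
                      _["Re_p"] = NumericVector(REP.begin(), REP.end()),
                      _["max_overlap"] = max_overlap,
                      _["crossing_volume"] = crossings);
}
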