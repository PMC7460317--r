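// Compiled inner kernels of the coupled estuary model.
//
// hydro_step_cpp: one forward-backward step of the depth-averaged
//   shallow-water equations on the Arakawa C grid (flux-form continuity with
//   upwind face depths and a positivity limiter; momentum with upwind
//   advection, semi-implicit Chezy-Manning friction, Coriolis and eddy
//   viscosity). Mirrors the R reference kernel hydro_step_core_r.
//
// transport_core_cpp: finite-volume advection-dispersion update of the
//   depth-integrated Cr mass (upwind advection by the hydrodynamic face
//   fluxes, central dispersion, per-cell mass-positivity limiter, boundary
//   export/import ledger). Mirrors transport_core_r.

#include <Rcpp.h>
using namespace Rcpp;

static inline double dmax(double a, double b) { return a > b ? a : b; }
static inline double dmin(double a, double b) { return a < b ? a : b; }

// side codes: 0 = N (j = ny-1, face fj = ny), 1 = S, 2 = E, 3 = W
static void inflow_velocity(NumericMatrix u, NumericMatrix v,
                            const NumericMatrix& zeta, const NumericMatrix& d,
                            const IntegerVector& infl_i, const IntegerVector& infl_j,
                            const IntegerVector& infl_side, double q_per_cell,
                            double dx, double dy, double hd) {
  for (int r = 0; r < infl_i.size(); ++r) {
    int i = infl_i[r], j = infl_j[r];
    double h = dmax(d(i, j) + zeta(i, j), hd);
    switch (infl_side[r]) {
    case 0: v(i, j + 1) = -q_per_cell / (dx * h); break;
    case 1: v(i, 0) = q_per_cell / (dx * h); break;
    case 2: u(i + 1, j) = -q_per_cell / (dy * h); break;
    default: u(0, j) = q_per_cell / (dy * h);
    }
  }
}

// [[Rcpp::export]]
List hydro_step_cpp(NumericMatrix zeta0, NumericMatrix u0, NumericMatrix v0,
                    double dt, NumericMatrix d, LogicalMatrix active,
                    NumericMatrix manning, double g, double f, double K,
                    double rho_w, NumericMatrix Fx, NumericMatrix Fy,
                    bool has_force, double hd, double dx, double dy,
                    IntegerMatrix tide_idx, double tide_level,
                    IntegerVector infl_i, IntegerVector infl_j,
                    IntegerVector infl_side, double q_per_cell) {
  const int nx = zeta0.nrow(), ny = zeta0.ncol();
  NumericMatrix zeta = clone(zeta0), u = clone(u0), v = clone(v0);
  inflow_velocity(u, v, zeta, d, infl_i, infl_j, infl_side, q_per_cell, dx, dy, hd);

  NumericMatrix qx(nx + 1, ny), qy(nx, ny + 1);
  NumericMatrix uin(nx + 1, ny), vin(nx, ny + 1); // closed faces zeroed

  // interior x faces: fi between cells fi-1 and fi
  for (int j = 0; j < ny; ++j) {
    for (int fi = 1; fi < nx; ++fi) {
      bool pair = active(fi - 1, j) && active(fi, j);
      double hf = dmax(zeta(fi - 1, j), zeta(fi, j)) + dmin(d(fi - 1, j), d(fi, j));
      bool open = pair && hf > hd;
      double ui = open ? u(fi, j) : 0.0;
      uin(fi, j) = ui;
      qx(fi, j) = hf * ui;
    }
  }
  if (ny >= 2) {
    for (int fj = 1; fj < ny; ++fj) {
      for (int i = 0; i < nx; ++i) {
        bool pair = active(i, fj - 1) && active(i, fj);
        double hf = dmax(zeta(i, fj - 1), zeta(i, fj)) + dmin(d(i, fj - 1), d(i, fj));
        bool open = pair && hf > hd;
        double vi = open ? v(i, fj) : 0.0;
        vin(i, fj) = vi;
        qy(i, fj) = hf * vi;
      }
    }
  }
  // inflow boundary faces carry their prescribed flux
  for (int r = 0; r < infl_i.size(); ++r) {
    int i = infl_i[r], j = infl_j[r];
    double h = dmax(d(i, j) + zeta(i, j), hd);
    switch (infl_side[r]) {
    case 0: qy(i, j + 1) = v(i, j + 1) * h; break;
    case 1: qy(i, 0) = v(i, 0) * h; break;
    case 2: qx(i + 1, j) = u(i + 1, j) * h; break;
    default: qx(0, j) = u(0, j) * h;
    }
  }

  // positivity limiter: volume export of a cell capped at 90% of its content
  {
    NumericMatrix s(nx, ny);
    bool any_need = false;
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        double out = (dmax(qx(i + 1, j), 0.0) + dmax(-qx(i, j), 0.0)) / dx +
                     (dmax(qy(i, j + 1), 0.0) + dmax(-qy(i, j), 0.0)) / dy;
        double h = d(i, j) + zeta(i, j);
        if (active(i, j) && out * dt > 0.9 * dmax(h, 0.0)) {
          s(i, j) = dmax(0.9 * h, 0.0) / (out * dt);
          any_need = true;
        } else {
          s(i, j) = 1.0;
        }
      }
    }
    if (any_need) {
      for (int j = 0; j < ny; ++j)
        for (int fi = 1; fi < nx; ++fi)
          qx(fi, j) *= qx(fi, j) > 0 ? s(fi - 1, j) : s(fi, j);
      if (ny >= 2)
        for (int fj = 1; fj < ny; ++fj)
          for (int i = 0; i < nx; ++i)
            qy(i, fj) *= qy(i, fj) > 0 ? s(i, fj - 1) : s(i, fj);
    }
  }

  // continuity (forward)
  NumericMatrix zn(nx, ny);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (active(i, j)) {
        double div = (qx(i + 1, j) - qx(i, j)) / dx + (qy(i, j + 1) - qy(i, j)) / dy;
        zn(i, j) = zeta(i, j) - dt * div;
      } else {
        zn(i, j) = zeta(i, j);
      }
    }
  }
  for (int r = 0; r < tide_idx.nrow(); ++r) {
    zn(tide_idx(r, 0), tide_idx(r, 1)) = tide_level;
  }
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (!R_finite(zn(i, j))) {
        stop("non-finite surface elevation at cell (%d, %d)", i + 1, j + 1);
      }
    }
  }

  // u momentum (backward in the surface gradient)
  NumericMatrix un_(nx + 1, ny), vn_(nx, ny + 1);
  for (int j = 0; j < ny; ++j) {
    for (int fi = 1; fi < nx; ++fi) {
      bool pair = active(fi - 1, j) && active(fi, j);
      double hf = dmax(zn(fi - 1, j), zn(fi, j)) + dmin(d(fi - 1, j), d(fi, j));
      if (!(pair && hf > hd)) { un_(fi, j) = 0.0; continue; }
      hf = dmax(hf, hd);
      double ui = uin(fi, j);
      double gx = (zn(fi, j) - zn(fi - 1, j)) / dx;
      double vbar = 0.0;
      if (ny >= 2) {
        vbar = 0.25 * (v(fi - 1, j) + v(fi, j) + v(fi - 1, j + 1) + v(fi, j + 1));
      }
      double speed = std::sqrt(ui * ui + vbar * vbar);
      double nf = 0.5 * (manning(fi - 1, j) + manning(fi, j));
      double Cf = std::pow(hf, 1.0 / 6.0) / nf;
      double fric = g * speed / (Cf * Cf * hf);
      double dudx = ui > 0 ? (u(fi, j) - u(fi - 1, j)) / dx
                           : (u(fi + 1, j) - u(fi, j)) / dx;
      double up = j > 0 ? uin(fi, j - 1) : uin(fi, j);
      double dn = j < ny - 1 ? uin(fi, j + 1) : uin(fi, j);
      double dudy = vbar > 0 ? (ui - up) / dy : (dn - ui) / dy;
      double adv = ui * dudx + vbar * dudy;
      double lap = (u(fi + 1, j) - 2.0 * ui + u(fi - 1, j)) / (dx * dx) +
                   (dn - 2.0 * ui + up) / (dy * dy);
      double rhs = -g * gx + f * vbar - adv + K * lap;
      if (has_force) {
        rhs += 0.5 * (Fx(fi - 1, j) + Fx(fi, j)) / (rho_w * hf);
      }
      un_(fi, j) = (ui + dt * rhs) / (1.0 + dt * fric);
    }
  }
  if (ny >= 2) {
    for (int fj = 1; fj < ny; ++fj) {
      for (int i = 0; i < nx; ++i) {
        bool pair = active(i, fj - 1) && active(i, fj);
        double hf = dmax(zn(i, fj - 1), zn(i, fj)) + dmin(d(i, fj - 1), d(i, fj));
        if (!(pair && hf > hd)) { vn_(i, fj) = 0.0; continue; }
        hf = dmax(hf, hd);
        double vi = vin(i, fj);
        double gy = (zn(i, fj) - zn(i, fj - 1)) / dy;
        double ubar = 0.25 * (u(i, fj - 1) + u(i + 1, fj - 1) + u(i, fj) + u(i + 1, fj));
        double speed = std::sqrt(vi * vi + ubar * ubar);
        double nf = 0.5 * (manning(i, fj - 1) + manning(i, fj));
        double Cf = std::pow(hf, 1.0 / 6.0) / nf;
        double fric = g * speed / (Cf * Cf * hf);
        double dvdy = vi > 0 ? (v(i, fj) - v(i, fj - 1)) / dy
                             : (v(i, fj + 1) - v(i, fj)) / dy;
        double vw = i > 0 ? vin(i - 1, fj) : vin(i, fj);
        double ve = i < nx - 1 ? vin(i + 1, fj) : vin(i, fj);
        double dvdx = ubar > 0 ? (vi - vw) / dx : (ve - vi) / dx;
        double adv = ubar * dvdx + vi * dvdy;
        double lap = (ve - 2.0 * vi + vw) / (dx * dx) +
                     (v(i, fj + 1) - 2.0 * vi + v(i, fj - 1)) / (dy * dy);
        double rhs = -g * gy - f * ubar - adv + K * lap;
        if (has_force) {
          rhs += 0.5 * (Fy(i, fj - 1) + Fy(i, fj)) / (rho_w * hf);
        }
        vn_(i, fj) = (vi + dt * rhs) / (1.0 + dt * fric);
      }
    }
  }
  inflow_velocity(un_, vn_, zn, d, infl_i, infl_j, infl_side, q_per_cell, dx, dy, hd);

  return List::create(_["zeta"] = zn, _["u"] = un_, _["v"] = vn_,
                      _["qx"] = qx, _["qy"] = qy);
}

// [[Rcpp::export]]
List transport_core_cpp(NumericMatrix m0, NumericMatrix h0,
                        NumericMatrix qx, NumericMatrix qy, double dt,
                        LogicalMatrix interior, LogicalMatrix tidecell,
                        double Dx, double Dy, double cbnd, double hd,
                        double dx, double dy,
                        IntegerVector infl_i, IntegerVector infl_j,
                        IntegerVector infl_side) {
  const int nx = m0.nrow(), ny = m0.ncol();
  NumericMatrix cc(nx, ny);
  double mmax = 0.0;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      cc(i, j) = interior(i, j) ? m0(i, j) / dmax(h0(i, j), 1e-12) : 0.0;
      if (m0(i, j) > mmax) mmax = m0(i, j);
    }
  }

  NumericMatrix Fx(nx + 1, ny), Fy(nx, ny + 1);
  for (int j = 0; j < ny; ++j) {
    for (int fi = 1; fi < nx; ++fi) {
      bool iL = interior(fi - 1, j), iR = interior(fi, j);
      double F = 0.0;
      if (iL && iR) {
        double q = qx(fi, j);
        F = q * (q > 0 ? cc(fi - 1, j) : cc(fi, j));
        if (h0(fi - 1, j) > hd && h0(fi, j) > hd) {
          double hf = 0.5 * (h0(fi - 1, j) + h0(fi, j));
          F += -Dx * hf * (cc(fi, j) - cc(fi - 1, j)) / dx;
        }
      } else if ((iL && tidecell(fi, j)) || (iR && tidecell(fi - 1, j))) {
        double q = qx(fi, j);
        double cup = q > 0 ? (iL ? cc(fi - 1, j) : cbnd)
                           : (iR ? cc(fi, j) : cbnd);
        F = q * cup;
      }
      Fx(fi, j) = F;
    }
  }
  if (ny >= 2) {
    for (int fj = 1; fj < ny; ++fj) {
      for (int i = 0; i < nx; ++i) {
        bool iB = interior(i, fj - 1), iT = interior(i, fj);
        double F = 0.0;
        if (iB && iT) {
          double q = qy(i, fj);
          F = q * (q > 0 ? cc(i, fj - 1) : cc(i, fj));
          if (h0(i, fj - 1) > hd && h0(i, fj) > hd) {
            double hf = 0.5 * (h0(i, fj - 1) + h0(i, fj));
            F += -Dy * hf * (cc(i, fj) - cc(i, fj - 1)) / dy;
          }
        } else if ((iB && tidecell(i, fj)) || (iT && tidecell(i, fj - 1))) {
          double q = qy(i, fj);
          double cup = q > 0 ? (iB ? cc(i, fj - 1) : cbnd)
                             : (iT ? cc(i, fj) : cbnd);
          F = q * cup;
        }
        Fy(i, fj) = F;
      }
    }
  }
  // prescribed-inflow edge faces
  for (int r = 0; r < infl_i.size(); ++r) {
    int i = infl_i[r], j = infl_j[r];
    double q;
    switch (infl_side[r]) {
    case 0: q = qy(i, j + 1); Fy(i, j + 1) = q * (q < 0 ? cbnd : cc(i, j)); break;
    case 1: q = qy(i, 0); Fy(i, 0) = q * (q > 0 ? cbnd : cc(i, j)); break;
    case 2: q = qx(i + 1, j); Fx(i + 1, j) = q * (q < 0 ? cbnd : cc(i, j)); break;
    default: q = qx(0, j); Fx(0, j) = q * (q > 0 ? cbnd : cc(i, j));
    }
  }

  // mass-positivity limiter: a cell cannot export more mass than it holds
  {
    NumericMatrix s(nx, ny);
    bool any_need = false;
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        s(i, j) = 1.0;
        if (!interior(i, j)) continue;
        double out = (dmax(Fx(i + 1, j), 0.0) + dmax(-Fx(i, j), 0.0)) / dx +
                     (dmax(Fy(i, j + 1), 0.0) + dmax(-Fy(i, j), 0.0)) / dy;
        if (out > 0 && out * dt > m0(i, j)) {
          s(i, j) = m0(i, j) / (out * dt);
          any_need = true;
        }
      }
    }
    if (any_need) {
      for (int j = 0; j < ny; ++j) {
        for (int fi = 0; fi <= nx; ++fi) {
          double F = Fx(fi, j);
          if (F == 0.0) continue;
          int src = F > 0 ? fi - 1 : fi;
          if (src >= 0 && src < nx) Fx(fi, j) *= s(src, j);
        }
      }
      for (int fj = 0; fj <= ny; ++fj) {
        for (int i = 0; i < nx; ++i) {
          double F = Fy(i, fj);
          if (F == 0.0) continue;
          int src = F > 0 ? fj - 1 : fj;
          if (src >= 0 && src < ny) Fy(i, fj) *= s(i, src);
        }
      }
    }
  }

  NumericMatrix m(nx, ny);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (!interior(i, j)) { m(i, j) = 0.0; continue; }
      double div = (Fx(i + 1, j) - Fx(i, j)) / dx + (Fy(i, j + 1) - Fy(i, j)) / dy;
      m(i, j) = m0(i, j) - dt * div;
    }
  }

  // boundary ledger: faces between interior and tide cells, plus inflow faces
  double exported = 0.0, imported = 0.0;
  for (int j = 0; j < ny; ++j) {
    for (int fi = 1; fi < nx; ++fi) {
      bool iL = interior(fi - 1, j), iR = interior(fi, j);
      double outw = 0.0;
      if (iL && tidecell(fi, j)) outw = Fx(fi, j) * dy * dt;
      else if (iR && tidecell(fi - 1, j)) outw = -Fx(fi, j) * dy * dt;
      else continue;
      if (outw > 0) exported += outw; else imported -= outw;
    }
  }
  if (ny >= 2) {
    for (int fj = 1; fj < ny; ++fj) {
      for (int i = 0; i < nx; ++i) {
        bool iB = interior(i, fj - 1), iT = interior(i, fj);
        double outw = 0.0;
        if (iB && tidecell(i, fj)) outw = Fy(i, fj) * dx * dt;
        else if (iT && tidecell(i, fj - 1)) outw = -Fy(i, fj) * dx * dt;
        else continue;
        if (outw > 0) exported += outw; else imported -= outw;
      }
    }
  }
  for (int r = 0; r < infl_i.size(); ++r) {
    int i = infl_i[r], j = infl_j[r];
    double outw;
    switch (infl_side[r]) {
    case 0: outw = Fy(i, j + 1) * dx * dt; break;
    case 1: outw = -Fy(i, 0) * dx * dt; break;
    case 2: outw = Fx(i + 1, j) * dy * dt; break;
    default: outw = -Fx(0, j) * dy * dt;
    }
    if (outw > 0) exported += outw; else imported -= outw;
  }

  double tol = -1e-9 * dmax(mmax, 1.0);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double mv = m(i, j);
      if (!R_finite(mv)) stop("non-finite concentration in transport step");
      if (mv < 0) {
        if (mv < tol) stop("transport produced negative mass: stability bound violated");
        m(i, j) = 0.0;
      }
    }
  }
  return List::create(_["m"] = m, _["exported"] = exported,
                      _["imported"] = imported);
}
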