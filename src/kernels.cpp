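// Low-level kernels for the MAC-grid fractional-step solver and polygon
// rasterization. Fields are R matrices with row index = x, column index = y:
//   u: (nx+1) x ny   at x-faces, u(i,j) at (i*dx,      (j+0.5)*dy)
//   v: nx x (ny+1)   at y-faces, v(i,j) at ((i+0.5)*dx, j*dy)
//   p/chi: nx x ny   at centers
// Boundary modes: 0 = fully periodic, 1 = closed no-slip tank (optional
// moving lid), 2 = forward flight (uniform inflow u=-Vinf on the right
// boundary, zero-gauge pressure outflow on the left, free-slip top/bottom),
// 3 = channel (periodic in x, no-slip bottom wall and moving lid).
#include <Rcpp.h>
using namespace Rcpp;

static inline int wrap(int i, int n) { return ((i % n) + n) % n; }

// ---- predictor: explicit advection (2nd-order upwind-biased) + diffusion ----

// [[Rcpp::export]]
List predict_velocity(NumericMatrix u, NumericMatrix v,
                      double dx, double dy, double nu, double dt,
                      int bc, double Vinf, double lid_u) {
  const int nx = v.nrow();
  const int ny = u.ncol();
  NumericMatrix us(nx + 1, ny), vs(nx, ny + 1);
  const bool px = (bc == 0 || bc == 3);   // periodic in x
  const bool py = (bc == 0);              // periodic in y
  const bool wall_y = (bc == 1 || bc == 3);

  // ghost accessors for u (tangential ghosts in y; x handled by loop ranges)
  auto U = [&](int i, int j) -> double {
    if (px) i = wrap(i, nx);
    if (py) return u(i, wrap(j, ny));
    if (j < 0) {
      if (wall_y) return -u(i, 0);             // no-slip bottom wall
      return u(i, 0);                          // free-slip
    }
    if (j > ny - 1) {
      if (wall_y) return 2.0 * lid_u - u(i, ny - 1);
      return u(i, ny - 1);
    }
    return u(i, j);
  };
  auto V = [&](int i, int j) -> double {
    if (px) i = wrap(i, nx);
    if (py) return v(i, wrap(j, ny));
    if (i < 0) {
      if (bc == 1) return -v(0, j);            // no-slip left wall
      return v(0, j);                          // outflow: zero-gradient
    }
    if (i > nx - 1) {
      return -v(nx - 1, j);                    // no-slip wall / uniform inflow
    }
    return v(i, j);
  };

  // u-momentum
  {
    int i0 = px ? 0 : 1;
    int i1 = nx - 1;
    for (int j = 0; j < ny; ++j) {
      for (int i = i0; i <= i1; ++i) {
        double uc = u(i, j);
        double vb = 0.25 * (V(i - 1, j) + V(i, j) + V(i - 1, j + 1) + V(i, j + 1));
        double dudx;
        if (uc >= 0.0) {
          if (px || i >= 2)
            dudx = (3.0 * uc - 4.0 * U(i - 1, j) + U(i - 2, j)) / (2.0 * dx);
          else
            dudx = (uc - U(i - 1, j)) / dx;
        } else {
          if (px || i <= nx - 2)
            dudx = (-3.0 * uc + 4.0 * U(i + 1, j) - U(i + 2, j)) / (2.0 * dx);
          else
            dudx = (U(i + 1, j) - uc) / dx;
        }
        double dudy;
        if (vb >= 0.0) {
          if (py || j >= 2)
            dudy = (3.0 * uc - 4.0 * U(i, j - 1) + U(i, j - 2)) / (2.0 * dy);
          else
            dudy = (uc - U(i, j - 1)) / dy;
        } else {
          if (py || j <= ny - 3)
            dudy = (-3.0 * uc + 4.0 * U(i, j + 1) - U(i, j + 2)) / (2.0 * dy);
          else
            dudy = (U(i, j + 1) - uc) / dy;
        }
        double lap = (U(i + 1, j) - 2.0 * uc + U(i - 1, j)) / (dx * dx)
                   + (U(i, j + 1) - 2.0 * uc + U(i, j - 1)) / (dy * dy);
        us(i, j) = uc + dt * (nu * lap - uc * dudx - vb * dudy);
      }
    }
    if (px) {
      for (int j = 0; j < ny; ++j) us(nx, j) = us(0, j);
    } else if (bc == 1) {
      for (int j = 0; j < ny; ++j) { us(0, j) = 0.0; us(nx, j) = 0.0; }
    } else {
      for (int j = 0; j < ny; ++j) { us(nx, j) = -Vinf; us(0, j) = us(1, j); }
    }
  }

  // v-momentum
  {
    int j0 = py ? 0 : 1;
    int j1 = ny - 1;
    for (int j = j0; j <= j1; ++j) {
      for (int i = 0; i < nx; ++i) {
        double vc = v(i, j);
        double ub = 0.25 * (U(i, j - 1) + U(i, j) + U(i + 1, j - 1) + U(i + 1, j));
        double dvdy;
        if (vc >= 0.0) {
          if (py || j >= 2)
            dvdy = (3.0 * vc - 4.0 * V(i, j - 1) + V(i, j - 2)) / (2.0 * dy);
          else
            dvdy = (vc - V(i, j - 1)) / dy;
        } else {
          if (py || j <= ny - 2)
            dvdy = (-3.0 * vc + 4.0 * V(i, j + 1) - V(i, j + 2)) / (2.0 * dy);
          else
            dvdy = (V(i, j + 1) - vc) / dy;
        }
        double dvdx;
        if (ub >= 0.0) {
          if (px || i >= 2)
            dvdx = (3.0 * vc - 4.0 * V(i - 1, j) + V(i - 2, j)) / (2.0 * dx);
          else
            dvdx = (vc - V(i - 1, j)) / dx;
        } else {
          if (px || i <= nx - 3)
            dvdx = (-3.0 * vc + 4.0 * V(i + 1, j) - V(i + 2, j)) / (2.0 * dx);
          else
            dvdx = (V(i + 1, j) - vc) / dx;
        }
        double lap = (V(i + 1, j) - 2.0 * vc + V(i - 1, j)) / (dx * dx)
                   + (V(i, j + 1) - 2.0 * vc + V(i, j - 1)) / (dy * dy);
        vs(i, j) = vc + dt * (nu * lap - ub * dvdx - vc * dvdy);
      }
    }
    if (py) {
      for (int i = 0; i < nx; ++i) vs(i, ny) = vs(i, 0);
    } else {
      for (int i = 0; i < nx; ++i) { vs(i, 0) = 0.0; vs(i, ny) = 0.0; }
    }
  }
  // v ghost accessor above needed v at j outside for dvdy near walls;
  // loop bounds keep j-2/j+2 within range except bc==0 (wrapped).
  return List::create(_["u"] = us, _["v"] = vs);
}

// ---- implicit Brinkman penalization toward rigid-body motion ----
// u_new = (u + (dt*chi/eta) * u_body) / (1 + dt*chi/eta)
// Returns the raw momentum deficit sums  sum(u - u_new)  and  sum(v - v_new);
// the caller scales by rho*dx*dy/dt to obtain the force on the body (N/m).

// [[Rcpp::export]]
List penalize_rigid(NumericMatrix u, NumericMatrix v,
                    NumericMatrix chiu, NumericMatrix chiv,
                    double vbx, double vby, double omega,
                    double xc, double yc,
                    double dx, double dy, double dt, double eta) {
  const int nxu = u.nrow(), nyu = u.ncol();
  const int nxv = v.nrow(), nyv = v.ncol();
  NumericMatrix un(nxu, nyu), vn(nxv, nyv);
  double fx = 0.0, fy = 0.0;
  for (int j = 0; j < nyu; ++j) {
    double yf = (j + 0.5) * dy;
    for (int i = 0; i < nxu; ++i) {
      double c = chiu(i, j);
      if (c <= 0.0) { un(i, j) = u(i, j); continue; }
      double xf = i * dx;
      double ub = vbx - omega * (yf - yc);
      double a = dt * c / eta;
      double nu_ = (u(i, j) + a * ub) / (1.0 + a);
      fx += u(i, j) - nu_;
      un(i, j) = nu_;
      (void)xf;
    }
  }
  for (int j = 0; j < nyv; ++j) {
    double yf = j * dy;
    for (int i = 0; i < nxv; ++i) {
      double c = chiv(i, j);
      if (c <= 0.0) { vn(i, j) = v(i, j); continue; }
      double xf = (i + 0.5) * dx;
      double vb = vby + omega * (xf - xc);
      double a = dt * c / eta;
      double nv_ = (v(i, j) + a * vb) / (1.0 + a);
      fy += v(i, j) - nv_;
      vn(i, j) = nv_;
    }
    (void)yf;
  }
  return List::create(_["u"] = un, _["v"] = vn, _["fx"] = fx, _["fy"] = fy);
}

// maximum over cells of |u_c| + |v_c| (combined Courant speed)

// [[Rcpp::export]]
double max_courant_speed(NumericMatrix u, NumericMatrix v) {
  const int nx = v.nrow(), ny = u.ncol();
  double m = 0.0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double uc = 0.5 * (u(i, j) + u(i + 1, j));
      double vc = 0.5 * (v(i, j) + v(i, j + 1));
      double s = std::fabs(uc) + std::fabs(vc);
      if (s > m) m = s;
    }
  return m;
}

// [[Rcpp::export]]
NumericMatrix divergence_mac(NumericMatrix u, NumericMatrix v,
                             double dx, double dy) {
  const int nx = v.nrow(), ny = u.ncol();
  NumericMatrix d(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      d(i, j) = (u(i + 1, j) - u(i, j)) / dx + (v(i, j + 1) - v(i, j)) / dy;
  return d;
}

// Subtract the discrete gradient of phi (units m^2/s) from (u, v); the
// stencil mirrors the Poisson matrix assembled in R exactly.

// [[Rcpp::export]]
List correct_velocity(NumericMatrix u, NumericMatrix v, NumericMatrix phi,
                      double dx, double dy, int bc) {
  const int nx = phi.nrow(), ny = phi.ncol();
  NumericMatrix un = clone(u), vn = clone(v);
  const bool px = (bc == 0 || bc == 3);
  const bool py = (bc == 0);
  for (int j = 0; j < ny; ++j) {
    for (int i = 1; i < nx; ++i)
      un(i, j) = u(i, j) - (phi(i, j) - phi(i - 1, j)) / dx;
    if (px) {
      un(0, j) = u(0, j) - (phi(0, j) - phi(nx - 1, j)) / dx;
      un(nx, j) = un(0, j);
    } else if (bc == 2) {
      un(0, j) = u(0, j) - 2.0 * phi(0, j) / dx;   // p = 0 at outflow face
    }
  }
  for (int i = 0; i < nx; ++i) {
    for (int j = 1; j < ny; ++j)
      vn(i, j) = v(i, j) - (phi(i, j) - phi(i, j - 1)) / dy;
    if (py) {
      vn(i, 0) = v(i, 0) - (phi(i, 0) - phi(i, ny - 1)) / dy;
      vn(i, ny) = vn(i, 0);
    }
  }
  return List::create(_["u"] = un, _["v"] = vn);
}

// ---- polygon solid fraction via smoothed signed distance ----
// loops: list of k x 2 matrices (closed loops, first vertex != last needed,
// closure implied). Evaluated at points (x0 + i*dx, y0 + j*dy). chi ramps
// linearly from 1 (d <= -eps) to 0 (d >= +eps).

// [[Rcpp::export]]
NumericMatrix polygon_chi(List loops, double x0, double dx, int nx,
                          double y0, double dy, int ny, double eps) {
  NumericMatrix chi(nx, ny);
  int nl = loops.size();
  std::vector<NumericMatrix> vs(nl);
  std::vector<double> bx0(nl), bx1(nl), by0(nl), by1(nl);
  for (int l = 0; l < nl; ++l) {
    vs[l] = as<NumericMatrix>(loops[l]);
    double a0 = R_PosInf, a1 = R_NegInf, b0 = R_PosInf, b1 = R_NegInf;
    for (int k = 0; k < vs[l].nrow(); ++k) {
      a0 = std::min(a0, vs[l](k, 0)); a1 = std::max(a1, vs[l](k, 0));
      b0 = std::min(b0, vs[l](k, 1)); b1 = std::max(b1, vs[l](k, 1));
    }
    bx0[l] = a0 - eps; bx1[l] = a1 + eps; by0[l] = b0 - eps; by1[l] = b1 + eps;
  }
  for (int j = 0; j < ny; ++j) {
    double py = y0 + j * dy;
    for (int i = 0; i < nx; ++i) {
      double px = x0 + i * dx;
      double dmin2 = R_PosInf;
      int crossings = 0;
      bool near = false;
      for (int l = 0; l < nl; ++l) {
        if (px < bx0[l] || px > bx1[l] || py < by0[l] || py > by1[l]) continue;
        near = true;
        const NumericMatrix &V = vs[l];
        int n = V.nrow();
        for (int k = 0; k < n; ++k) {
          int k2 = (k + 1) % n;
          double x1 = V(k, 0), y1 = V(k, 1), x2 = V(k2, 0), y2 = V(k2, 1);
          // crossing number (ray toward +x)
          if ((y1 > py) != (y2 > py)) {
            double xint = x1 + (py - y1) / (y2 - y1) * (x2 - x1);
            if (xint > px) ++crossings;
          }
          // squared distance to segment
          double ex = x2 - x1, ey = y2 - y1;
          double wx = px - x1, wy = py - y1;
          double L2 = ex * ex + ey * ey;
          double t = (L2 > 0.0) ? std::max(0.0, std::min(1.0, (wx * ex + wy * ey) / L2)) : 0.0;
          double qx = wx - t * ex, qy = wy - t * ey;
          double d2 = qx * qx + qy * qy;
          if (d2 < dmin2) dmin2 = d2;
        }
      }
      if (!near) { chi(i, j) = 0.0; continue; }
      double d = std::sqrt(dmin2);
      if (crossings % 2 == 1) d = -d;
      double c;
      if (eps <= 0.0) c = (d < 0.0) ? 1.0 : 0.0;
      else c = std::max(0.0, std::min(1.0, 0.5 - d / (2.0 * eps)));
      chi(i, j) = c;
    }
  }
  return chi;
}

// First self-intersection among non-adjacent segments of a closed loop;
// returns c(i, j) (1-based segment indices) or c(0, 0) if simple.

// [[Rcpp::export]]
IntegerVector polygon_self_intersection(NumericMatrix V) {
  int n = V.nrow();
  auto seg = [&](int k, double &x1, double &y1, double &x2, double &y2) {
    int k2 = (k + 1) % n;
    x1 = V(k, 0); y1 = V(k, 1); x2 = V(k2, 0); y2 = V(k2, 1);
  };
  auto orient = [](double ax, double ay, double bx, double by,
                   double cx, double cy) -> double {
    return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
  };
  for (int a = 0; a < n; ++a) {
    for (int b = a + 2; b < n; ++b) {
      if (a == 0 && b == n - 1) continue;  // adjacent through closure
      double ax1, ay1, ax2, ay2, bx1, by1, bx2, by2;
      seg(a, ax1, ay1, ax2, ay2);
      seg(b, bx1, by1, bx2, by2);
      double o1 = orient(ax1, ay1, ax2, ay2, bx1, by1);
      double o2 = orient(ax1, ay1, ax2, ay2, bx2, by2);
      double o3 = orient(bx1, by1, bx2, by2, ax1, ay1);
      double o4 = orient(bx1, by1, bx2, by2, ax2, ay2);
      if (((o1 > 0) != (o2 > 0)) && ((o3 > 0) != (o4 > 0)) &&
          o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
        return IntegerVector::create(a + 1, b + 1);
    }
  }
  return IntegerVector::create(0, 0);
}

// Vorticity dv/dx - du/dy at grid nodes (nx+1) x (ny+1), central interior,
// one-sided at the boundary.

// [[Rcpp::export]]
NumericMatrix vorticity_nodes(NumericMatrix u, NumericMatrix v,
                              double dx, double dy) {
  const int nx = v.nrow(), ny = u.ncol();
  NumericMatrix w(nx + 1, ny + 1);
  for (int j = 0; j <= ny; ++j) {
    int jv = std::min(j, ny);               // v column index at node row j
    for (int i = 0; i <= nx; ++i) {
      double dvdx;
      if (i == 0)       dvdx = (v(1, jv) - v(0, jv)) / dx;
      else if (i == nx) dvdx = (v(nx - 1, jv) - v(nx - 2, jv)) / dx;
      else              dvdx = (v(i, jv) - v(i - 1, jv)) / dx;
      double dudy;
      if (j == 0)       dudy = (u(i, 1) - u(i, 0)) / dy;
      else if (j == ny) dudy = (u(i, ny - 1) - u(i, ny - 2)) / dy;
      else              dudy = (u(i, j) - u(i, j - 1)) / dy;
      w(i, j) = dvdx - dudy;
    }
  }
  return w;
}
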