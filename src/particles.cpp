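#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Massless-tracer advection through stored staggered-grid snapshots with
// trilinear interpolation in space and linear, cycle-periodic interpolation
// in time.  Classical fourth-order Runge-Kutta in time.

struct FieldStack {
  const double* data; // nfaces x nsnap, column major
  int fd[3];
  int nface;
};

static inline double tri(const FieldStack& F, int snap, double gx, double gy,
                         double gz) {
  // gx,gy,gz are continuous indices in the face lattice of this component
  int i0 = (int)std::floor(gx), j0 = (int)std::floor(gy),
      k0 = (int)std::floor(gz);
  double fx = gx - i0, fy = gy - j0, fz = gz - k0;
  const double* base = F.data + (size_t)snap * F.nface;
  double acc = 0.0;
  for (int dk = 0; dk < 2; ++dk)
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        int i = i0 + di, j = j0 + dj, k = k0 + dk;
        double wgt = (di ? fx : 1 - fx) * (dj ? fy : 1 - fy) *
                     (dk ? fz : 1 - fz);
        if (wgt == 0.0 || i < 0 || i >= F.fd[0] || j < 0 || j >= F.fd[1] ||
            k < 0 || k >= F.fd[2])
          continue; // outside lattice contributes 0 (wall faces are 0 too)
        acc += wgt * base[i + F.fd[0] * (j + (size_t)F.fd[1] * k)];
      }
  return acc;
}

// [[Rcpp::export(name = ".advect_particles_cpp")]]
List advect_particles_cpp(NumericMatrix pos,      // n x 3, metres
                          NumericVector trel,     // release times, s
                          IntegerVector status,   // 0 active
                          NumericMatrix usnap, NumericMatrix vsnap,
                          NumericMatrix wsnap,
                          NumericVector stimes,   // snapshot times, s
                          double period,          // cycle period for wrapping
                          IntegerVector dims, NumericVector origin, double h,
                          IntegerVector plane_axis,  // per capture plane
                          NumericVector plane_coord,
                          IntegerVector plane_dir,   // +1: capture if x>=coord
                          IntegerVector plane_code,  // status code on capture
                          double t_end, double dtp) {
  int n = pos.nrow();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int ns = stimes.size();
  FieldStack F[3];
  F[0] = {REAL(usnap), {nx + 1, ny, nz}, (nx + 1) * ny * nz};
  F[1] = {REAL(vsnap), {nx, ny + 1, nz}, nx * (ny + 1) * nz};
  F[2] = {REAL(wsnap), {nx, ny, nz + 1}, nx * ny * (nz + 1)};
  double t0s = stimes[0];
  int nplane = plane_axis.size();
  NumericVector tcap(n, NA_REAL);

  auto velocity = [&](const double* x, double t, double* out) {
    int sa = 0, sb = 0;
    double wb = 0.0;
    if (ns > 1) {
      double rel = t - t0s;
      double tau = rel - period * std::floor(rel / period);
      // snapshots assumed uniformly ordered over one cycle
      sa = ns - 1;
      for (int s = 0; s < ns - 1; ++s)
        if (tau >= stimes[s] - t0s && tau < stimes[s + 1] - t0s) {
          sa = s;
          break;
        }
      if (sa < ns - 1) {
        sb = sa + 1;
        double span = stimes[sb] - stimes[sa];
        wb = (tau - (stimes[sa] - t0s)) / span;
      } else { // wrap last -> first
        sb = 0;
        double span = period - (stimes[ns - 1] - t0s);
        wb = span > 0 ? (tau - (stimes[ns - 1] - t0s)) / span : 0.0;
      }
    }
    for (int a = 0; a < 3; ++a) {
      double g[3];
      for (int b = 0; b < 3; ++b) {
        g[b] = (x[b] - origin[b]) / h;
        if (b != a) g[b] -= 0.5;
      }
      double va = tri(F[a], sa, g[0], g[1], g[2]);
      if (ns > 1 && wb > 0.0)
        va = (1 - wb) * va + wb * tri(F[a], sb, g[0], g[1], g[2]);
      out[a] = va;
    }
  };

  double box_lo[3] = {origin[0], origin[1], origin[2]};
  double box_hi[3] = {origin[0] + nx * h, origin[1] + ny * h,
                      origin[2] + nz * h};

  for (int ip = 0; ip < n; ++ip) {
    if (status[ip] != 0) continue;
    double x[3] = {pos(ip, 0), pos(ip, 1), pos(ip, 2)};
    double t = trel[ip];
    while (t < t_end && status[ip] == 0) {
      double dt = std::min(dtp, t_end - t);
      double k1[3], k2[3], k3[3], k4[3], xt[3];
      velocity(x, t, k1);
      for (int b = 0; b < 3; ++b) xt[b] = x[b] + 0.5 * dt * k1[b];
      velocity(xt, t + 0.5 * dt, k2);
      for (int b = 0; b < 3; ++b) xt[b] = x[b] + 0.5 * dt * k2[b];
      velocity(xt, t + 0.5 * dt, k3);
      for (int b = 0; b < 3; ++b) xt[b] = x[b] + dt * k3[b];
      velocity(xt, t + dt, k4);
      for (int b = 0; b < 3; ++b)
        x[b] += dt / 6.0 * (k1[b] + 2 * k2[b] + 2 * k3[b] + k4[b]);
      t += dt;
      // capture planes first (outlet planes coincide with the box faces)
      for (int q = 0; q < nplane; ++q) {
        int a = plane_axis[q];
        if ((plane_dir[q] > 0 && x[a] >= plane_coord[q]) ||
            (plane_dir[q] < 0 && x[a] <= plane_coord[q])) {
          status[ip] = plane_code[q];
          tcap[ip] = t;
          break;
        }
      }
      if (status[ip] == 0) {
        for (int b = 0; b < 3; ++b)
          if (x[b] < box_lo[b] || x[b] > box_hi[b]) {
            status[ip] = -1; // left the domain away from a capture plane
            tcap[ip] = t;
            break;
          }
      }
    }
    pos(ip, 0) = x[0];
    pos(ip, 1) = x[1];
    pos(ip, 2) = x[2];
  }
  return List::create(_["pos"] = pos, _["status"] = status,
                      _["t_capture"] = tcap);
}
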