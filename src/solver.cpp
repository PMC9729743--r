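#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Staggered-grid (MAC) kernels for the voxel projection solver.
//
// Cell-centred arrays have dims (nx, ny, nz); the face array of velocity
// component a has dims (nx,ny,nz) + e_a.  Face type codes:
//   0 = wall / outside lumen (value pinned to 0),
//   1 = active (both adjacent cells are lumen; updated by the solver),
//   2 = prescribed boundary face (inlet/outlet plug value, set per step).

static inline int lin3(int i, int j, int k, const int* d) {
  return i + d[0] * (j + d[1] * k);
}

// Value of face array U at index f (given as i,j,k) for a stencil centred on
// an active face with value uc.  g is the stencil direction, a the component
// axis.  Out-of-range or wall faces: in-line (g == a) the wall sits at the
// face location so the normal velocity is 0; tangential, the wall lies
// halfway to the neighbour face, so the ghost value -uc puts u = 0 there.
static inline double face_val(const double* U, const int* FT, const int* fd,
                              int i, int j, int k, int g, int a, double uc) {
  int idx[3] = {i, j, k};
  if (idx[g] < 0 || idx[g] >= fd[g]) return (g == a) ? 0.0 : -uc;
  int l = lin3(i, j, k, fd);
  int t = FT[l];
  if (t == 0) return (g == a) ? 0.0 : -uc;
  return U[l];
}

struct CompView {
  double *U, *Us;
  const int* FT;
  int fd[3];
};

// [[Rcpp::export(name = ".classify_faces_cpp")]]
List classify_faces_cpp(IntegerVector lumen, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int cd[3] = {nx, ny, nz};
  IntegerVector ftu(Dimension(nx + 1, ny, nz));
  IntegerVector ftv(Dimension(nx, ny + 1, nz));
  IntegerVector ftw(Dimension(nx, ny, nz + 1));
  int fdu[3] = {nx + 1, ny, nz}, fdv[3] = {nx, ny + 1, nz},
      fdw[3] = {nx, ny, nz + 1};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (!lumen[lin3(i, j, k, cd)]) continue;
        if (i + 1 < nx && lumen[lin3(i + 1, j, k, cd)])
          ftu[lin3(i + 1, j, k, fdu)] = 1;
        if (j + 1 < ny && lumen[lin3(i, j + 1, k, cd)])
          ftv[lin3(i, j + 1, k, fdv)] = 1;
        if (k + 1 < nz && lumen[lin3(i, j, k + 1, cd)])
          ftw[lin3(i, j, k + 1, fdw)] = 1;
      }
  return List::create(_["ftu"] = ftu, _["ftv"] = ftv, _["ftw"] = ftw);
}

// Is face (i,j,k) of the component with face types FT a regular value-carrying
// face (active or prescribed)?
static inline bool face_ok(const int* FT, const int* fd, int i, int j, int k) {
  if (i < 0 || i >= fd[0] || j < 0 || j >= fd[1] || k < 0 || k >= fd[2])
    return false;
  return FT[lin3(i, j, k, fd)] != 0;
}

// Precomputed per-face stencil tables for the advection-diffusion
// predictor.  For every active face and direction g they hold the grid
// index of the two in-stencil neighbours (-1: in-line wall ghost, value 0;
// -2: tangential wall ghost, value -uc), the second-upwind indices for the
// QUICK derivative (-1 when the 4-point stencil is cut by a wall), and the
// gather indices of the four transverse faces used for the advecting
// velocity.
struct StencilTables {
  std::vector<int> im[3], ip[3], i2m[3], i2p[3]; // nact*3 each
  std::vector<int> vget[3];                      // nact*3*4 gather indices
};

// [[Rcpp::export(name = ".build_stencil_cpp")]]
SEXP build_stencil_cpp(IntegerVector ftu, IntegerVector ftv,
                       IntegerVector ftw, List active, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const int* FTs[3] = {INTEGER(ftu), INTEGER(ftv), INTEGER(ftw)};
  int fds[3][3] = {{nx + 1, ny, nz}, {nx, ny + 1, nz}, {nx, ny, nz + 1}};
  int e[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  Rcpp::XPtr<StencilTables> tab(new StencilTables(), true);
  for (int a = 0; a < 3; ++a) {
    IntegerVector act = active[a];
    int n = act.size();
    const int* fd = fds[a];
    const int* FT = FTs[a];
    tab->im[a].assign((size_t)n * 3, -1);
    tab->ip[a].assign((size_t)n * 3, -1);
    tab->i2m[a].assign((size_t)n * 3, -1);
    tab->i2p[a].assign((size_t)n * 3, -1);
    tab->vget[a].assign((size_t)n * 3 * 4, 0);
    for (int t = 0; t < n; ++t) {
      int l = act[t];
      int i = l % fd[0];
      int r = l / fd[0];
      int j = r % fd[1];
      int k = r / fd[1];
      for (int g = 0; g < 3; ++g) {
        size_t o = (size_t)t * 3 + g;
        int im[3] = {i - e[g][0], j - e[g][1], k - e[g][2]};
        int ip[3] = {i + e[g][0], j + e[g][1], k + e[g][2]};
        bool okm = face_ok(FT, fd, im[0], im[1], im[2]);
        bool okp = face_ok(FT, fd, ip[0], ip[1], ip[2]);
        tab->im[a][o] = okm ? lin3(im[0], im[1], im[2], fd)
                            : (g == a ? -1 : -2);
        tab->ip[a][o] = okp ? lin3(ip[0], ip[1], ip[2], fd)
                            : (g == a ? -1 : -2);
        int i2m[3] = {i - 2 * e[g][0], j - 2 * e[g][1], k - 2 * e[g][2]};
        int i2p[3] = {i + 2 * e[g][0], j + 2 * e[g][1], k + 2 * e[g][2]};
        if (okm && okp && face_ok(FT, fd, i2m[0], i2m[1], i2m[2]))
          tab->i2m[a][o] = lin3(i2m[0], i2m[1], i2m[2], fd);
        if (okm && okp && face_ok(FT, fd, i2p[0], i2p[1], i2p[2]))
          tab->i2p[a][o] = lin3(i2p[0], i2p[1], i2p[2], fd);
        if (g != a) {
          const int* wfd = fds[g];
          int cl[3] = {i - e[a][0], j - e[a][1], k - e[a][2]};
          int ch[3] = {i, j, k};
          int pts[4][3] = {
            {cl[0], cl[1], cl[2]},
            {cl[0] + e[g][0], cl[1] + e[g][1], cl[2] + e[g][2]},
            {ch[0], ch[1], ch[2]},
            {ch[0] + e[g][0], ch[1] + e[g][1], ch[2] + e[g][2]}};
          for (int q = 0; q < 4; ++q)
            tab->vget[a][o * 4 + q] =
              lin3(pts[q][0], pts[q][1], pts[q][2], wfd);
        }
      }
    }
  }
  return tab;
}

// Advection-diffusion right-hand side F = -(u.grad)u + nu Lap u for
// component a over its active faces, using the precomputed tables.
// scheme 0 = first-order upwind; scheme 1 = QUICK (third-order
// upwind-biased), blending upwind and central differencing wherever a wall
// cuts the 4-point stencil (pure upwinding there acts like a large
// artificial viscosity, pure central rings at the stair corners).
static void rhs_comp(int a, const CompView V[3], double* F,
                     const IntegerVector& act, double h, double nu,
                     int scheme, const StencilTables* tab) {
  const double* U = V[a].U;
  int n = act.size();
  const int* actp = INTEGER(act);
  const int* imt = tab->im[a].data();
  const int* ipt = tab->ip[a].data();
  const int* i2mt = tab->i2m[a].data();
  const int* i2pt = tab->i2p[a].data();
  const int* vgt = tab->vget[a].data();
  const double inv_h = 1.0 / h, inv_8h = 1.0 / (8.0 * h);
  const double nu_h2 = nu / (h * h);
  for (int t = 0; t < n; ++t) {
    int l = actp[t];
    double uc = U[l];
    double adv = 0.0, lap = 0.0;
    size_t o0 = (size_t)t * 3;
    for (int g = 0; g < 3; ++g) {
      size_t o = o0 + g;
      double vg;
      if (g == a) {
        vg = uc;
      } else {
        const double* W = V[g].U;
        const int* q4 = vgt + o * 4;
        vg = 0.25 * (W[q4[0]] + W[q4[1]] + W[q4[2]] + W[q4[3]]);
      }
      int lm = imt[o], lp = ipt[o];
      double vm = lm >= 0 ? U[lm] : (lm == -1 ? 0.0 : -uc);
      double vp = lp >= 0 ? U[lp] : (lp == -1 ? 0.0 : -uc);
      double dug;
      if (scheme == 1) {
        int l2;
        if (vg > 0.0 && (l2 = i2mt[o]) >= 0) {
          dug = (3.0 * vp + 3.0 * uc - 7.0 * vm + U[l2]) * inv_8h;
        } else if (vg <= 0.0 && (l2 = i2pt[o]) >= 0) {
          dug = -(3.0 * vm + 3.0 * uc - 7.0 * vp + U[l2]) * inv_8h;
        } else {
          double up1 = (vg > 0.0) ? (uc - vm) : (vp - uc);
          dug = (0.5 * up1 + 0.25 * (vp - vm)) * inv_h;
        }
      } else {
        dug = ((vg > 0.0) ? (uc - vm) : (vp - uc)) * inv_h;
      }
      adv += vg * dug;
      lap += vm - 2.0 * uc + vp;
    }
    F[l] = -adv + nu_h2 * lap;
  }
}

// [[Rcpp::export(name = ".advance_cpp")]]
List advance_cpp(NumericVector u, NumericVector v, NumericVector w,
                 NumericVector p,
                 NumericVector us, NumericVector vs, NumericVector ws,
                 NumericVector fu, NumericVector fv, NumericVector fw,
                 int scheme, int use_ab2,
                 IntegerVector ftu, IntegerVector ftv, IntegerVector ftw,
                 List active,            // 0-based active face indices per comp
                 IntegerVector dims,
                 IntegerVector fcell,    // 0-based grid indices of lumen cells
                 IntegerMatrix fnbr,     // 6 x nf neighbour positions in fcell, -1 none
                 List portface_comp,     // per port: IntegerVector comp (0..2)
                 List portface_idx,      // per port: 0-based face linear index
                 List portface_sign,     // per port: outward sign (+1/-1)
                 List portface_int,      // per port: in-line interior face index
                 List portcell_idx,      // per port: 0-based positions in fcell
                 IntegerVector portmode,  // 0 prescribed plug; 1 convective outflow
                 NumericVector portvalue, // per port: plug face value or target flux
                 NumericVector out_res,   // per port: outlet resistance or NA
                 NumericVector out_pref,  // per port: outlet reference pressure
                 NumericVector plast,     // previous pressure on fluid cells
                 int use_extrap,
                 NumericVector avg_u, NumericVector avg_v,
                 NumericVector avg_w, NumericVector avg_p,
                 double avg_weight,       // 0 = no averaging this step
                 SEXP stencil,            // XPtr from .build_stencil_cpp
                 double h, double dt, double rho, double mu,
                 double cgtol, int cgmax) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int cd[3] = {nx, ny, nz};
  CompView V[3];
  V[0] = {REAL(u), REAL(us), INTEGER(ftu), {nx + 1, ny, nz}};
  V[1] = {REAL(v), REAL(vs), INTEGER(ftv), {nx, ny + 1, nz}};
  V[2] = {REAL(w), REAL(ws), INTEGER(ftw), {nx, ny, nz + 1}};
  double nu = mu / rho;

  Rcpp::XPtr<StencilTables> tab(stencil);
  if (!tab) stop("stale solver context: stencil tables missing");

  // explicit advection-diffusion: Adams-Bashforth 2 on the stored RHS
  // (first step falls back to forward Euler)
  double* Fprev[3] = {REAL(fu), REAL(fv), REAL(fw)};
  static std::vector<double> Fn_buf;
  for (int a = 0; a < 3; ++a) {
    IntegerVector act = active[a];
    int nfc = V[a].fd[0] * V[a].fd[1] * V[a].fd[2];
    Fn_buf.assign(nfc, 0.0);
    rhs_comp(a, V, Fn_buf.data(), act, h, nu, scheme, tab.get());
    const int* actp = INTEGER(act);
    double* Fp = Fprev[a];
    for (int t = 0; t < act.size(); ++t) {
      int l = actp[t];
      double rhs = use_ab2 ? (1.5 * Fn_buf[l] - 0.5 * Fp[l]) : Fn_buf[l];
      V[a].Us[l] = V[a].U[l] + dt * rhs;
      Fp[l] = Fn_buf[l];
    }
  }

  // prescribed boundary faces: inlets carry the new-time plug value; outlets
  // copy the interior profile (zero-gradient) rescaled to the target flux
  int nport = portvalue.size();
  double h2 = h * h;
  for (int pt = 0; pt < nport; ++pt) {
    if (!R_finite(portvalue[pt])) continue;
    IntegerVector pc = portface_comp[pt], pi = portface_idx[pt];
    if (portmode[pt] == 0) {
      for (int q = 0; q < pi.size(); ++q) V[pc[q]].Us[pi[q]] = portvalue[pt];
    } else {
      IntegerVector ps = portface_sign[pt], pn = portface_int[pt];
      double Qt = portvalue[pt];
      double raw = 0.0;
      for (int q = 0; q < pi.size(); ++q)
        raw += ps[q] * V[pc[q]].Us[pn[q]] * h2;
      double area = pi.size() * h2;
      if (raw > 1e-3 * (std::fabs(Qt) + 1e-300)) {
        double sc = Qt / raw;
        for (int q = 0; q < pi.size(); ++q)
          V[pc[q]].Us[pi[q]] = V[pc[q]].Us[pn[q]] * sc;
      } else { // start-up or reversed interior flow: plug fallback
        for (int q = 0; q < pi.size(); ++q)
          V[pc[q]].Us[pi[q]] = ps[q] * Qt / area;
      }
    }
  }

  int nf = fcell.size();
  const int* fc = INTEGER(fcell);
  const int* nb6 = INTEGER(fnbr); // 6 x nf, column per fluid cell
  // divergence -> rhs
  std::vector<double> b(nf), x(nf), rres(nf), z(nf), pd(nf), Ap(nf);
  std::vector<int> ndeg(nf);
  double bsum = 0.0;
  for (int c = 0; c < nf; ++c) {
    int l = fc[c];
    int i = l % nx, r = l / nx, j = r % ny, k = r / ny;
    double div =
      (V[0].Us[lin3(i + 1, j, k, V[0].fd)] - V[0].Us[lin3(i, j, k, V[0].fd)] +
       V[1].Us[lin3(i, j + 1, k, V[1].fd)] - V[1].Us[lin3(i, j, k, V[1].fd)] +
       V[2].Us[lin3(i, j, k + 1, V[2].fd)] - V[2].Us[lin3(i, j, k, V[2].fd)]) / h;
    // A = -Laplacian (SPD on the zero-mean subspace), so the projection
    // requirement Lap p = (rho/dt) div gives b = -(rho/dt) div
    b[c] = -(rho / dt) * div;
    bsum += b[c];
    int d = 0;
    const int* col = nb6 + 6 * (size_t)c;
    for (int q = 0; q < 6; ++q) if (col[q] >= 0) ++d;
    ndeg[c] = d;
  }
  double bmean = bsum / nf;
  double bnorm2 = 0.0;
  for (int c = 0; c < nf; ++c) { b[c] -= bmean; bnorm2 += b[c] * b[c]; }

  // warm start: linear-in-time extrapolation of the previous pressures
  // (mean removed: nullspace)
  double pmean = 0.0;
  double* P = REAL(p);
  double* PL = REAL(plast);
  for (int c = 0; c < nf; ++c) {
    double guess = use_extrap ? 2.0 * P[fc[c]] - PL[c] : P[fc[c]];
    PL[c] = P[fc[c]];
    x[c] = guess;
    pmean += guess;
  }
  pmean /= nf;
  for (int c = 0; c < nf; ++c) x[c] -= pmean;

  const double inv_h2 = 1.0 / h2;
  auto applyA = [&](const std::vector<double>& q, std::vector<double>& out) {
    const double* qp = q.data();
    for (int c = 0; c < nf; ++c) {
      const int* col = nb6 + 6 * (size_t)c;
      double s = ndeg[c] * qp[c];
      for (int d2 = 0; d2 < 6; ++d2) {
        int nb = col[d2];
        if (nb >= 0) s -= qp[nb];
      }
      out[c] = s * inv_h2;
    }
  };

  // Incomplete-Cholesky (DIC) preconditioner: off-diagonals of the 7-point
  // Laplacian are kept, only the diagonal is modified, so the factor shares
  // A's sparsity and applying M^{-1} costs a forward plus a backward sweep.
  std::vector<double> dic(nf), inv_dic(nf);
  for (int c = 0; c < nf; ++c) {
    const int* col = nb6 + 6 * (size_t)c;
    double d = std::max(ndeg[c], 1) * inv_h2;
    for (int d2 = 0; d2 < 6; ++d2) {
      int nb = col[d2];
      if (nb >= 0 && nb < c) d -= inv_h2 * inv_h2 * inv_dic[nb];
    }
    dic[c] = std::max(d, 0.05 * inv_h2); // guard against breakdown
    inv_dic[c] = 1.0 / dic[c];
  }
  auto applyM = [&](const std::vector<double>& r2, std::vector<double>& out) {
    const double* rp = r2.data();
    for (int c = 0; c < nf; ++c) {
      const int* col = nb6 + 6 * (size_t)c;
      double s = rp[c];
      for (int d2 = 0; d2 < 6; ++d2) {
        int nb = col[d2];
        if (nb >= 0 && nb < c) s += out[nb] * inv_h2;
      }
      out[c] = s * inv_dic[c];
    }
    for (int c = 0; c < nf; ++c) out[c] *= dic[c];
    for (int c = nf - 1; c >= 0; --c) {
      const int* col = nb6 + 6 * (size_t)c;
      double s = out[c];
      for (int d2 = 0; d2 < 6; ++d2) {
        int nb = col[d2];
        if (nb >= 0 && nb > c) s += out[nb] * inv_h2;
      }
      out[c] = s * inv_dic[c];
    }
  };

  int iters = 0;
  double relres = 0.0;
  if (bnorm2 > 0.0) {
    applyA(x, Ap);
    for (int c = 0; c < nf; ++c) rres[c] = b[c] - Ap[c];
    applyM(rres, z);
    double rz = 0.0;
    for (int c = 0; c < nf; ++c) {
      pd[c] = z[c];
      rz += rres[c] * z[c];
    }
    double tol2 = cgtol * cgtol * bnorm2;
    for (iters = 0; iters < cgmax; ++iters) {
      double rn2 = 0.0;
      for (int c = 0; c < nf; ++c) rn2 += rres[c] * rres[c];
      relres = std::sqrt(rn2 / bnorm2);
      if (rn2 <= tol2) break;
      applyA(pd, Ap);
      double pAp = 0.0;
      for (int c = 0; c < nf; ++c) pAp += pd[c] * Ap[c];
      if (pAp <= 0.0) break; // semidefinite guard
      double alpha = rz / pAp;
      for (int c = 0; c < nf; ++c) {
        x[c] += alpha * pd[c];
        rres[c] -= alpha * Ap[c];
      }
      applyM(rres, z);
      double rznew = 0.0;
      for (int c = 0; c < nf; ++c) rznew += rres[c] * z[c];
      double beta = rznew / rz;
      rz = rznew;
      for (int c = 0; c < nf; ++c) pd[c] = z[c] + beta * pd[c];
    }
  }

  // scatter pressure, remove mean
  double xm = 0.0;
  for (int c = 0; c < nf; ++c) xm += x[c];
  xm /= nf;
  for (int c = 0; c < nf; ++c) P[fc[c]] = x[c] - xm;

  // corrector: copy predictor then project active faces
  for (int a = 0; a < 3; ++a) {
    int n = V[a].fd[0] * V[a].fd[1] * V[a].fd[2];
    std::copy(V[a].Us, V[a].Us + n, V[a].U);
  }
  int e[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  double fac = dt / (rho * h);
  for (int a = 0; a < 3; ++a) {
    IntegerVector act = active[a];
    for (int t = 0; t < act.size(); ++t) {
      int l = act[t];
      int i = l % V[a].fd[0];
      int r = l / V[a].fd[0];
      int j = r % V[a].fd[1];
      int k = r / V[a].fd[1];
      int chi = lin3(i, j, k, cd);
      int clo = lin3(i - e[a][0], j - e[a][1], k - e[a][2], cd);
      V[a].U[l] -= fac * (P[chi] - P[clo]);
    }
  }

  // diagnostics + per-port flux, pressure, energy flux
  double maxdiv = 0.0, ke = 0.0, maxvel = 0.0;
  for (int c = 0; c < nf; ++c) {
    int l = fc[c];
    int i = l % nx, r = l / nx, j = r % ny, k = r / ny;
    double ul = V[0].U[lin3(i, j, k, V[0].fd)],
           ur = V[0].U[lin3(i + 1, j, k, V[0].fd)],
           vl = V[1].U[lin3(i, j, k, V[1].fd)],
           vr = V[1].U[lin3(i, j + 1, k, V[1].fd)],
           wl = V[2].U[lin3(i, j, k, V[2].fd)],
           wr = V[2].U[lin3(i, j, k + 1, V[2].fd)];
    double div = (ur - ul + vr - vl + wr - wl) / h;
    if (std::fabs(div) > maxdiv) maxdiv = std::fabs(div);
    double uc = 0.5 * (ul + ur), vc = 0.5 * (vl + vr), wc = 0.5 * (wl + wr);
    double sp2 = uc * uc + vc * vc + wc * wc;
    ke += sp2;
    double sp = std::sqrt(sp2);
    if (sp > maxvel) maxvel = sp;
  }
  ke *= 0.5 * rho * h * h * h;

  NumericVector portQ(nport), portP(nport), portE(nport);
  for (int pt = 0; pt < nport; ++pt) {
    IntegerVector pcv = portface_comp[pt], piv = portface_idx[pt],
                  psv = portface_sign[pt], pcell = portcell_idx[pt];
    double Q = 0.0, E = 0.0;
    for (int q = 0; q < piv.size(); ++q) {
      double uf = V[pcv[q]].U[piv[q]];
      double qn = psv[q] * uf * h2; // outward volumetric flux of this face
      Q += qn;
      // pressure of the adjacent lumen cell (face q caps port cell q; the
      // R-side setup builds the two lists in matching order)
      double pc = P[fc[pcell[q]]];
      E += (pc + 0.5 * rho * uf * uf) * qn;
    }
    double Pm = 0.0;
    for (int q = 0; q < pcell.size(); ++q) Pm += P[fc[pcell[q]]];
    portQ[pt] = Q;
    portP[pt] = pcell.size() ? Pm / pcell.size() : NA_REAL;
    portE[pt] = E;
  }

  // pin the pressure level so the outlet resistance relation holds in the
  // mean: P_port = R * Q_port + P_ref across the outlets
  double off = 0.0;
  int noutl = 0;
  for (int pt = 0; pt < nport; ++pt) {
    if (!R_finite(out_res[pt])) continue;
    off += out_res[pt] * portQ[pt] + out_pref[pt] - portP[pt];
    ++noutl;
  }
  if (noutl > 0) {
    off /= noutl;
    for (int c = 0; c < nf; ++c) P[fc[c]] += off;
    for (int pt = 0; pt < nport; ++pt) {
      portP[pt] += off;
      portE[pt] += off * portQ[pt];
    }
  }

  if (avg_weight > 0.0) {
    double* av[4] = {REAL(avg_u), REAL(avg_v), REAL(avg_w), REAL(avg_p)};
    const double* src[4] = {V[0].U, V[1].U, V[2].U, P};
    int len[4] = {V[0].fd[0] * V[0].fd[1] * V[0].fd[2],
                  V[1].fd[0] * V[1].fd[1] * V[1].fd[2],
                  V[2].fd[0] * V[2].fd[1] * V[2].fd[2], nx * ny * nz};
    for (int q = 0; q < 4; ++q)
      for (int l = 0; l < len[q]; ++l) av[q][l] += avg_weight * src[q][l];
  }

  return List::create(_["portQ"] = portQ, _["portP"] = portP,
                      _["portE"] = portE, _["iters"] = iters,
                      _["relres"] = relres, _["maxdiv"] = maxdiv,
                      _["ke"] = ke, _["maxvel"] = maxvel);
}

// [[Rcpp::export(name = ".flood_fill_cpp")]]
IntegerVector flood_fill_cpp(IntegerVector lumen, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int cd[3] = {nx, ny, nz};
  int n = nx * ny * nz;
  IntegerVector comp(n, 0);
  std::vector<int> stack;
  int label = 0;
  for (int s = 0; s < n; ++s) {
    if (!lumen[s] || comp[s]) continue;
    ++label;
    stack.push_back(s);
    comp[s] = label;
    while (!stack.empty()) {
      int l = stack.back();
      stack.pop_back();
      int i = l % nx, r = l / nx, j = r % ny, k = r / ny;
      int di[6] = {-1, 1, 0, 0, 0, 0}, dj[6] = {0, 0, -1, 1, 0, 0},
          dk[6] = {0, 0, 0, 0, -1, 1};
      for (int q = 0; q < 6; ++q) {
        int i2 = i + di[q], j2 = j + dj[q], k2 = k + dk[q];
        if (i2 < 0 || i2 >= nx || j2 < 0 || j2 >= ny || k2 < 0 || k2 >= nz)
          continue;
        int l2 = lin3(i2, j2, k2, cd);
        if (lumen[l2] && !comp[l2]) {
          comp[l2] = label;
          stack.push_back(l2);
        }
      }
    }
  }
  comp.attr("n_components") = label;
  return comp;
}
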