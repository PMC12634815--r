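// Point location and Lagrangian tracer advection on labeled tetrahedral
// meshes. Location uses a neighbor-walk with a uniform-grid fallback;
// velocities are barycentric (P1) interpolants of the stored phase fields,
// extended periodically in time.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

struct Locator {
  int n, ne;
  std::vector<double> coords;   // 3*n, xyz per node
  std::vector<int> tet;         // 4*ne, 0-based
  std::vector<double> x0;       // 3*ne (vertex 0)
  std::vector<double> tinv;     // 9*ne row-major inverse edge matrix
  std::vector<int> neigh;       // 4*ne neighbor across face opposite local k
  std::vector<int> facelab;     // 4*ne, 0 interior, 1 moving, 2 rigid, 3 outlet
  // uniform grid
  double org[3], csz[3];
  int ncell[3];
  std::vector<int> cell_start, cell_items;

  int cell_of(const double* p) const {
    int c[3];
    for (int d = 0; d < 3; ++d) {
      int i = (int)std::floor((p[d] - org[d]) / csz[d]);
      if (i < 0) i = 0;
      if (i >= ncell[d]) i = ncell[d] - 1;
      c[d] = i;
    }
    return (c[2] * ncell[1] + c[1]) * ncell[0] + c[0];
  }

  void bary(int e, const double* p, double* lam) const {
    const double* xe = &x0[3 * e];
    const double* ti = &tinv[9 * e];
    double d0 = p[0] - xe[0], d1 = p[1] - xe[1], d2 = p[2] - xe[2];
    lam[1] = ti[0] * d0 + ti[1] * d1 + ti[2] * d2;
    lam[2] = ti[3] * d0 + ti[4] * d1 + ti[5] * d2;
    lam[3] = ti[6] * d0 + ti[7] * d1 + ti[8] * d2;
    lam[0] = 1.0 - lam[1] - lam[2] - lam[3];
  }

  // locate point; returns tet id or -1; lam filled when found;
  // exit_lab receives the boundary label crossed when the walk leaves
  int locate(const double* p, int hint, double* lam, int* exit_lab) const {
    *exit_lab = 0;
    const double tol = -1e-10;
    if (hint >= 0 && hint < ne) {
      int cur = hint;
      for (int it = 0; it < 128; ++it) {
        bary(cur, p, lam);
        int kmin = 0;
        for (int k = 1; k < 4; ++k) if (lam[k] < lam[kmin]) kmin = k;
        if (lam[kmin] >= tol) return cur;
        int nx = neigh[4 * cur + kmin];
        if (nx < 0) { *exit_lab = facelab[4 * cur + kmin]; break; }
        cur = nx;
      }
    }
    // grid fallback: best candidate in the containing cell
    int cell = cell_of(p);
    int best = -1;
    double bestmin = -1e30;
    double lamtmp[4];
    for (int ii = cell_start[cell]; ii < cell_start[cell + 1]; ++ii) {
      int e = cell_items[ii];
      bary(e, p, lamtmp);
      double mn = lamtmp[0];
      for (int k = 1; k < 4; ++k) if (lamtmp[k] < mn) mn = lamtmp[k];
      if (mn > bestmin) { bestmin = mn; best = e; }
    }
    if (best >= 0 && bestmin >= tol) { bary(best, p, lam); return best; }
    return -1;
  }
};

static inline uint64_t face_key(int a, int b, int c, int n) {
  int s1 = a < b ? (a < c ? a : c) : (b < c ? b : c);
  int s3 = a > b ? (a > c ? a : c) : (b > c ? b : c);
  int s2 = a + b + c - s1 - s3;
  return ((uint64_t)s1 * (n + 1) + s2) * (uint64_t)(n + 1) + s3;
}

// [[Rcpp::export]]
SEXP cm_locator_build(NumericMatrix nodes, IntegerMatrix tets,
                      IntegerMatrix tris, IntegerVector tri_label) {
  Locator* L = new Locator();
  L->n = nodes.nrow();
  L->ne = tets.nrow();
  L->coords.resize(3 * L->n);
  for (int i = 0; i < L->n; ++i)
    for (int d = 0; d < 3; ++d) L->coords[3 * i + d] = nodes(i, d);
  L->tet.resize(4 * L->ne);
  for (int e = 0; e < L->ne; ++e)
    for (int k = 0; k < 4; ++k) L->tet[4 * e + k] = tets(e, k) - 1;
  L->x0.resize(3 * L->ne);
  L->tinv.resize(9 * L->ne);
  for (int e = 0; e < L->ne; ++e) {
    const int* v = &L->tet[4 * e];
    double E[9];
    for (int d = 0; d < 3; ++d) {
      L->x0[3 * e + d] = L->coords[3 * v[0] + d];
      for (int k = 0; k < 3; ++k)
        E[3 * d + k] = L->coords[3 * v[k + 1] + d] - L->coords[3 * v[0] + d];
    }
    double det =
      E[0] * (E[4] * E[8] - E[5] * E[7]) -
      E[1] * (E[3] * E[8] - E[5] * E[6]) +
      E[2] * (E[3] * E[7] - E[4] * E[6]);
    double* ti = &L->tinv[9 * e];
    ti[0] = (E[4] * E[8] - E[5] * E[7]) / det;
    ti[1] = (E[2] * E[7] - E[1] * E[8]) / det;
    ti[2] = (E[1] * E[5] - E[2] * E[4]) / det;
    ti[3] = (E[5] * E[6] - E[3] * E[8]) / det;
    ti[4] = (E[0] * E[8] - E[2] * E[6]) / det;
    ti[5] = (E[2] * E[3] - E[0] * E[5]) / det;
    ti[6] = (E[3] * E[7] - E[4] * E[6]) / det;
    ti[7] = (E[1] * E[6] - E[0] * E[7]) / det;
    ti[8] = (E[0] * E[4] - E[1] * E[3]) / det;
  }
  // adjacency via face hashing
  L->neigh.assign(4 * L->ne, -1);
  L->facelab.assign(4 * L->ne, 0);
  {
    std::unordered_map<uint64_t, int> seen;  // key -> 4*e + k of first side
    seen.reserve(4 * L->ne);
    const int faceloc[4][3] = {{1, 2, 3}, {0, 3, 2}, {0, 1, 3}, {0, 2, 1}};
    for (int e = 0; e < L->ne; ++e) {
      for (int k = 0; k < 4; ++k) {
        const int* v = &L->tet[4 * e];
        uint64_t key = face_key(v[faceloc[k][0]], v[faceloc[k][1]],
                                v[faceloc[k][2]], L->n);
        auto it = seen.find(key);
        if (it == seen.end()) {
          seen[key] = 4 * e + k;
        } else {
          int other = it->second;
          L->neigh[4 * e + k] = other / 4;
          L->neigh[other] = e;
          seen.erase(it);
        }
      }
    }
    // label remaining (boundary) faces from the triangle list
    std::unordered_map<uint64_t, int> labmap;
    labmap.reserve(tris.nrow());
    for (int t = 0; t < tris.nrow(); ++t)
      labmap[face_key(tris(t, 0) - 1, tris(t, 1) - 1, tris(t, 2) - 1, L->n)] =
        tri_label[t];
    const int faceloc2[4][3] = {{1, 2, 3}, {0, 3, 2}, {0, 1, 3}, {0, 2, 1}};
    for (int e = 0; e < L->ne; ++e)
      for (int k = 0; k < 4; ++k)
        if (L->neigh[4 * e + k] < 0) {
          const int* v = &L->tet[4 * e];
          uint64_t key = face_key(v[faceloc2[k][0]], v[faceloc2[k][1]],
                                  v[faceloc2[k][2]], L->n);
          auto it = labmap.find(key);
          L->facelab[4 * e + k] = (it == labmap.end()) ? 2 : it->second;
        }
  }
  // uniform grid sized to the mean element
  double lo[3] = {1e300, 1e300, 1e300}, hi[3] = {-1e300, -1e300, -1e300};
  for (int i = 0; i < L->n; ++i)
    for (int d = 0; d < 3; ++d) {
      double v = L->coords[3 * i + d];
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  double vol_tot = (hi[0] - lo[0]) * (hi[1] - lo[1]) * (hi[2] - lo[2]);
  double volmean = std::cbrt(std::max(vol_tot / std::max(L->ne, 1), 1e-12)) * 2.0;
  long ncelltot = 1;
  for (int d = 0; d < 3; ++d) {
    double ext = hi[d] - lo[d];
    int nc = std::max(1, (int)std::floor(ext / volmean));
    if (nc > 256) nc = 256;
    L->ncell[d] = nc;
    L->org[d] = lo[d] - 1e-9 * (1 + ext);
    L->csz[d] = (ext + 2e-9 * (1 + ext)) / nc;
    ncelltot *= nc;
  }
  std::vector<int> counts(ncelltot + 1, 0);
  std::vector<std::array<int, 6>> ranges(L->ne);
  for (int e = 0; e < L->ne; ++e) {
    double elo[3] = {1e300, 1e300, 1e300}, ehi[3] = {-1e300, -1e300, -1e300};
    for (int k = 0; k < 4; ++k) {
      const double* p = &L->coords[3 * L->tet[4 * e + k]];
      for (int d = 0; d < 3; ++d) {
        if (p[d] < elo[d]) elo[d] = p[d];
        if (p[d] > ehi[d]) ehi[d] = p[d];
      }
    }
    for (int d = 0; d < 3; ++d) {
      int i0 = (int)std::floor((elo[d] - L->org[d]) / L->csz[d]);
      int i1 = (int)std::floor((ehi[d] - L->org[d]) / L->csz[d]);
      if (i0 < 0) i0 = 0;
      if (i1 >= L->ncell[d]) i1 = L->ncell[d] - 1;
      ranges[e][2 * d] = i0;
      ranges[e][2 * d + 1] = i1;
    }
    for (int iz = ranges[e][4]; iz <= ranges[e][5]; ++iz)
      for (int iy = ranges[e][2]; iy <= ranges[e][3]; ++iy)
        for (int ix = ranges[e][0]; ix <= ranges[e][1]; ++ix)
          counts[(iz * L->ncell[1] + iy) * L->ncell[0] + ix + 1]++;
  }
  for (long c = 0; c < ncelltot; ++c) counts[c + 1] += counts[c];
  L->cell_start = counts;
  L->cell_items.resize(counts[ncelltot]);
  std::vector<int> fill(ncelltot, 0);
  for (int e = 0; e < L->ne; ++e) {
    for (int iz = ranges[e][4]; iz <= ranges[e][5]; ++iz)
      for (int iy = ranges[e][2]; iy <= ranges[e][3]; ++iy)
        for (int ix = ranges[e][0]; ix <= ranges[e][1]; ++ix) {
          long c = (iz * L->ncell[1] + iy) * L->ncell[0] + ix;
          L->cell_items[L->cell_start[c] + fill[c]++] = e;
        }
  }
  XPtr<Locator> xp(L, true);
  return xp;
}

// [[Rcpp::export]]
bool cm_locator_valid(SEXP xp) {
  return R_ExternalPtrAddr(xp) != NULL;
}

// [[Rcpp::export]]
List cm_locate(SEXP xp_, NumericMatrix pts, IntegerVector hints) {
  XPtr<Locator> xp(xp_);
  int m = pts.nrow();
  IntegerVector tet(m), exitlab(m);
  NumericMatrix bar(m, 4);
  double p[3], lam[4];
  int hint = -1;
  for (int i = 0; i < m; ++i) {
    p[0] = pts(i, 0); p[1] = pts(i, 1); p[2] = pts(i, 2);
    int h = (hints.size() == m) ? hints[i] - 1 : hint;
    int lab = 0;
    int e = xp->locate(p, h, lam, &lab);
    tet[i] = e + 1;
    exitlab[i] = lab;
    if (e >= 0) {
      for (int k = 0; k < 4; ++k) bar(i, k) = lam[k];
      hint = e;
    }
  }
  return List::create(_["tet"] = tet, _["bary"] = bar,
                      _["exit_label"] = exitlab);
}

struct FieldTime {
  const double* u;  // n x 3 x P
  int n, P;
  const double* ptimes;  // length P
  double period;
  int interp;  // 0 linear, 1 catmull-rom
  std::vector<double> buf;  // n x 3 blended

  void blend(double t) {
    // periodic reduction without fmod (avoids a glibc-2.38 symbol version)
    double s = t - period * std::floor(t / period);
    if (s >= period) s = 0.0;
    int p = P - 1;
    for (int k = 0; k < P - 1; ++k)
      if (s >= ptimes[k] && s < ptimes[k + 1]) { p = k; break; }
    double t1 = ptimes[p];
    double t2 = (p + 1 < P) ? ptimes[p + 1] : period;
    double w = (t2 > t1) ? (s - t1) / (t2 - t1) : 0.0;
    int p2 = (p + 1) % P;
    long stride = (long)n * 3;
    if (interp == 0) {
      const double* a = u + stride * p;
      const double* b = u + stride * p2;
      for (long i = 0; i < stride; ++i) buf[i] = (1 - w) * a[i] + w * b[i];
    } else {
      int pm = (p - 1 + P) % P, pp = (p + 2) % P;
      const double* um = u + stride * pm;
      const double* u0 = u + stride * p;
      const double* u1 = u + stride * p2;
      const double* up = u + stride * pp;
      double w2 = w * w, w3 = w2 * w;
      double c0 = -0.5 * w3 + w2 - 0.5 * w;
      double c1 = 1.5 * w3 - 2.5 * w2 + 1.0;
      double c2 = -1.5 * w3 + 2.0 * w2 + 0.5 * w;
      double c3 = 0.5 * w3 - 0.5 * w2;
      for (long i = 0; i < stride; ++i)
        buf[i] = c0 * um[i] + c1 * u0[i] + c2 * u1[i] + c3 * up[i];
    }
  }

  // P1 interpolation from the blended buffer
  void eval(const Locator* L, int e, const double* lam, double* v) const {
    v[0] = v[1] = v[2] = 0;
    for (int k = 0; k < 4; ++k) {
      int nd = L->tet[4 * e + k];
      v[0] += lam[k] * buf[nd];
      v[1] += lam[k] * buf[n + nd];
      v[2] += lam[k] * buf[2 * (long)n + nd];
    }
  }
};

// [[Rcpp::export]]
List cm_advect(SEXP xp_, NumericMatrix pos, IntegerVector status,
               IntegerVector hint, NumericVector ufield,
               NumericVector ptimes, double period,
               int n_cycles, int substeps, int interp, int scheme) {
  XPtr<Locator> xp(xp_);
  Locator* L = xp.get();
  IntegerVector dim = ufield.attr("dim");
  int n = dim[0], P = dim[2];
  if (n != L->n) stop("field/mesh node count mismatch");
  int m = pos.nrow();
  NumericMatrix out = clone(pos);
  IntegerVector st = clone(status);
  IntegerVector ht = clone(hint);
  FieldTime F;
  F.u = ufield.begin(); F.n = n; F.P = P;
  F.ptimes = ptimes.begin(); F.period = period; F.interp = interp;
  F.buf.resize((long)n * 3);
  FieldTime Fb = F, Fc = F;
  Fb.buf.resize((long)n * 3);
  Fc.buf.resize((long)n * 3);
  double lam[4], v[3];

  for (int cyc = 0; cyc < n_cycles; ++cyc) {
    for (int ph = 0; ph < P; ++ph) {
      double t0p = ptimes[ph];
      double t1p = (ph + 1 < P) ? ptimes[ph + 1] : period;
      double dtp = (t1p - t0p) / substeps;
      for (int s = 0; s < substeps; ++s) {
        double t0 = t0p + s * dtp;
        F.blend(t0);
        Fb.blend(t0 + 0.5 * dtp);
        Fc.blend(t0 + dtp);
        for (int i = 0; i < m; ++i) {
          if (st[i] != 0) continue;
          double x[3] = {out(i, 0), out(i, 1), out(i, 2)};
          int lab = 0;
          int e = L->locate(x, ht[i] - 1, lam, &lab);
          if (e < 0) { st[i] = (lab == 3) ? 1 : 0; continue; }
          ht[i] = e + 1;
          double k1[3], k2[3], k3[3], k4[3], xn[3];
          F.eval(L, e, lam, k1);
          if (scheme == 2) {  // midpoint RK2
            double xm[3] = {x[0] + 0.5 * dtp * k1[0], x[1] + 0.5 * dtp * k1[1],
                            x[2] + 0.5 * dtp * k1[2]};
            int e2 = L->locate(xm, e, lam, &lab);
            if (e2 >= 0) Fb.eval(L, e2, lam, k2);
            else { k2[0] = k2[1] = k2[2] = 0; }
            for (int d = 0; d < 3; ++d) xn[d] = x[d] + dtp * k2[d];
          } else {  // RK4
            double xt[3];
            for (int d = 0; d < 3; ++d) xt[d] = x[d] + 0.5 * dtp * k1[d];
            int e2 = L->locate(xt, e, lam, &lab);
            if (e2 >= 0) Fb.eval(L, e2, lam, k2);
            else { k2[0] = k2[1] = k2[2] = 0; }
            for (int d = 0; d < 3; ++d) xt[d] = x[d] + 0.5 * dtp * k2[d];
            int e3 = L->locate(xt, e2 >= 0 ? e2 : e, lam, &lab);
            if (e3 >= 0) Fb.eval(L, e3, lam, k3);
            else { k3[0] = k3[1] = k3[2] = 0; }
            for (int d = 0; d < 3; ++d) xt[d] = x[d] + dtp * k3[d];
            int e4 = L->locate(xt, e3 >= 0 ? e3 : e, lam, &lab);
            if (e4 >= 0) Fc.eval(L, e4, lam, k4);
            else { k4[0] = k4[1] = k4[2] = 0; }
            for (int d = 0; d < 3; ++d)
              xn[d] = x[d] + dtp / 6.0 * (k1[d] + 2 * k2[d] + 2 * k3[d] + k4[d]);
          }
          int lab2 = 0;
          int en = L->locate(xn, e, lam, &lab2);
          if (en >= 0) {
            out(i, 0) = xn[0]; out(i, 1) = xn[1]; out(i, 2) = xn[2];
            ht[i] = en + 1;
          } else if (lab2 == 3) {
            st[i] = 1;  // exited through an outlet; frozen at last inside point
          }
          // wall graze: cancel the move, stay active at the old position
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["pos"] = out, _["status"] = st, _["hint"] = ht);
}
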