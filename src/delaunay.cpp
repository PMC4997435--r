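// Incremental 3D Delaunay tetrahedralization (Bowyer-Watson with an implicit
// vertex at infinity), point location by walking, and barycentric weight
// evaluation. Coordinates are the scaled space-time coordinates (x, y, c*t);
// predicates run on internally normalized copies so tolerances are relative
// to the cloud's extent.
#include <Rcpp.h>
#include <vector>
#include <array>
#include <map>
#include <cmath>
#include <random>
using namespace Rcpp;

namespace {

const int INFV = -1;

struct Tet {
  int v[4];
  int n[4];        // neighbour opposite v[i]; -1 = none (only during setup)
  bool alive;
  unsigned stamp;  // conflict-search mark
};

inline double det3(double a1, double a2, double a3,
                   double b1, double b2, double b3,
                   double c1, double c2, double c3) {
  return a1 * (b2 * c3 - b3 * c2)
       - a2 * (b1 * c3 - b3 * c1)
       + a3 * (b1 * c2 - b2 * c1);
}

inline double det3abs(double a1, double a2, double a3,
                      double b1, double b2, double b3,
                      double c1, double c2, double c3) {
  a1 = std::fabs(a1); a2 = std::fabs(a2); a3 = std::fabs(a3);
  b1 = std::fabs(b1); b2 = std::fabs(b2); b3 = std::fabs(b3);
  c1 = std::fabs(c1); c2 = std::fabs(c2); c3 = std::fabs(c3);
  return a1 * (b2 * c3 + b3 * c2)
       + a2 * (b1 * c3 + b3 * c1)
       + a3 * (b1 * c2 + b2 * c1);
}

// > 0 when d lies on the positive side of the plane through a, b, c
// (tetrahedra are kept with orient3d(v0, v1, v2, v3) > 0; the signed volume
// is orient3d / 6). `err`, when requested, receives a magnitude-scaled
// tie threshold: |det| <= err means "numerically coplanar".
inline double orient3d(const double* a, const double* b,
                       const double* c, const double* d,
                       double* err = 0) {
  double bx = b[0] - a[0], by = b[1] - a[1], bz = b[2] - a[2];
  double cx = c[0] - a[0], cy = c[1] - a[1], cz = c[2] - a[2];
  double dx = d[0] - a[0], dy = d[1] - a[1], dz = d[2] - a[2];
  if (err)
    *err = 1e-13 * det3abs(bx, by, bz, cx, cy, cz, dx, dy, dz);
  return det3(bx, by, bz, cx, cy, cz, dx, dy, dz);
}

// > 0 when e is strictly inside the circumsphere of the positively oriented
// tetrahedron abcd; `err` as for orient3d
inline double insphere(const double* a, const double* b, const double* c,
                       const double* d, const double* e, double* err = 0) {
  double ax = a[0] - e[0], ay = a[1] - e[1], az = a[2] - e[2];
  double bx = b[0] - e[0], by = b[1] - e[1], bz = b[2] - e[2];
  double cx = c[0] - e[0], cy = c[1] - e[1], cz = c[2] - e[2];
  double dx = d[0] - e[0], dy = d[1] - e[1], dz = d[2] - e[2];
  double al = ax * ax + ay * ay + az * az;
  double bl = bx * bx + by * by + bz * bz;
  double cl = cx * cx + cy * cy + cz * cz;
  double dl = dx * dx + dy * dy + dz * dz;
  double det = -al * det3(bx, by, bz, cx, cy, cz, dx, dy, dz)
             +  bl * det3(ax, ay, az, cx, cy, cz, dx, dy, dz)
             -  cl * det3(ax, ay, az, bx, by, bz, dx, dy, dz)
             +  dl * det3(ax, ay, az, bx, by, bz, cx, cy, cz);
  if (err)
    *err = 1e-12 * (al * det3abs(bx, by, bz, cx, cy, cz, dx, dy, dz)
                  + bl * det3abs(ax, ay, az, cx, cy, cz, dx, dy, dz)
                  + cl * det3abs(ax, ay, az, bx, by, bz, dx, dy, dz)
                  + dl * det3abs(ax, ay, az, bx, by, bz, cx, cy, cz));
  return -det;
}

// 2D in-circumcircle test for a point (nearly) coplanar with triangle abc,
// orientation-corrected so the answer does not depend on the winding of abc
bool in_circumdisk(const double* a, const double* b, const double* c,
                   const double* p) {
  double u[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
  double v[3] = { c[0] - a[0], c[1] - a[1], c[2] - a[2] };
  double lu = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  if (lu == 0.0) return false;
  double e1[3] = { u[0] / lu, u[1] / lu, u[2] / lu };
  double pv = v[0] * e1[0] + v[1] * e1[1] + v[2] * e1[2];
  double w[3] = { v[0] - pv * e1[0], v[1] - pv * e1[1], v[2] - pv * e1[2] };
  double lw = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  if (lw == 0.0) return false;
  double e2[3] = { w[0] / lw, w[1] / lw, w[2] / lw };
  double q[3] = { p[0] - a[0], p[1] - a[1], p[2] - a[2] };
  double Bx = lu, By = 0.0, Cx = pv, Cy = lw;
  double Px = q[0] * e1[0] + q[1] * e1[1] + q[2] * e1[2];
  double Py = q[0] * e2[0] + q[1] * e2[1] + q[2] * e2[2];
  // incircle determinant, rows relative to P
  double axp = -Px, ayp = -Py;
  double bxp = Bx - Px, byp = By - Py;
  double cxp = Cx - Px, cyp = Cy - Py;
  double det = (axp * axp + ayp * ayp) * (bxp * cyp - byp * cxp)
             - (bxp * bxp + byp * byp) * (axp * cyp - ayp * cxp)
             + (cxp * cxp + cyp * cyp) * (axp * byp - ayp * bxp);
  double orient = Bx * Cy;  // orient2d(A, B, C) with A at origin, By = 0
  return (orient > 0 ? det : -det) > 0;
}

struct Triangulation {
  std::vector<std::array<double, 3>> P;
  std::vector<Tet> T;
  std::vector<int> freelist;
  unsigned stamp;
  int last;
  double ref0[3];  // interior reference point (centroid of the seed tet)

  Triangulation() : stamp(0), last(0) {}

  const double* pt(int i) const { return P[i].data(); }
  static int infslot(const Tet& t) {
    for (int i = 0; i < 4; ++i) if (t.v[i] == INFV) return i;
    return -1;
  }

  // orientation det of tet t with the point in slot k replaced by p;
  // all other slots must hold finite vertices
  double orient_rep(const Tet& t, int k, const double* p,
                    double* err = 0) const {
    const double* q[4];
    for (int i = 0; i < 4; ++i) q[i] = (i == k) ? p : pt(t.v[i]);
    return orient3d(q[0], q[1], q[2], q[3], err);
  }

  bool in_conflict(int ti, const double* p) const {
    const Tet& t = T[ti];
    int k = infslot(t);
    double err;
    if (k < 0) {
      double s = insphere(pt(t.v[0]), pt(t.v[1]), pt(t.v[2]), pt(t.v[3]), p,
                          &err);
      return s > err;  // numerically cospherical counts as not in conflict
    }
    double o = orient_rep(t, k, p, &err);
    if (o > err) return true;
    if (o < -err) return false;
    const double* f[3];
    int j = 0;
    for (int i = 0; i < 4; ++i) if (i != k) f[j++] = pt(t.v[i]);
    return in_circumdisk(f[0], f[1], f[2], p);
  }

  int alloc() {
    int id;
    if (!freelist.empty()) { id = freelist.back(); freelist.pop_back(); }
    else { T.push_back(Tet()); id = (int)T.size() - 1; }
    Tet& t = T[id];
    t.alive = true;
    t.stamp = 0;
    for (int i = 0; i < 4; ++i) { t.v[i] = INFV; t.n[i] = -1; }
    return id;
  }

  void kill(int ti) { T[ti].alive = false; freelist.push_back(ti); }

  int slot_of_neighbor(int ti, int nb) const {
    for (int i = 0; i < 4; ++i) if (T[ti].n[i] == nb) return i;
    return -1;
  }

  void swap_slots(int ti, int a, int b) {
    std::swap(T[ti].v[a], T[ti].v[b]);
    std::swap(T[ti].n[a], T[ti].n[b]);
  }

  // enforce the orientation invariants on a freshly wired tet:
  // finite tets positively oriented; infinite tets such that replacing the
  // infinite slot by a point strictly outside the hull face gives a positive
  // determinant (the interior reference must give a negative one)
  void fix_orientation(int ti) {
    Tet& t = T[ti];
    int k = infslot(t);
    if (k < 0) {
      double o = orient3d(pt(t.v[0]), pt(t.v[1]), pt(t.v[2]), pt(t.v[3]));
      if (o < 0) swap_slots(ti, 0, 1);
      return;
    }
    double err;
    double o = orient_rep(t, k, ref0, &err);
    if (std::fabs(o) <= err) {
      // reference nearly coplanar with the hull face: use the opposite
      // vertex of the finite neighbour behind the face instead
      int nb = t.n[k];
      if (nb >= 0) {
        int s = slot_of_neighbor(nb, ti);
        if (s >= 0 && T[nb].v[s] != INFV)
          o = orient_rep(t, k, pt(T[nb].v[s]));
      }
    }
    if (o > 0) {
      int a = (k == 0) ? 1 : 0;
      int b = (k == 0 || k == 1) ? 2 : 1;
      swap_slots(ti, a, b);
    }
  }

  // walk toward p; returns a finite tet containing p (within tolerance) or
  // an infinite tet whose hull face p lies on/beyond
  int walk(const double* p) {
    int cur = last;
    if (cur < 0 || cur >= (int)T.size() || !T[cur].alive) {
      cur = -1;
      for (int i = 0; i < (int)T.size(); ++i)
        if (T[i].alive) { cur = i; break; }
      if (cur < 0) return -1;
    }
    int maxsteps = 1000 + (int)T.size();
    for (int steps = 0; steps < maxsteps; ++steps) {
      const Tet& t = T[cur];
      int k = infslot(t);
      double err;
      if (k >= 0) {
        double o = orient_rep(t, k, p, &err);
        if (o > -err) return cur;
        cur = t.n[k];
        continue;
      }
      int best = -1;
      double bestv = 0.0;
      for (int i = 0; i < 4; ++i) {
        double o = orient_rep(t, i, p, &err);
        if (o < -err && o < bestv) { bestv = o; best = i; }
      }
      if (best < 0) return cur;
      cur = t.n[best];
      if (cur < 0) return -1;
    }
    // tolerance-induced cycle: fall back to an exhaustive conflict scan
    for (int i = 0; i < (int)T.size(); ++i)
      if (T[i].alive && in_conflict(i, p)) return i;
    return -1;
  }

  void insert(int pid) {
    const double* p = pt(pid);
    int t0 = walk(p);
    if (t0 < 0) stop("tetrahedralization: point location failed");
    if (infslot(T[t0]) >= 0 && !in_conflict(t0, p)) {
      int back = T[t0].n[infslot(T[t0])];
      if (back >= 0) t0 = back;
    }
    bool forced = !in_conflict(t0, p);
    ++stamp;
    std::vector<int> cavity;
    T[t0].stamp = stamp;
    cavity.push_back(t0);
    if (!forced) {
      for (size_t h = 0; h < cavity.size(); ++h) {
        int ct = cavity[h];
        for (int i = 0; i < 4; ++i) {
          int nb = T[ct].n[i];
          if (nb < 0 || T[nb].stamp == stamp) continue;
          if (in_conflict(nb, p)) {
            T[nb].stamp = stamp;
            cavity.push_back(nb);
          }
        }
      }
    }
    // build the star of p over the cavity boundary
    std::vector<int> newtets;
    std::map<std::pair<int, int>, std::pair<int, int>> rim;
    for (size_t h = 0; h < cavity.size(); ++h) {
      int ct = cavity[h];
      for (int i = 0; i < 4; ++i) {
        int nb = T[ct].n[i];
        if (nb >= 0 && T[nb].stamp == stamp) continue;
        int f[3], j = 0;
        for (int s = 0; s < 4; ++s) if (s != i) f[j++] = T[ct].v[s];
        int nt = alloc();
        T[nt].v[0] = f[0]; T[nt].v[1] = f[1]; T[nt].v[2] = f[2];
        T[nt].v[3] = pid;
        T[nt].n[3] = nb;
        if (nb >= 0) {
          int s = slot_of_neighbor(nb, ct);
          if (s >= 0) T[nb].n[s] = nt;
        }
        for (int s = 0; s < 3; ++s) {
          int e1 = f[(s + 1) % 3], e2 = f[(s + 2) % 3];
          std::pair<int, int> key(std::min(e1, e2), std::max(e1, e2));
          auto it = rim.find(key);
          if (it == rim.end()) {
            rim[key] = std::make_pair(nt, s);
          } else {
            T[nt].n[s] = it->second.first;
            T[it->second.first].n[it->second.second] = nt;
            rim.erase(it);
          }
        }
        newtets.push_back(nt);
      }
    }
    for (size_t h = 0; h < cavity.size(); ++h) kill(cavity[h]);
    for (size_t h = 0; h < newtets.size(); ++h) fix_orientation(newtets[h]);
    if (!newtets.empty()) last = newtets.back();
  }
};

}  // namespace

// [[Rcpp::export]]
List delaunay3d_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("tetrahedralization needs at least 4 unique points");
  Triangulation tri;
  // normalize uniformly so predicates see O(1) coordinates
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      double v = pts(i, d);
      if (!R_finite(v)) stop("non-finite coordinate in point cloud");
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  double scale = 0.0;
  for (int d = 0; d < 3; ++d) scale = std::max(scale, hi[d] - lo[d]);
  if (scale <= 0.0)
    stop("degenerate point cloud: all points coincide");
  tri.P.resize(n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d)
      tri.P[i][d] = (pts(i, d) - lo[d]) / scale;

  // seed simplex: four affinely independent points, judged on the clean
  // (unperturbed) coordinates so a truly degenerate cloud is refused
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  const double tol = 1e-10;
  for (int i = 1; i < n && i1 < 0; ++i) {
    double dx = tri.P[i][0] - tri.P[i0][0];
    double dy = tri.P[i][1] - tri.P[i0][1];
    double dz = tri.P[i][2] - tri.P[i0][2];
    if (dx * dx + dy * dy + dz * dz > tol * tol) i1 = i;
  }
  if (i1 < 0) stop("degenerate point cloud: all points coincide");
  for (int i = 1; i < n && i2 < 0; ++i) {
    if (i == i1) continue;
    double u[3] = { tri.P[i1][0] - tri.P[i0][0], tri.P[i1][1] - tri.P[i0][1],
                    tri.P[i1][2] - tri.P[i0][2] };
    double v[3] = { tri.P[i][0] - tri.P[i0][0], tri.P[i][1] - tri.P[i0][1],
                    tri.P[i][2] - tri.P[i0][2] };
    double cx = u[1] * v[2] - u[2] * v[1];
    double cy = u[2] * v[0] - u[0] * v[2];
    double cz = u[0] * v[1] - u[1] * v[0];
    if (cx * cx + cy * cy + cz * cz > tol * tol) i2 = i;
  }
  if (i2 < 0) stop("degenerate point cloud: all points are collinear");
  for (int i = 1; i < n && i3 < 0; ++i) {
    if (i == i1 || i == i2) continue;
    double o = orient3d(tri.pt(i0), tri.pt(i1), tri.pt(i2), tri.pt(i));
    if (std::fabs(o) > tol) i3 = i;
  }
  if (i3 < 0) stop("degenerate point cloud: all points are coplanar");

  // deterministic symbolic-style joggle: a tiny reproducible perturbation
  // (1e-10 of the cloud extent) breaks the exact cosphericity ties a
  // site-by-day measurement grid is full of; the perturbed coordinates are
  // returned and become the mesh geometry, so all downstream weights are
  // consistent
  {
    std::mt19937_64 rng(20090101ull);
    const double amp = 1e-10;
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        double u = (double)(rng() >> 11) * (1.0 / 9007199254740992.0);
        tri.P[i][d] += amp * (2.0 * u - 1.0);
      }
  }

  int t0 = tri.alloc();
  tri.T[t0].v[0] = i0; tri.T[t0].v[1] = i1;
  tri.T[t0].v[2] = i2; tri.T[t0].v[3] = i3;
  if (orient3d(tri.pt(i0), tri.pt(i1), tri.pt(i2), tri.pt(i3)) < 0)
    std::swap(tri.T[t0].v[0], tri.T[t0].v[1]);
  for (int d = 0; d < 3; ++d)
    tri.ref0[d] = (tri.P[tri.T[t0].v[0]][d] + tri.P[tri.T[t0].v[1]][d] +
                   tri.P[tri.T[t0].v[2]][d] + tri.P[tri.T[t0].v[3]][d]) / 4.0;
  // four infinite tets glued to the faces of the seed
  int itet[4];
  for (int i = 0; i < 4; ++i) {
    int nt = tri.alloc();
    int j = 0;
    for (int s = 0; s < 4; ++s)
      if (s != i) tri.T[nt].v[j++] = tri.T[t0].v[s];
    tri.T[nt].v[3] = INFV;
    tri.T[nt].n[3] = t0;
    tri.T[t0].n[i] = nt;
    itet[i] = nt;
  }
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      if (i == j) continue;
      int vj = tri.T[t0].v[j];
      for (int s = 0; s < 3; ++s)
        if (tri.T[itet[i]].v[s] == vj) tri.T[itet[i]].n[s] = itet[j];
    }
  for (int i = 0; i < 4; ++i) tri.fix_orientation(itet[i]);
  tri.last = t0;

  // remaining points in a deterministic shuffled order
  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i)
    if (i != i0 && i != i1 && i != i2 && i != i3) order.push_back(i);
  std::mt19937 rng(88172645u);
  for (int i = (int)order.size() - 1; i > 0; --i) {
    int j = (int)(rng() % (unsigned)(i + 1));
    std::swap(order[i], order[j]);
  }
  for (size_t h = 0; h < order.size(); ++h) tri.insert(order[h]);

  // compact the finite tets
  int m = 0;
  for (size_t i = 0; i < tri.T.size(); ++i)
    if (tri.T[i].alive && Triangulation::infslot(tri.T[i]) < 0) ++m;
  IntegerMatrix tets(m, 4), nbrs(m, 4);
  std::vector<int> remap(tri.T.size(), 0);
  int k = 0;
  for (size_t i = 0; i < tri.T.size(); ++i)
    if (tri.T[i].alive && Triangulation::infslot(tri.T[i]) < 0)
      remap[i] = ++k;
  k = 0;
  for (size_t i = 0; i < tri.T.size(); ++i) {
    if (!(tri.T[i].alive && Triangulation::infslot(tri.T[i]) < 0)) continue;
    for (int s = 0; s < 4; ++s) {
      tets(k, s) = tri.T[i].v[s] + 1;
      int nb = tri.T[i].n[s];
      nbrs(k, s) = (nb >= 0 && tri.T[nb].alive) ? remap[nb] : 0;
    }
    ++k;
  }
  NumericMatrix jogged(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d)
      jogged(i, d) = lo[d] + scale * tri.P[i][d];
  return List::create(_["tets"] = tets, _["neighbors"] = nbrs,
                      _["points"] = jogged);
}

namespace {

// barycentric weights of p in tet row ti (0-based) of the compacted mesh;
// returns the weight vector and the (6x) signed volume through `sum`
inline void tet_weights(const NumericMatrix& pts, const IntegerMatrix& tets,
                        int ti, const double* p, double* w, double& sum) {
  const double* q[4];
  double buf[4][3];
  for (int s = 0; s < 4; ++s) {
    int vi = tets(ti, s) - 1;
    buf[s][0] = pts(vi, 0); buf[s][1] = pts(vi, 1); buf[s][2] = pts(vi, 2);
    q[s] = buf[s];
  }
  double o[4];
  for (int s = 0; s < 4; ++s) {
    const double* r[4];
    for (int j = 0; j < 4; ++j) r[j] = (j == s) ? p : q[j];
    o[s] = orient3d(r[0], r[1], r[2], r[3]);
  }
  sum = o[0] + o[1] + o[2] + o[3];
  if (sum != 0.0)
    for (int s = 0; s < 4; ++s) w[s] = o[s] / sum;
  else
    for (int s = 0; s < 4; ++s) w[s] = o[s];
}

}  // namespace

// Walks the mesh toward each query; queries should be pre-sorted for spatial
// coherence (each walk starts from the previous hit). Returns, per query, the
// 1-based containing tet (0 = outside the convex hull) and its four
// barycentric weights.
// [[Rcpp::export]]
List locate_weights_cpp(NumericMatrix pts, IntegerMatrix tets,
                        IntegerMatrix nbrs, LogicalVector degen,
                        NumericMatrix queries, double tol) {
  int m = tets.nrow(), nq = queries.nrow();
  IntegerVector hit(nq);
  NumericMatrix W(nq, 4);
  if (m == 0) stop("empty mesh");
  int cur = 0;
  for (int qi = 0; qi < nq; ++qi) {
    double p[3] = { queries(qi, 0), queries(qi, 1), queries(qi, 2) };
    int found = -1;
    bool outside = false;
    double w[4], sum;
    int start = cur;
    int maxsteps = 1000 + m;
    for (int steps = 0; steps < maxsteps; ++steps) {
      tet_weights(pts, tets, cur, p, w, sum);
      int worst = -1;
      double worstv = -tol;
      for (int s = 0; s < 4; ++s)
        if (w[s] < worstv) { worstv = w[s]; worst = s; }
      if (worst < 0 && sum > 0.0) { found = cur; break; }
      if (worst < 0) { found = cur; break; }  // degenerate but containing-ish
      int nb = nbrs(cur, worst);
      if (nb == 0) { outside = true; break; }
      cur = nb - 1;
    }
    if (found < 0 && !outside) {
      // cycle fallback: exhaustive best-containing scan
      double bestmin = R_NegInf;
      int best = -1;
      for (int t = 0; t < m; ++t) {
        tet_weights(pts, tets, t, p, w, sum);
        if (sum <= 0.0) continue;
        double mn = std::min(std::min(w[0], w[1]), std::min(w[2], w[3]));
        if (mn > bestmin) { bestmin = mn; best = t; }
      }
      if (best >= 0 && bestmin >= -tol) found = best;
      else outside = true;
      if (found >= 0) cur = found;
    }
    if (outside || found < 0) {
      hit[qi] = 0;
      W(qi, 0) = W(qi, 1) = W(qi, 2) = W(qi, 3) = NA_REAL;
      cur = start;
      continue;
    }
    // resolve queries landing in a degenerate sliver through a neighbour
    if (degen[found]) {
      std::vector<int> cand;
      for (int s = 0; s < 4; ++s) {
        int nb = nbrs(found, s);
        if (nb == 0) continue;
        cand.push_back(nb - 1);
        for (int s2 = 0; s2 < 4; ++s2) {
          int nb2 = nbrs(nb - 1, s2);
          if (nb2 != 0 && nb2 - 1 != found) cand.push_back(nb2 - 1);
        }
      }
      double bestmin = R_NegInf;
      int best = -1;
      for (size_t h = 0; h < cand.size(); ++h) {
        if (degen[cand[h]]) continue;
        tet_weights(pts, tets, cand[h], p, w, sum);
        if (sum <= 0.0) continue;
        double mn = std::min(std::min(w[0], w[1]), std::min(w[2], w[3]));
        if (mn > bestmin) { bestmin = mn; best = cand[h]; }
      }
      if (best >= 0 && bestmin >= -tol) found = best;
    }
    tet_weights(pts, tets, found, p, w, sum);
    if (sum <= 0.0) {  // irrecoverably flat: report as unresolvable/outside
      hit[qi] = 0;
      W(qi, 0) = W(qi, 1) = W(qi, 2) = W(qi, 3) = NA_REAL;
      continue;
    }
    hit[qi] = found + 1;
    for (int s = 0; s < 4; ++s) W(qi, s) = w[s];
    cur = found;
  }
  return List::create(_["tet"] = hit, _["weights"] = W);
}

// Exact k-nearest neighbours by brute-force scan with a deterministic
// (distance, index) tie-break. Returns 1-based neighbour indices sorted by
// increasing distance and the distances themselves.
// [[Rcpp::export]]
List knn_cpp(NumericMatrix train, NumericMatrix queries, int k) {
  int n = train.nrow(), nq = queries.nrow();
  if (k < 1) stop("k must be >= 1");
  if (k > n) stop("k exceeds the number of training points");
  IntegerMatrix idx(nq, k);
  NumericMatrix dist(nq, k);
  std::vector<std::pair<double, int>> d(n);
  for (int qi = 0; qi < nq; ++qi) {
    double qx = queries(qi, 0), qy = queries(qi, 1), qz = queries(qi, 2);
    for (int i = 0; i < n; ++i) {
      double dx = train(i, 0) - qx;
      double dy = train(i, 1) - qy;
      double dz = train(i, 2) - qz;
      d[i] = std::make_pair(dx * dx + dy * dy + dz * dz, i);
    }
    std::partial_sort(d.begin(), d.begin() + k, d.end());
    for (int j = 0; j < k; ++j) {
      idx(qi, j) = d[j].second + 1;
      dist(qi, j) = std::sqrt(d[j].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}
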