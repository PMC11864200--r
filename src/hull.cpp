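#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <map>
using namespace Rcpp;

// Incremental 3D convex hull. Points are rows of an n x 3 matrix (micrometers).
// Returns outward-oriented triangular faces plus hull volume and the volume
// centroid (centroid of the solid, not the mean of input points).

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3 &a, const Vec3 &b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3 &a, const Vec3 &b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;     // vertex indices
  Vec3 n;          // outward normal (not normalized)
  bool alive;
};

inline Vec3 face_normal(const std::vector<Vec3> &p, int a, int b, int c) {
  return cross(sub(p[b], p[a]), sub(p[c], p[a]));
}

// signed distance of point q from the plane of face f (positive = outside)
inline double plane_dist(const std::vector<Vec3> &p, const Face &f, const Vec3 &q) {
  return dot(f.n, sub(q, p[f.a])) / norm(f.n);
}

}  // namespace

// [[Rcpp::export(name = ".convex_hull_3d")]]
List convex_hull_3d(NumericMatrix pts) {
  const int n = pts.nrow();
  std::vector<Vec3> p(n);
  for (int i = 0; i < n; ++i) p[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};

  List degen = List::create(_["degenerate"] = true, _["volume"] = NA_REAL,
                            _["centroid"] = NumericVector::create(NA_REAL, NA_REAL, NA_REAL),
                            _["faces"] = IntegerMatrix(0, 3));
  if (n < 4) return degen;

  // overall scale for tolerances
  double scale = 0.0;
  for (int d = 0; d < 3; ++d) {
    double lo = pts(0, d), hi = pts(0, d);
    for (int i = 1; i < n; ++i) {
      lo = std::min(lo, pts(i, d));
      hi = std::max(hi, pts(i, d));
    }
    scale = std::max(scale, hi - lo);
  }
  if (scale <= 0) return degen;
  const double eps = 1e-10 * scale;

  // initial simplex: farthest pair among axis extremes, then farthest from the
  // line, then farthest from the plane
  int i0 = 0, i1 = 0;
  {
    std::vector<int> ext;
    for (int d = 0; d < 3; ++d) {
      int lo = 0, hi = 0;
      for (int i = 1; i < n; ++i) {
        if (pts(i, d) < pts(lo, d)) lo = i;
        if (pts(i, d) > pts(hi, d)) hi = i;
      }
      ext.push_back(lo);
      ext.push_back(hi);
    }
    double best = -1;
    for (size_t a = 0; a < ext.size(); ++a)
      for (size_t b = a + 1; b < ext.size(); ++b) {
        double d = norm(sub(p[ext[a]], p[ext[b]]));
        if (d > best) { best = d; i0 = ext[a]; i1 = ext[b]; }
      }
    if (best < eps) return degen;
  }
  int i2 = -1;
  {
    Vec3 u = sub(p[i1], p[i0]);
    double best = -1;
    for (int i = 0; i < n; ++i) {
      double d = norm(cross(u, sub(p[i], p[i0]))) / norm(u);
      if (d > best) { best = d; i2 = i; }
    }
    if (best < eps) return degen;  // collinear
  }
  int i3 = -1;
  {
    Vec3 nrm = face_normal(p, i0, i1, i2);
    double best = -1;
    for (int i = 0; i < n; ++i) {
      double d = std::fabs(dot(nrm, sub(p[i], p[i0]))) / norm(nrm);
      if (d > best) { best = d; i3 = i; }
    }
    if (best < eps) return degen;  // coplanar
  }

  Vec3 inner = {(p[i0].x + p[i1].x + p[i2].x + p[i3].x) / 4.0,
                (p[i0].y + p[i1].y + p[i2].y + p[i3].y) / 4.0,
                (p[i0].z + p[i1].z + p[i2].z + p[i3].z) / 4.0};

  std::vector<Face> faces;
  auto add_face = [&](int a, int b, int c) {
    Face f;
    f.a = a; f.b = b; f.c = c;
    f.n = face_normal(p, a, b, c);
    if (dot(f.n, sub(inner, p[a])) > 0) {  // flip to point away from interior
      std::swap(f.b, f.c);
      f.n = face_normal(p, f.a, f.b, f.c);
    }
    f.alive = true;
    faces.push_back(f);
  };
  add_face(i0, i1, i2);
  add_face(i0, i1, i3);
  add_face(i0, i2, i3);
  add_face(i1, i2, i3);

  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    // faces visible from point i
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f)
      if (faces[f].alive && plane_dist(p, faces[f], p[i]) > eps) vis.push_back((int)f);
    if (vis.empty()) continue;
    // horizon = directed edges of visible faces whose reverse is not visible
    std::map<std::pair<int, int>, int> edges;
    for (int f : vis) {
      const Face &fc = faces[f];
      int e[3][2] = {{fc.a, fc.b}, {fc.b, fc.c}, {fc.c, fc.a}};
      for (auto &ed : e) edges[{ed[0], ed[1]}] = 1;
    }
    std::vector<std::pair<int, int>> horizon;
    for (auto &kv : edges)
      if (edges.find({kv.first.second, kv.first.first}) == edges.end())
        horizon.push_back(kv.first);
    for (int f : vis) faces[f].alive = false;
    for (auto &ed : horizon) add_face(ed.first, ed.second, i);
  }

  // volume + volume centroid from tetrahedra (inner, a, b, c)
  double vol = 0.0;
  double cx = 0, cy = 0, cz = 0;
  int nf = 0;
  for (const Face &f : faces) {
    if (!f.alive) continue;
    ++nf;
    Vec3 a = sub(p[f.a], inner), b = sub(p[f.b], inner), c = sub(p[f.c], inner);
    double v6 = dot(a, cross(b, c));  // 6 x signed volume, positive if outward
    vol += v6 / 6.0;
    double tcx = inner.x + (a.x + b.x + c.x) / 4.0;
    double tcy = inner.y + (a.y + b.y + c.y) / 4.0;
    double tcz = inner.z + (a.z + b.z + c.z) / 4.0;
    cx += v6 / 6.0 * tcx;
    cy += v6 / 6.0 * tcy;
    cz += v6 / 6.0 * tcz;
  }
  if (vol <= 0) return degen;

  IntegerMatrix fm(nf, 3);
  int r = 0;
  for (const Face &f : faces) {
    if (!f.alive) continue;
    fm(r, 0) = f.a + 1;
    fm(r, 1) = f.b + 1;
    fm(r, 2) = f.c + 1;
    ++r;
  }
  return List::create(_["degenerate"] = false, _["volume"] = vol,
                      _["centroid"] = NumericVector::create(cx / vol, cy / vol, cz / vol),
                      _["faces"] = fm);
}

// For each query point q (row of `query`), the parameter t >= 0 at which the
// ray centroid -> q exits the convex hull: t = min over faces with n.dir > 0
// of plane intersection. Normalized radial position is then 1/t (0 for q at
// the centroid). Exact for a convex polytope; no triangle test needed.
// [[Rcpp::export(name = ".hull_radial")]]
NumericVector hull_radial(NumericMatrix pts, IntegerMatrix faces,
                          NumericVector centroid, NumericMatrix query) {
  const int nf = faces.nrow(), nq = query.nrow();
  std::vector<Vec3> p(pts.nrow());
  for (int i = 0; i < pts.nrow(); ++i) p[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
  Vec3 c = {centroid[0], centroid[1], centroid[2]};
  std::vector<Vec3> nrm(nf), v0(nf);
  for (int f = 0; f < nf; ++f) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, cc = faces(f, 2) - 1;
    nrm[f] = cross(sub(p[b], p[a]), sub(p[cc], p[a]));
    v0[f] = p[a];
  }
  NumericVector out(nq);
  for (int q = 0; q < nq; ++q) {
    Vec3 pt = {query(q, 0), query(q, 1), query(q, 2)};
    Vec3 dir = sub(pt, c);
    double len = norm(dir);
    if (len == 0) { out[q] = 0.0; continue; }
    double tmin = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double denom = dot(nrm[f], dir);
      if (denom <= 0) continue;
      double t = dot(nrm[f], sub(v0[f], c)) / denom;
      if (t > 0 && t < tmin) tmin = t;
    }
    out[q] = (R_finite(tmin) && tmin > 0) ? 1.0 / tmin : NA_REAL;
  }
  return out;
}
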