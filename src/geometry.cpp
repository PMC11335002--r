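// Geometry kernel: triangle-triangle intersection (exact contact queries)
// and ray-parity point-in-mesh tests (grid overlap volumes).
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 v3(double x, double y, double z) { return Vec3{x, y, z}; }
inline Vec3 sub(const Vec3& a, const Vec3& b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

struct Tri {
  Vec3 a, b, c;
  double lo[3], hi[3];
};

inline void triBounds(Tri& t) {
  t.lo[0] = std::min(t.a.x, std::min(t.b.x, t.c.x));
  t.lo[1] = std::min(t.a.y, std::min(t.b.y, t.c.y));
  t.lo[2] = std::min(t.a.z, std::min(t.b.z, t.c.z));
  t.hi[0] = std::max(t.a.x, std::max(t.b.x, t.c.x));
  t.hi[1] = std::max(t.a.y, std::max(t.b.y, t.c.y));
  t.hi[2] = std::max(t.a.z, std::max(t.b.z, t.c.z));
}

inline bool boxOverlap(const Tri& s, const Tri& t) {
  for (int k = 0; k < 3; ++k)
    if (s.hi[k] < t.lo[k] || t.hi[k] < s.lo[k]) return false;
  return true;
}

std::vector<Tri> collectTris(const NumericMatrix& V, const IntegerMatrix& F) {
  std::vector<Tri> tris(F.nrow());
  for (int i = 0; i < F.nrow(); ++i) {
    int ia = F(i, 0), ib = F(i, 1), ic = F(i, 2);
    tris[i].a = v3(V(ia, 0), V(ia, 1), V(ia, 2));
    tris[i].b = v3(V(ib, 0), V(ib, 1), V(ib, 2));
    tris[i].c = v3(V(ic, 0), V(ic, 1), V(ic, 2));
    triBounds(tris[i]);
  }
  return tris;
}

// ---- Moller (1997) triangle-triangle intersection test ------------------

inline void isect(double vv0, double vv1, double vv2, double d0, double d1, double d2,
                  double* i0, double* i1) {
  *i0 = vv0 + (vv1 - vv0) * d0 / (d0 - d1);
  *i1 = vv0 + (vv2 - vv0) * d0 / (d0 - d2);
}

bool coplanarTriTri(const Vec3& n, const Tri& t1, const Tri& t2);

bool triTriIntersect(const Tri& t1, const Tri& t2) {
  Vec3 e1 = sub(t1.b, t1.a), e2 = sub(t1.c, t1.a);
  Vec3 n1 = cross(e1, e2);
  double d1 = -dot(n1, t1.a);
  double du0 = dot(n1, t2.a) + d1;
  double du1 = dot(n1, t2.b) + d1;
  double du2 = dot(n1, t2.c) + d1;
  double du0du1 = du0 * du1, du0du2 = du0 * du2;
  if (du0du1 > 0.0 && du0du2 > 0.0) return false;

  Vec3 e3 = sub(t2.b, t2.a), e4 = sub(t2.c, t2.a);
  Vec3 n2 = cross(e3, e4);
  double d2 = -dot(n2, t2.a);
  double dv0 = dot(n2, t1.a) + d2;
  double dv1 = dot(n2, t1.b) + d2;
  double dv2 = dot(n2, t1.c) + d2;
  double dv0dv1 = dv0 * dv1, dv0dv2 = dv0 * dv2;
  if (dv0dv1 > 0.0 && dv0dv2 > 0.0) return false;

  Vec3 dd = cross(n1, n2);
  double max = std::fabs(dd.x);
  int index = 0;
  double bb = std::fabs(dd.y), cc = std::fabs(dd.z);
  if (bb > max) { max = bb; index = 1; }
  if (cc > max) { max = cc; index = 2; }
  if (max < 1e-30) {
    // coplanar (or degenerate) triangles
    if (du0 != 0.0 || du1 != 0.0 || du2 != 0.0) return false;
    return coplanarTriTri(n1, t1, t2);
  }

  auto proj = [index](const Vec3& p) { return index == 0 ? p.x : (index == 1 ? p.y : p.z); };
  double vp0 = proj(t1.a), vp1 = proj(t1.b), vp2 = proj(t1.c);
  double up0 = proj(t2.a), up1 = proj(t2.b), up2 = proj(t2.c);

  double isect1[2], isect2[2];
  // interval for triangle 1
  if (dv0dv1 > 0.0) isect(vp2, vp0, vp1, dv2, dv0, dv1, &isect1[0], &isect1[1]);
  else if (dv0dv2 > 0.0) isect(vp1, vp0, vp2, dv1, dv0, dv2, &isect1[0], &isect1[1]);
  else if (dv1 * dv2 > 0.0 || dv0 != 0.0) isect(vp0, vp1, vp2, dv0, dv1, dv2, &isect1[0], &isect1[1]);
  else if (dv1 != 0.0) isect(vp1, vp0, vp2, dv1, dv0, dv2, &isect1[0], &isect1[1]);
  else if (dv2 != 0.0) isect(vp2, vp0, vp1, dv2, dv0, dv1, &isect1[0], &isect1[1]);
  else return coplanarTriTri(n1, t1, t2);
  // interval for triangle 2
  if (du0du1 > 0.0) isect(up2, up0, up1, du2, du0, du1, &isect2[0], &isect2[1]);
  else if (du0du2 > 0.0) isect(up1, up0, up2, du1, du0, du2, &isect2[0], &isect2[1]);
  else if (du1 * du2 > 0.0 || du0 != 0.0) isect(up0, up1, up2, du0, du1, du2, &isect2[0], &isect2[1]);
  else if (du1 != 0.0) isect(up1, up0, up2, du1, du0, du2, &isect2[0], &isect2[1]);
  else if (du2 != 0.0) isect(up2, up0, up1, du2, du0, du1, &isect2[0], &isect2[1]);
  else return coplanarTriTri(n1, t1, t2);

  if (isect1[0] > isect1[1]) std::swap(isect1[0], isect1[1]);
  if (isect2[0] > isect2[1]) std::swap(isect2[0], isect2[1]);
  return !(isect1[1] < isect2[0] || isect2[1] < isect1[0]);
}

inline bool edgeEdge2d(double ax, double ay, double bx, double by,
                       double cx, double cy, double dx_, double dy_) {
  double r[2] = {bx - ax, by - ay};
  double s[2] = {dx_ - cx, dy_ - cy};
  double denom = r[0] * s[1] - r[1] * s[0];
  double qpx = cx - ax, qpy = cy - ay;
  double tnum = qpx * s[1] - qpy * s[0];
  double unum = qpx * r[1] - qpy * r[0];
  if (denom == 0.0) return false;  // parallel; containment test covers overlap
  double t = tnum / denom, u = -unum / denom;
  // note: u sign convention depends on denom; recompute robustly
  u = (qpx * r[1] - qpy * r[0]) / denom;
  return t >= 0.0 && t <= 1.0 && u >= 0.0 && u <= 1.0;
}

inline bool pointInTri2d(double px, double py, double ax, double ay,
                         double bx, double by, double cx, double cy) {
  double d1 = (px - bx) * (ay - by) - (ax - bx) * (py - by);
  double d2 = (px - cx) * (by - cy) - (bx - cx) * (py - cy);
  double d3 = (px - ax) * (cy - ay) - (cx - ax) * (py - ay);
  bool neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
  bool pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
  return !(neg && pos);
}

bool coplanarTriTri(const Vec3& n, const Tri& t1, const Tri& t2) {
  // project onto the dominant axis plane
  double ax = std::fabs(n.x), ay = std::fabs(n.y), az = std::fabs(n.z);
  int i0, i1;
  if (ax > ay && ax > az) { i0 = 1; i1 = 2; }
  else if (ay > az) { i0 = 0; i1 = 2; }
  else { i0 = 0; i1 = 1; }
  auto gx = [i0](const Vec3& p) { return i0 == 0 ? p.x : p.y; };
  auto gy = [i1](const Vec3& p) { return i1 == 1 ? p.y : p.z; };
  double p1[3][2] = {{gx(t1.a), gy(t1.a)}, {gx(t1.b), gy(t1.b)}, {gx(t1.c), gy(t1.c)}};
  double p2[3][2] = {{gx(t2.a), gy(t2.a)}, {gx(t2.b), gy(t2.b)}, {gx(t2.c), gy(t2.c)}};
  for (int i = 0; i < 3; ++i) {
    int j = (i + 1) % 3;
    for (int k = 0; k < 3; ++k) {
      int l = (k + 1) % 3;
      if (edgeEdge2d(p1[i][0], p1[i][1], p1[j][0], p1[j][1],
                     p2[k][0], p2[k][1], p2[l][0], p2[l][1])) return true;
    }
  }
  if (pointInTri2d(p1[0][0], p1[0][1], p2[0][0], p2[0][1], p2[1][0], p2[1][1], p2[2][0], p2[2][1]))
    return true;
  if (pointInTri2d(p2[0][0], p2[0][1], p1[0][0], p1[0][1], p1[1][0], p1[1][1], p1[2][0], p1[2][1]))
    return true;
  return false;
}

// ---- ray-parity point-in-mesh -------------------------------------------

// fixed "irrational" ray directions: avoid axis-aligned degeneracies
const double RAY_DIRS[4][3] = {
  {0.2989889356329, 0.5932359736688, 0.7475622352163},
  {-0.5633212752344, 0.7218191321117, 0.4019874301137},
  {0.8021291237642, -0.1223498713519, 0.5844942761239},
  {0.1431562298374, -0.8352631492385, -0.5309841237465}
};

// 0 = outside, 1 = inside, -1 = uncertain (grazing hit)
int rayParity(const Vec3& p, const std::vector<Tri>& tris,
              const std::vector<int>& idx, const Vec3& dir) {
  int crossings = 0;
  const double EPS = 1e-10;
  for (int k : idx) {
    const Tri& t = tris[k];
    Vec3 e1 = sub(t.b, t.a), e2 = sub(t.c, t.a);
    Vec3 pv = cross(dir, e2);
    double det = dot(e1, pv);
    if (std::fabs(det) < 1e-14) continue;  // parallel to plane
    double inv = 1.0 / det;
    Vec3 tv = sub(p, t.a);
    double u = dot(tv, pv) * inv;
    if (u < -EPS || u > 1.0 + EPS) continue;
    Vec3 qv = cross(tv, e1);
    double v = dot(dir, qv) * inv;
    if (v < -EPS || u + v > 1.0 + EPS) continue;
    double tt = dot(e2, qv) * inv;
    if (tt <= 0.0) {
      if (tt > -EPS) return -1;  // point on surface: uncertain
      continue;
    }
    // grazing: hit near an edge/vertex of the triangle
    if (u < EPS || v < EPS || u + v > 1.0 - EPS) return -1;
    ++crossings;
  }
  return crossings % 2;
}

bool pointInComponent(const Vec3& p, const std::vector<Tri>& tris,
                      const std::vector<int>& idx) {
  for (int d = 0; d < 4; ++d) {
    Vec3 dir = v3(RAY_DIRS[d][0], RAY_DIRS[d][1], RAY_DIRS[d][2]);
    int r = rayParity(p, tris, idx, dir);
    if (r >= 0) return r == 1;
  }
  return true;  // on-surface for all probes: call it inside
}

}  // namespace

// [[Rcpp::export]]
bool cpp_meshes_intersect(NumericMatrix VA, IntegerMatrix FA,
                          NumericMatrix VB, IntegerMatrix FB) {
  std::vector<Tri> ta = collectTris(VA, FA);
  std::vector<Tri> tb = collectTris(VB, FB);
  // overall bounding boxes
  Tri boxA{}, boxB{};
  for (int k = 0; k < 3; ++k) {
    boxA.lo[k] = R_PosInf; boxA.hi[k] = R_NegInf;
    boxB.lo[k] = R_PosInf; boxB.hi[k] = R_NegInf;
  }
  for (const Tri& t : ta)
    for (int k = 0; k < 3; ++k) {
      boxA.lo[k] = std::min(boxA.lo[k], t.lo[k]);
      boxA.hi[k] = std::max(boxA.hi[k], t.hi[k]);
    }
  for (const Tri& t : tb)
    for (int k = 0; k < 3; ++k) {
      boxB.lo[k] = std::min(boxB.lo[k], t.lo[k]);
      boxB.hi[k] = std::max(boxB.hi[k], t.hi[k]);
    }
  if (!boxOverlap(boxA, boxB)) return false;
  // candidate triangles restricted to the box overlap region
  Tri region{};
  for (int k = 0; k < 3; ++k) {
    region.lo[k] = std::max(boxA.lo[k], boxB.lo[k]);
    region.hi[k] = std::min(boxA.hi[k], boxB.hi[k]);
  }
  std::vector<const Tri*> ca, cb;
  for (const Tri& t : ta) if (boxOverlap(t, region)) ca.push_back(&t);
  for (const Tri& t : tb) if (boxOverlap(t, region)) cb.push_back(&t);
  for (const Tri* s : ca)
    for (const Tri* t : cb) {
      if (!boxOverlap(*s, *t)) continue;
      if (triTriIntersect(*s, *t)) return true;
    }
  return false;
}

// [[Rcpp::export]]
NumericVector cpp_intersect_region(NumericMatrix VA, IntegerMatrix FA,
                                   NumericMatrix VB, IntegerMatrix FB) {
  // returns c(found, lo_xyz, hi_xyz): AABB of all intersecting triangle pairs
  std::vector<Tri> ta = collectTris(VA, FA);
  std::vector<Tri> tb = collectTris(VB, FB);
  NumericVector out(7);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  bool found = false;
  for (const Tri& s : ta)
    for (const Tri& t : tb) {
      if (!boxOverlap(s, t)) continue;
      if (!triTriIntersect(s, t)) continue;
      found = true;
      for (int k = 0; k < 3; ++k) {
        lo[k] = std::min(lo[k], std::max(s.lo[k], t.lo[k]));
        hi[k] = std::max(hi[k], std::min(s.hi[k], t.hi[k]));
      }
    }
  out[0] = found ? 1.0 : 0.0;
  for (int k = 0; k < 3; ++k) { out[1 + k] = lo[k]; out[4 + k] = hi[k]; }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix P, NumericMatrix V,
                                 IntegerMatrix F, IntegerVector comp) {
  std::vector<Tri> tris = collectTris(V, F);
  int ncomp = 0;
  for (int i = 0; i < comp.size(); ++i) ncomp = std::max(ncomp, comp[i] + 1);
  std::vector<std::vector<int>> byComp(ncomp);
  for (int i = 0; i < comp.size(); ++i) byComp[comp[i]].push_back(i);
  // per-component bounding boxes
  std::vector<Tri> cbox(ncomp);
  for (int c = 0; c < ncomp; ++c) {
    for (int k = 0; k < 3; ++k) { cbox[c].lo[k] = R_PosInf; cbox[c].hi[k] = R_NegInf; }
    for (int i : byComp[c])
      for (int k = 0; k < 3; ++k) {
        cbox[c].lo[k] = std::min(cbox[c].lo[k], tris[i].lo[k]);
        cbox[c].hi[k] = std::max(cbox[c].hi[k], tris[i].hi[k]);
      }
  }
  int n = P.nrow();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    Vec3 p = v3(P(i, 0), P(i, 1), P(i, 2));
    bool inside = false;
    for (int c = 0; c < ncomp && !inside; ++c) {
      if (p.x < cbox[c].lo[0] || p.x > cbox[c].hi[0] ||
          p.y < cbox[c].lo[1] || p.y > cbox[c].hi[1] ||
          p.z < cbox[c].lo[2] || p.z > cbox[c].hi[2]) continue;
      inside = pointInComponent(p, tris, byComp[c]);
    }
    out[i] = inside;
  }
  return out;
}

// [[Rcpp::export]]
double cpp_grid_inside_both(NumericMatrix VA, IntegerMatrix FA, IntegerVector compA,
                            NumericMatrix VB, IntegerMatrix FB, IntegerVector compB,
                            NumericVector lo, NumericVector hi, IntegerVector nDiv) {
  // count grid cell centres inside both meshes; returns estimated volume
  std::vector<Tri> ta = collectTris(VA, FA);
  std::vector<Tri> tb = collectTris(VB, FB);
  int ncompA = 0, ncompB = 0;
  for (int i = 0; i < compA.size(); ++i) ncompA = std::max(ncompA, compA[i] + 1);
  for (int i = 0; i < compB.size(); ++i) ncompB = std::max(ncompB, compB[i] + 1);
  std::vector<std::vector<int>> bcA(ncompA), bcB(ncompB);
  for (int i = 0; i < compA.size(); ++i) bcA[compA[i]].push_back(i);
  for (int i = 0; i < compB.size(); ++i) bcB[compB[i]].push_back(i);

  int nx = nDiv[0], ny = nDiv[1], nz = nDiv[2];
  double dx = (hi[0] - lo[0]) / nx, dy = (hi[1] - lo[1]) / ny, dz = (hi[2] - lo[2]) / nz;
  long count = 0;
  for (int i = 0; i < nx; ++i) {
    double px = lo[0] + (i + 0.5) * dx;
    for (int j = 0; j < ny; ++j) {
      double py = lo[1] + (j + 0.5) * dy;
      for (int k = 0; k < nz; ++k) {
        Vec3 p = v3(px, py, lo[2] + (k + 0.5) * dz);
        bool inA = false;
        for (int c = 0; c < ncompA && !inA; ++c) inA = pointInComponent(p, ta, bcA[c]);
        if (!inA) continue;
        bool inB = false;
        for (int c = 0; c < ncompB && !inB; ++c) inB = pointInComponent(p, tb, bcB[c]);
        if (inB) ++count;
      }
    }
  }
  return count * dx * dy * dz;
}
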