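// Compiled mesh primitives: ray-parity membership and exact point-to-
// triangle projection. Meshes from voxelized enclosing volumes reach ~1e5
// triangles, so these inner loops are the hot path of the volumetric
// labelling route and of grid snapping.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// squared distance from point p to triangle (a,b,c); Ericson, Real-Time
// Collision Detection, closest-point-on-triangle.
static double tri_dist2(const double* p, const double* a, const double* b,
                        const double* c, double* closest) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) { ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i]; }
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int i = 0; i < 3; ++i) closest[i] = a[i];
  } else {
    double bp[3]; for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
    double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
    if (d3 >= 0.0 && d4 <= d3) {
      for (int i = 0; i < 3; ++i) closest[i] = b[i];
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int i = 0; i < 3; ++i) closest[i] = a[i] + v * ab[i];
      } else {
        double cp[3]; for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
        double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
        if (d6 >= 0.0 && d5 <= d6) {
          for (int i = 0; i < 3; ++i) closest[i] = c[i];
        } else {
          double vb = d5 * d2 - d1 * d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = d2 / (d2 - d6);
            for (int i = 0; i < 3; ++i) closest[i] = a[i] + w * ac[i];
          } else {
            double va = d3 * d6 - d5 * d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int i = 0; i < 3; ++i) closest[i] = b[i] + w * (c[i] - b[i]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int i = 0; i < 3; ++i) closest[i] = a[i] + ab[i] * v + ac[i] * w;
            }
          }
        }
      }
    }
  }
  double d[3] = { p[0] - closest[0], p[1] - closest[1], p[2] - closest[2] };
  return dot3(d, d);
}

// Moller-Trumbore; returns 1 on a clean interior hit with t > 0, -1 when
// the hit is degenerate (grazing an edge/vertex or t ~ 0), 0 on a miss.
static int ray_tri(const double* o, const double* d, const double* a,
                   const double* b, const double* c) {
  const double EPS = 1e-12, BEPS = 1e-9;
  double e1[3], e2[3], pv[3], tv[3], qv[3];
  for (int i = 0; i < 3; ++i) { e1[i] = b[i] - a[i]; e2[i] = c[i] - a[i]; }
  pv[0] = d[1] * e2[2] - d[2] * e2[1];
  pv[1] = d[2] * e2[0] - d[0] * e2[2];
  pv[2] = d[0] * e2[1] - d[1] * e2[0];
  double det = dot3(e1, pv);
  if (std::fabs(det) < EPS) return 0;
  double inv = 1.0 / det;
  for (int i = 0; i < 3; ++i) tv[i] = o[i] - a[i];
  double u = dot3(tv, pv) * inv;
  if (u < -BEPS || u > 1 + BEPS) return 0;
  qv[0] = tv[1] * e1[2] - tv[2] * e1[1];
  qv[1] = tv[2] * e1[0] - tv[0] * e1[2];
  qv[2] = tv[0] * e1[1] - tv[1] * e1[0];
  double v = dot3(d, qv) * inv;
  if (v < -BEPS || u + v > 1 + BEPS) return 0;
  double t = dot3(e2, qv) * inv;
  if (t <= 0) return (t > -BEPS) ? -1 : 0;
  // near an edge or vertex: parity unreliable, ask for another direction
  if (u < BEPS || v < BEPS || u + v > 1 - BEPS || t < BEPS) return -1;
  return 1;
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix pts, NumericMatrix V,
                                 IntegerMatrix F, double eps) {
  int np = pts.nrow(), nf = F.nrow();
  LogicalVector out(np);
  // a few fixed, mutually skew directions; retried on degenerate hits
  double dirs[5][3] = {
    {0.5773502691896258, 0.2113248654051871, 0.7886751345948129},
    {0.8556428941123031, 0.4628299385983368, 0.2341203156383280},
    {0.1429847751348341, 0.9138847291288371, 0.3800912383718341},
    {0.3984712938471234, 0.1298347123847123, 0.9081726354817263},
    {0.7071067811865475, 0.6324555320336759, 0.3162277660168379}};
  double cl[3];
  for (int i = 0; i < np; ++i) {
    double p[3] = { pts(i, 0), pts(i, 1), pts(i, 2) };
    // boundary counts as inside
    bool onb = false;
    double e2 = eps * eps;
    for (int j = 0; j < nf && !onb; ++j) {
      double a[3] = { V(F(j,0),0), V(F(j,0),1), V(F(j,0),2) };
      double b[3] = { V(F(j,1),0), V(F(j,1),1), V(F(j,1),2) };
      double c[3] = { V(F(j,2),0), V(F(j,2),1), V(F(j,2),2) };
      if (tri_dist2(p, a, b, c, cl) <= e2) onb = true;
    }
    if (onb) { out[i] = true; continue; }
    bool decided = false;
    for (int k = 0; k < 5 && !decided; ++k) {
      int hits = 0; bool degen = false;
      for (int j = 0; j < nf; ++j) {
        double a[3] = { V(F(j,0),0), V(F(j,0),1), V(F(j,0),2) };
        double b[3] = { V(F(j,1),0), V(F(j,1),1), V(F(j,1),2) };
        double c[3] = { V(F(j,2),0), V(F(j,2),1), V(F(j,2),2) };
        int r = ray_tri(p, dirs[k], a, b, c);
        if (r == -1) { degen = true; break; }
        hits += r;
      }
      if (!degen) { out[i] = (hits % 2) == 1; decided = true; }
    }
    if (!decided) out[i] = false;  // all directions degenerate: vanishing measure
  }
  return out;
}

// [[Rcpp::export]]
List cpp_nearest_point_on_mesh(NumericMatrix pts, NumericMatrix V,
                               IntegerMatrix F) {
  int np = pts.nrow(), nf = F.nrow();
  NumericMatrix proj(np, 3);
  NumericVector dist(np);
  IntegerVector face(np);
  double cl[3];
  for (int i = 0; i < np; ++i) {
    double p[3] = { pts(i, 0), pts(i, 1), pts(i, 2) };
    double best = R_PosInf; int bj = 0; double bp[3] = {0, 0, 0};
    for (int j = 0; j < nf; ++j) {
      double a[3] = { V(F(j,0),0), V(F(j,0),1), V(F(j,0),2) };
      double b[3] = { V(F(j,1),0), V(F(j,1),1), V(F(j,1),2) };
      double c[3] = { V(F(j,2),0), V(F(j,2),1), V(F(j,2),2) };
      double d2 = tri_dist2(p, a, b, c, cl);
      if (d2 < best) { best = d2; bj = j; bp[0] = cl[0]; bp[1] = cl[1]; bp[2] = cl[2]; }
    }
    proj(i, 0) = bp[0]; proj(i, 1) = bp[1]; proj(i, 2) = bp[2];
    dist[i] = std::sqrt(best);
    face[i] = bj;
  }
  return List::create(_["points"] = proj, _["distance"] = dist, _["face"] = face);
}
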