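// Geometry kernels: point-to-triangle-surface distances (Eberly's closest
// point on a triangle), deterministic nearest-point queries with lowest-index
// tie-breaks, and a triangle-triangle intersection census with bounding-box
// prefilter (Moller's separating-axis test).
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
inline void sub3(const double* a, const double* b, double* c) {
  c[0] = a[0] - b[0]; c[1] = a[1] - b[1]; c[2] = a[2] - b[2];
}
inline void cross3(const double* a, const double* b, double* c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

// squared distance from point P to triangle (A,B,C)
double pt_tri_sq(const double* P, const double* A, const double* B,
                 const double* C) {
  double ab[3], ac[3], ap[3];
  sub3(B, A, ab); sub3(C, A, ac); sub3(P, A, ap);
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0 && d2 <= 0) return dot3(ap, ap);
  double bp[3];
  sub3(P, B, bp);
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0 && d4 <= d3) return dot3(bp, bp);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    double q[3] = {A[0] + v * ab[0] - P[0], A[1] + v * ab[1] - P[1],
                   A[2] + v * ab[2] - P[2]};
    return dot3(q, q);
  }
  double cp[3];
  sub3(P, C, cp);
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0 && d5 <= d6) return dot3(cp, cp);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    double q[3] = {A[0] + w * ac[0] - P[0], A[1] + w * ac[1] - P[1],
                   A[2] + w * ac[2] - P[2]};
    return dot3(q, q);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double q[3] = {B[0] + w * (C[0] - B[0]) - P[0],
                   B[1] + w * (C[1] - B[1]) - P[1],
                   B[2] + w * (C[2] - B[2]) - P[2]};
    return dot3(q, q);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  double q[3] = {A[0] + v * ab[0] + w * ac[0] - P[0],
                 A[1] + v * ab[1] + w * ac[1] - P[1],
                 A[2] + v * ab[2] + w * ac[2] - P[2]};
  return dot3(q, q);
}

}  // namespace

// min distance from each query point to a triangle surface (+ 1-based tri id)
// [[Rcpp::export]]
List cpp_dist_to_surface(NumericMatrix P, NumericMatrix V, IntegerMatrix Tri) {
  int nq = P.nrow(), nt = Tri.nrow();
  NumericVector dist(nq);
  IntegerVector which(nq);
  // per-triangle bounding spheres for pruning
  std::vector<double> cx(nt), cy(nt), cz(nt), cr(nt);
  for (int t = 0; t < nt; ++t) {
    double c[3] = {0, 0, 0};
    for (int a = 0; a < 3; ++a)
      for (int j = 0; j < 3; ++j) c[j] += V(Tri(t, a) - 1, j) / 3.0;
    double r2 = 0;
    for (int a = 0; a < 3; ++a) {
      double d2 = 0;
      for (int j = 0; j < 3; ++j) {
        double d = V(Tri(t, a) - 1, j) - c[j];
        d2 += d * d;
      }
      r2 = std::max(r2, d2);
    }
    cx[t] = c[0]; cy[t] = c[1]; cz[t] = c[2]; cr[t] = std::sqrt(r2);
  }
  for (int q = 0; q < nq; ++q) {
    double p[3] = {P(q, 0), P(q, 1), P(q, 2)};
    double best = R_PosInf;
    int bi = 0;
    for (int t = 0; t < nt; ++t) {
      double dx = p[0] - cx[t], dy = p[1] - cy[t], dz = p[2] - cz[t];
      double dc = std::sqrt(dx * dx + dy * dy + dz * dz) - cr[t];
      if (dc * dc >= best && dc > 0) continue;
      double A[3], B[3], C[3];
      for (int j = 0; j < 3; ++j) {
        A[j] = V(Tri(t, 0) - 1, j);
        B[j] = V(Tri(t, 1) - 1, j);
        C[j] = V(Tri(t, 2) - 1, j);
      }
      double d2 = pt_tri_sq(p, A, B, C);
      if (d2 < best) { best = d2; bi = t + 1; }
    }
    dist[q] = std::sqrt(best);
    which[q] = bi;
  }
  return List::create(_["dist"] = dist, _["tri"] = which);
}

// for each row of A, index (1-based) of nearest row of B; ties -> lowest index
// [[Rcpp::export]]
IntegerVector cpp_nearest_index(NumericMatrix A, NumericMatrix B) {
  int na = A.nrow(), nb = B.nrow();
  IntegerVector out(na);
  for (int q = 0; q < na; ++q) {
    double best = R_PosInf;
    int bi = 1;
    for (int t = 0; t < nb; ++t) {
      double d2 = 0;
      for (int j = 0; j < 3; ++j) {
        double d = A(q, j) - B(t, j);
        d2 += d * d;
      }
      if (d2 < best) { best = d2; bi = t + 1; }
    }
    out[q] = bi;
  }
  return out;
}

namespace {

// Moller interval-overlap triangle-triangle intersection test.
bool tri_tri_overlap(const double* V0, const double* V1, const double* V2,
                     const double* U0, const double* U1, const double* U2) {
  const double eps = 1e-10;
  double E1[3], E2[3], N1[3];
  sub3(V1, V0, E1); sub3(V2, V0, E2); cross3(E1, E2, N1);
  double d1 = -dot3(N1, V0);
  double du0 = dot3(N1, U0) + d1, du1 = dot3(N1, U1) + d1,
         du2 = dot3(N1, U2) + d1;
  if (std::fabs(du0) < eps) du0 = 0;
  if (std::fabs(du1) < eps) du1 = 0;
  if (std::fabs(du2) < eps) du2 = 0;
  double du01 = du0 * du1, du02 = du0 * du2;
  if (du01 > 0 && du02 > 0) return false;
  double F1[3], F2[3], N2[3];
  sub3(U1, U0, F1); sub3(U2, U0, F2); cross3(F1, F2, N2);
  double d2 = -dot3(N2, U0);
  double dv0 = dot3(N2, V0) + d2, dv1 = dot3(N2, V1) + d2,
         dv2 = dot3(N2, V2) + d2;
  if (std::fabs(dv0) < eps) dv0 = 0;
  if (std::fabs(dv1) < eps) dv1 = 0;
  if (std::fabs(dv2) < eps) dv2 = 0;
  double dv01 = dv0 * dv1, dv02 = dv0 * dv2;
  if (dv01 > 0 && dv02 > 0) return false;
  if (du0 == 0 && du1 == 0 && du2 == 0) return false;  // coplanar: ignored
  double D[3];
  cross3(N1, N2, D);
  int idx = 0;
  double m = std::fabs(D[0]);
  if (std::fabs(D[1]) > m) { m = std::fabs(D[1]); idx = 1; }
  if (std::fabs(D[2]) > m) idx = 2;
  double vp0 = V0[idx], vp1 = V1[idx], vp2 = V2[idx];
  double up0 = U0[idx], up1 = U1[idx], up2 = U2[idx];
  auto interval = [](double p0, double p1, double p2, double dd0, double dd1,
                     double dd2, double* t) -> bool {
    double d01 = dd0 * dd1, d02 = dd0 * dd2;
    double a, b, c, x0, x1;
    if (d02 > 0) { a = p1; b = (p0 - p1) * dd1; c = (p2 - p1) * dd1;
                   x0 = dd1 - dd0; x1 = dd1 - dd2; }
    else if (d01 > 0) { a = p2; b = (p0 - p2) * dd2; c = (p1 - p2) * dd2;
                        x0 = dd2 - dd0; x1 = dd2 - dd1; }
    else if (dd1 * dd2 > 0 || dd0 != 0) {
      a = p0; b = (p1 - p0) * dd0; c = (p2 - p0) * dd0;
      x0 = dd0 - dd1; x1 = dd0 - dd2;
    } else if (dd1 != 0) { a = p1; b = (p0 - p1) * dd1; c = (p2 - p1) * dd1;
                           x0 = dd1 - dd0; x1 = dd1 - dd2; }
    else if (dd2 != 0) { a = p2; b = (p0 - p2) * dd2; c = (p1 - p2) * dd2;
                         x0 = dd2 - dd0; x1 = dd2 - dd1; }
    else return false;  // coplanar
    t[0] = a + b / x0 * 1.0;
    t[1] = a + c / x1 * 1.0;
    // scaled form: isect = a + b/x0, a + c/x1 (after common scaling)
    return true;
  };
  double t1[2], t2[2];
  if (!interval(vp0, vp1, vp2, dv0, dv1, dv2, t1)) return false;
  if (!interval(up0, up1, up2, du0, du1, du2, t2)) return false;
  if (t1[0] > t1[1]) std::swap(t1[0], t1[1]);
  if (t2[0] > t2[1]) std::swap(t2[0], t2[1]);
  return !(t1[1] < t2[0] + eps || t2[1] < t1[0] + eps);
}

}  // namespace

// count of intersecting, non-vertex-sharing triangle pairs on one surface
// [[Rcpp::export]]
int cpp_self_intersections(NumericMatrix V, IntegerMatrix Tri) {
  int nt = Tri.nrow();
  std::vector<double> lo(3 * nt), hi(3 * nt);
  for (int t = 0; t < nt; ++t)
    for (int j = 0; j < 3; ++j) {
      double a = V(Tri(t, 0) - 1, j), b = V(Tri(t, 1) - 1, j),
             c = V(Tri(t, 2) - 1, j);
      lo[3 * t + j] = std::min(a, std::min(b, c));
      hi[3 * t + j] = std::max(a, std::max(b, c));
    }
  int count = 0;
  for (int s = 0; s < nt; ++s) {
    for (int t = s + 1; t < nt; ++t) {
      bool sep = false;
      for (int j = 0; j < 3; ++j)
        if (lo[3 * s + j] > hi[3 * t + j] || lo[3 * t + j] > hi[3 * s + j]) {
          sep = true;
          break;
        }
      if (sep) continue;
      bool share = false;
      for (int a = 0; a < 3 && !share; ++a)
        for (int b = 0; b < 3; ++b)
          if (Tri(s, a) == Tri(t, b)) { share = true; break; }
      if (share) continue;
      double A[3][3], B[3][3];
      for (int a = 0; a < 3; ++a)
        for (int j = 0; j < 3; ++j) {
          A[a][j] = V(Tri(s, a) - 1, j);
          B[a][j] = V(Tri(t, a) - 1, j);
        }
      if (tri_tri_overlap(A[0], A[1], A[2], B[0], B[1], B[2])) ++count;
    }
  }
  return count;
}
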