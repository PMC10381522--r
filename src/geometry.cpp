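#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Closest distance from point p to triangle (a,b,c).
// Region-based closest-point algorithm (Ericson, Real-Time Collision Detection, 5.1.5).
static double pt_tri_dist2(const double *p, const double *a, const double *b,
                           const double *c) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) {
    q[0] = a[0]; q[1] = a[1]; q[2] = a[2];
  } else {
    double bp[3], cp[3];
    for (int k = 0; k < 3; ++k) { bp[k] = p[k] - b[k]; cp[k] = p[k] - c[k]; }
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
    double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      q[0] = b[0]; q[1] = b[1]; q[2] = b[2];
    } else if (d6 >= 0.0 && d5 <= d6) {
      q[0] = c[0]; q[1] = c[1]; q[2] = c[2];
    } else {
      double vc = d1 * d4 - d3 * d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = (d1 - d3) != 0.0 ? d1 / (d1 - d3) : 0.0;
        for (int k = 0; k < 3; ++k) q[k] = a[k] + v * ab[k];
      } else {
        double vb = d5 * d2 - d1 * d6;
        if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
          double w = (d2 - d6) != 0.0 ? d2 / (d2 - d6) : 0.0;
          for (int k = 0; k < 3; ++k) q[k] = a[k] + w * ac[k];
        } else {
          double va = d3 * d6 - d5 * d4;
          if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
            double den = (d4 - d3) + (d5 - d6);
            double w = den != 0.0 ? (d4 - d3) / den : 0.0;
            for (int k = 0; k < 3; ++k) q[k] = b[k] + w * (c[k] - b[k]);
          } else {
            double denom = va + vb + vc;
            double v = denom != 0.0 ? vb / denom : 0.0;
            double w = denom != 0.0 ? vc / denom : 0.0;
            for (int k = 0; k < 3; ++k) q[k] = a[k] + ab[k] * v + ac[k] * w;
          }
        }
      }
    }
  }
  double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
  return dx * dx + dy * dy + dz * dz;
}

// Unsigned nearest distance from each row of P to the triangle set (V, F).
// Two-stage filter: the centroid pass yields an upper bound, then only
// triangles whose bounding sphere can beat it are tested exactly.
// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance(NumericMatrix P, NumericMatrix V,
                                      IntegerMatrix F) {
  int np = P.nrow(), nt = F.nrow();
  if (nt == 0) stop("empty triangle set");
  std::vector<double> cx(nt), cy(nt), cz(nt), rad(nt);
  std::vector<double> tri(9 * nt);
  for (int t = 0; t < nt; ++t) {
    double mx = 0, my = 0, mz = 0;
    for (int j = 0; j < 3; ++j) {
      int v = F(t, j) - 1;
      tri[9 * t + 3 * j + 0] = V(v, 0);
      tri[9 * t + 3 * j + 1] = V(v, 1);
      tri[9 * t + 3 * j + 2] = V(v, 2);
      mx += V(v, 0); my += V(v, 1); mz += V(v, 2);
    }
    cx[t] = mx / 3.0; cy[t] = my / 3.0; cz[t] = mz / 3.0;
    double r2 = 0;
    for (int j = 0; j < 3; ++j) {
      double dx = tri[9 * t + 3 * j + 0] - cx[t];
      double dy = tri[9 * t + 3 * j + 1] - cy[t];
      double dz = tri[9 * t + 3 * j + 2] - cz[t];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > r2) r2 = d2;
    }
    rad[t] = std::sqrt(r2);
  }
  NumericVector out(np);
  std::vector<double> dc(nt);
  for (int i = 0; i < np; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    double ub = R_PosInf;
    int tmin = 0;
    for (int t = 0; t < nt; ++t) {
      double dx = p[0] - cx[t], dy = p[1] - cy[t], dz = p[2] - cz[t];
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      dc[t] = d;
      if (d < ub) { ub = d; tmin = t; }
    }
    double best2 = pt_tri_dist2(p, &tri[9 * tmin], &tri[9 * tmin + 3],
                                &tri[9 * tmin + 6]);
    double best = std::sqrt(best2);
    for (int t = 0; t < nt; ++t) {
      if (dc[t] - rad[t] >= best) continue;
      double d2 = pt_tri_dist2(p, &tri[9 * t], &tri[9 * t + 3], &tri[9 * t + 6]);
      if (d2 < best2) { best2 = d2; best = std::sqrt(best2); }
    }
    out[i] = best;
  }
  return out;
}

// Vertical (-z) ray cast of each query point onto the triangle set.
// A uniform 2D grid over the xy bounding box prunes candidate triangles.
// Returns per point: z of the chosen intersection and a hit flag.
// Preference: highest intersection at or below the query z; if none,
// the intersection nearest in |dz|.
// [[Rcpp::export]]
List cpp_raycast_down(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  int np = P.nrow(), nt = F.nrow();
  if (nt == 0) stop("empty triangle set");
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int v = 0; v < V.nrow(); ++v) {
    if (V(v, 0) < xmin) xmin = V(v, 0);
    if (V(v, 0) > xmax) xmax = V(v, 0);
    if (V(v, 1) < ymin) ymin = V(v, 1);
    if (V(v, 1) > ymax) ymax = V(v, 1);
  }
  int ng = (int)std::ceil(std::sqrt((double)nt / 2.0));
  if (ng < 1) ng = 1;
  if (ng > 512) ng = 512;
  double ex = (xmax - xmin), ey = (ymax - ymin);
  if (ex <= 0) ex = 1e-9;
  if (ey <= 0) ey = 1e-9;
  double hx = ex / ng, hy = ey / ng;
  std::vector<std::vector<int> > cells(ng * ng);
  for (int t = 0; t < nt; ++t) {
    double txmin = R_PosInf, txmax = R_NegInf, tymin = R_PosInf, tymax = R_NegInf;
    for (int j = 0; j < 3; ++j) {
      int v = F(t, j) - 1;
      if (V(v, 0) < txmin) txmin = V(v, 0);
      if (V(v, 0) > txmax) txmax = V(v, 0);
      if (V(v, 1) < tymin) tymin = V(v, 1);
      if (V(v, 1) > tymax) tymax = V(v, 1);
    }
    int i0 = (int)std::floor((txmin - xmin) / hx), i1 = (int)std::floor((txmax - xmin) / hx);
    int j0 = (int)std::floor((tymin - ymin) / hy), j1 = (int)std::floor((tymax - ymin) / hy);
    if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0;
    if (i1 >= ng) i1 = ng - 1; if (j1 >= ng) j1 = ng - 1;
    for (int ii = i0; ii <= i1; ++ii)
      for (int jj = j0; jj <= j1; ++jj)
        cells[ii * ng + jj].push_back(t);
  }
  NumericVector zout(np);
  LogicalVector hit(np), below(np);
  const double beps = 1e-10;
  for (int i = 0; i < np; ++i) {
    double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
    int ci = (int)std::floor((px - xmin) / hx);
    int cj = (int)std::floor((py - ymin) / hy);
    // clamp queries on the bounding-box edge into the outermost cells
    if (ci == ng) ci = ng - 1;
    if (cj == ng) cj = ng - 1;
    bool any = false, anyBelow = false;
    double bestBelow = R_NegInf, bestAnyDz = R_PosInf, bestAnyZ = NA_REAL;
    if (ci >= 0 && ci < ng && cj >= 0 && cj < ng) {
      const std::vector<int> &cand = cells[ci * ng + cj];
      for (size_t m = 0; m < cand.size(); ++m) {
        int t = cand[m];
        int v0 = F(t, 0) - 1, v1 = F(t, 1) - 1, v2 = F(t, 2) - 1;
        double ax = V(v0, 0), ay = V(v0, 1), az = V(v0, 2);
        double bx = V(v1, 0), by = V(v1, 1), bz = V(v1, 2);
        double cx2 = V(v2, 0), cy2 = V(v2, 1), cz2 = V(v2, 2);
        double d = (by - cy2) * (ax - cx2) + (cx2 - bx) * (ay - cy2);
        if (std::fabs(d) < 1e-300) continue;
        double l1 = ((by - cy2) * (px - cx2) + (cx2 - bx) * (py - cy2)) / d;
        double l2 = ((cy2 - ay) * (px - cx2) + (ax - cx2) * (py - cy2)) / d;
        double l3 = 1.0 - l1 - l2;
        if (l1 < -beps || l2 < -beps || l3 < -beps) continue;
        double zhit = l1 * az + l2 * bz + l3 * cz2;
        any = true;
        if (zhit <= pz + 1e-9) {
          anyBelow = true;
          if (zhit > bestBelow) bestBelow = zhit;
        }
        double dz = std::fabs(zhit - pz);
        if (dz < bestAnyDz) { bestAnyDz = dz; bestAnyZ = zhit; }
      }
    }
    hit[i] = any;
    below[i] = anyBelow;
    zout[i] = any ? (anyBelow ? bestBelow : bestAnyZ) : NA_REAL;
  }
  return List::create(_["z"] = zout, _["hit"] = hit, _["below"] = below);
}
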