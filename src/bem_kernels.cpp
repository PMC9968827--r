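#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Signed solid angle subtended by each mesh triangle at each observation
// point (van Oosterom & Strackee 1983).  Faces must be consistently
// oriented; with outward normals the angles of a closed surface sum to
// 4*pi for an interior observation point and 0 for an exterior one.
// vertices: nv x 3, faces: nf x 3 (1-based), obs: m x 3.  Result: m x nf.
// [[Rcpp::export(name = ".solidAngleMatrix")]]
NumericMatrix solidAngleMatrix(NumericMatrix obs, NumericMatrix vertices,
                               IntegerMatrix faces) {
  const int m = obs.nrow(), nf = faces.nrow();
  NumericMatrix out(m, nf);
  for (int f = 0; f < nf; ++f) {
    const int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    const double ax = vertices(a, 0), ay = vertices(a, 1), az = vertices(a, 2);
    const double bx = vertices(b, 0), by = vertices(b, 1), bz = vertices(b, 2);
    const double cx = vertices(c, 0), cy = vertices(c, 1), cz = vertices(c, 2);
    for (int i = 0; i < m; ++i) {
      const double r1x = ax - obs(i, 0), r1y = ay - obs(i, 1), r1z = az - obs(i, 2);
      const double r2x = bx - obs(i, 0), r2y = by - obs(i, 1), r2z = bz - obs(i, 2);
      const double r3x = cx - obs(i, 0), r3y = cy - obs(i, 1), r3z = cz - obs(i, 2);
      const double n1 = std::sqrt(r1x * r1x + r1y * r1y + r1z * r1z);
      const double n2 = std::sqrt(r2x * r2x + r2y * r2y + r2z * r2z);
      const double n3 = std::sqrt(r3x * r3x + r3y * r3y + r3z * r3z);
      const double triple = r1x * (r2y * r3z - r2z * r3y)
                          - r1y * (r2x * r3z - r2z * r3x)
                          + r1z * (r2x * r3y - r2y * r3x);
      const double d12 = r1x * r2x + r1y * r2y + r1z * r2z;
      const double d13 = r1x * r3x + r1y * r3y + r1z * r3z;
      const double d23 = r2x * r3x + r2y * r3y + r2z * r3z;
      const double den = n1 * n2 * n3 + d12 * n3 + d13 * n2 + d23 * n1;
      out(i, f) = 2.0 * std::atan2(triple, den);
    }
  }
  return out;
}

// Inverse-distance kernel matrix 1/max(|obs_i - src_j|, rmin_j).
// obs: m x 3, src: n x 3, rmin: length n (may be all zeros).  Result: m x n.
// [[Rcpp::export(name = ".invDistMatrix")]]
NumericMatrix invDistMatrix(NumericMatrix obs, NumericMatrix src,
                            NumericVector rmin) {
  const int m = obs.nrow(), n = src.nrow();
  NumericMatrix out(m, n);
  for (int j = 0; j < n; ++j) {
    const double sx = src(j, 0), sy = src(j, 1), sz = src(j, 2);
    const double rm = rmin[j];
    for (int i = 0; i < m; ++i) {
      const double dx = obs(i, 0) - sx, dy = obs(i, 1) - sy, dz = obs(i, 2) - sz;
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < rm) r = rm;
      if (r == 0.0) stop("field point coincides with a source and rmin is 0");
      out(i, j) = 1.0 / r;
    }
  }
  return out;
}

// Minimum Euclidean distance from each query point to a triangle mesh,
// handling face/edge/vertex closest-point cases exactly
// (Eberly's point-triangle projection in barycentric form).
// [[Rcpp::export(name = ".pointMeshDistance")]]
NumericVector pointMeshDistance(NumericMatrix pts, NumericMatrix vertices,
                                IntegerMatrix faces) {
  const int np = pts.nrow(), nf = faces.nrow();
  NumericVector out(np);
  for (int i = 0; i < np; ++i) {
    const double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      const int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
      const double ax = vertices(a, 0), ay = vertices(a, 1), az = vertices(a, 2);
      double e0x = vertices(b, 0) - ax, e0y = vertices(b, 1) - ay, e0z = vertices(b, 2) - az;
      double e1x = vertices(c, 0) - ax, e1y = vertices(c, 1) - ay, e1z = vertices(c, 2) - az;
      double dx = ax - px, dy = ay - py, dz = az - pz;
      const double A = e0x * e0x + e0y * e0y + e0z * e0z;
      const double B = e0x * e1x + e0y * e1y + e0z * e1z;
      const double C = e1x * e1x + e1y * e1y + e1z * e1z;
      const double D = e0x * dx + e0y * dy + e0z * dz;
      const double E = e1x * dx + e1y * dy + e1z * dz;
      const double det = A * C - B * B;
      double s = B * E - C * D, t = B * D - A * E;
      if (s + t <= det) {
        if (s < 0) {
          if (t < 0) { // region 4
            if (D < 0) { t = 0; s = (-D >= A ? 1 : -D / A); }
            else { s = 0; t = (E >= 0 ? 0 : (-E >= C ? 1 : -E / C)); }
          } else { // region 3
            s = 0; t = (E >= 0 ? 0 : (-E >= C ? 1 : -E / C));
          }
        } else if (t < 0) { // region 5
          t = 0; s = (D >= 0 ? 0 : (-D >= A ? 1 : -D / A));
        } else { // region 0
          const double inv = 1.0 / det; s *= inv; t *= inv;
        }
      } else {
        if (s < 0) { // region 2
          const double tmp0 = B + D, tmp1 = C + E;
          if (tmp1 > tmp0) {
            const double numer = tmp1 - tmp0, denom = A - 2 * B + C;
            s = (numer >= denom ? 1 : numer / denom); t = 1 - s;
          } else { s = 0; t = (tmp1 <= 0 ? 1 : (E >= 0 ? 0 : -E / C)); }
        } else if (t < 0) { // region 6
          const double tmp0 = B + E, tmp1 = A + D;
          if (tmp1 > tmp0) {
            const double numer = tmp1 - tmp0, denom = A - 2 * B + C;
            t = (numer >= denom ? 1 : numer / denom); s = 1 - t;
          } else { t = 0; s = (tmp1 <= 0 ? 1 : (D >= 0 ? 0 : -D / A)); }
        } else { // region 1
          const double numer = (C + E) - (B + D);
          if (numer <= 0) s = 0;
          else { const double denom = A - 2 * B + C; s = (numer >= denom ? 1 : numer / denom); }
          t = 1 - s;
        }
      }
      const double qx = dx + s * e0x + t * e1x;
      const double qy = dy + s * e0y + t * e1y;
      const double qz = dz + s * e0z + t * e1z;
      const double d2 = qx * qx + qy * qy + qz * qz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
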