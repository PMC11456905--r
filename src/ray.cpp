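#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exact voxel-traversal (Amanatides-Woo style) line integral of a scalar
// map along the segment p0 -> p1, in mm. Voxel [i,j,k] (0-based here) is
// the axis-aligned box centred at origin + idx * spacing, i.e. it spans
// origin + (idx - 0.5) * spacing .. origin + (idx + 0.5) * spacing.
// Values outside the grid contribute zero.
static double segment_integral(const double* map, const int* dims,
                               const double* spacing, const double* origin,
                               const double* p0, const double* p1) {
  double d[3], lo[3], hi[3];
  double seg_len = 0.0;
  for (int a = 0; a < 3; ++a) {
    d[a] = p1[a] - p0[a];
    seg_len += d[a] * d[a];
    lo[a] = origin[a] - 0.5 * spacing[a];
    hi[a] = origin[a] + (dims[a] - 0.5) * spacing[a];
  }
  seg_len = std::sqrt(seg_len);
  if (seg_len <= 0.0) return 0.0;

  // clip the segment (parameter t in [0,1]) to the grid box
  double t0 = 0.0, t1 = 1.0;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) < 1e-12) {
      if (p0[a] < lo[a] || p0[a] > hi[a]) return 0.0;
    } else {
      double ta = (lo[a] - p0[a]) / d[a];
      double tb = (hi[a] - p0[a]) / d[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
    }
  }
  if (t0 >= t1) return 0.0;

  // traverse voxels between t0 and t1
  double pos[3];
  int idx[3], step[3];
  double tMax[3], tDelta[3];
  const double eps = 1e-9;
  for (int a = 0; a < 3; ++a) {
    pos[a] = p0[a] + (t0 + eps) * d[a];
    double f = (pos[a] - (origin[a] - 0.5 * spacing[a])) / spacing[a];
    idx[a] = (int)std::floor(f);
    if (idx[a] < 0) idx[a] = 0;
    if (idx[a] >= dims[a]) idx[a] = dims[a] - 1;
    if (d[a] > 0) {
      step[a] = 1;
      double bnd = origin[a] + (idx[a] + 0.5) * spacing[a];
      tMax[a] = (bnd - p0[a]) / d[a];
      tDelta[a] = spacing[a] / d[a];
    } else if (d[a] < 0) {
      step[a] = -1;
      double bnd = origin[a] + (idx[a] - 0.5) * spacing[a];
      tMax[a] = (bnd - p0[a]) / d[a];
      tDelta[a] = -spacing[a] / d[a];
    } else {
      step[a] = 0;
      tMax[a] = R_PosInf;
      tDelta[a] = R_PosInf;
    }
  }
  double integral = 0.0;
  double t = t0;
  int guard = 3 * (dims[0] + dims[1] + dims[2]) + 6;
  while (t < t1 && guard-- > 0) {
    int a = 0;
    if (tMax[1] < tMax[a]) a = 1;
    if (tMax[2] < tMax[a]) a = 2;
    double t_next = tMax[a] < t1 ? tMax[a] : t1;
    double val = map[idx[0] + (size_t)dims[0] * (idx[1] + (size_t)dims[1] * idx[2])];
    integral += val * (t_next - t) * seg_len;
    t = t_next;
    if (t >= t1) break;
    idx[a] += step[a];
    if (idx[a] < 0 || idx[a] >= dims[a]) break;
    tMax[a] += tDelta[a];
  }
  return integral;
}

// [[Rcpp::export(name = ".segment_integrals")]]
NumericVector segment_integrals(NumericVector map, IntegerVector dims,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix p0, NumericMatrix p1) {
  const int n = p0.nrow();
  if (p1.nrow() != n) stop("p0 and p1 must have the same number of rows");
  NumericVector out(n);
  int dm[3] = {dims[0], dims[1], dims[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double og[3] = {origin[0], origin[1], origin[2]};
  for (int r = 0; r < n; ++r) {
    double a[3] = {p0(r, 0), p0(r, 1), p0(r, 2)};
    double b[3] = {p1(r, 0), p1(r, 1), p1(r, 2)};
    out[r] = segment_integral(REAL(map), dm, sp, og, a, b);
  }
  return out;
}

// Radiological depth of every listed point along a fixed (parallel-beam)
// direction: integral of the map from grid entry to the point.
// [[Rcpp::export(name = ".ray_depths")]]
NumericVector ray_depths(NumericVector map, IntegerVector dims,
                         NumericVector spacing, NumericVector origin,
                         NumericVector direction, NumericMatrix points) {
  const int n = points.nrow();
  NumericVector out(n);
  int dm[3] = {dims[0], dims[1], dims[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double og[3] = {origin[0], origin[1], origin[2]};
  double norm = std::sqrt(direction[0] * direction[0] +
                          direction[1] * direction[1] +
                          direction[2] * direction[2]);
  if (norm <= 0) stop("direction must be non-zero");
  // back-off distance safely beyond the grid along -direction
  double diag = 0.0;
  for (int a = 0; a < 3; ++a) diag += dims[a] * sp[a] * dims[a] * sp[a];
  diag = std::sqrt(diag) + 10.0;
  double d[3] = {direction[0] / norm, direction[1] / norm, direction[2] / norm};
  for (int r = 0; r < n; ++r) {
    double b[3] = {points(r, 0), points(r, 1), points(r, 2)};
    double a[3] = {b[0] - diag * d[0], b[1] - diag * d[1], b[2] - diag * d[2]};
    out[r] = segment_integral(REAL(map), dm, sp, og, a, b);
  }
  return out;
}
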