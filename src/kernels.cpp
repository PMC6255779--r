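#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Separable 1-D convolution of a 3-D volume along one axis.
// Kernel is renormalised where it overhangs the boundary, so a constant
// volume is an exact fixed point and the mean is preserved.
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector vol, IntegerVector dim,
                                int axis, NumericVector kernel) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const int klen = kernel.size();
  const int rad = (klen - 1) / 2;
  NumericVector out(vol.size());
  int n, s1, s2, n2, n3, sa;
  // sa: stride along the convolved axis; s1/s2 strides of the other two
  if (axis == 1)      { n = d1; sa = 1;       n2 = d2; s1 = d1;      n3 = d3; s2 = d1 * d2; }
  else if (axis == 2) { n = d2; sa = d1;      n2 = d1; s1 = 1;       n3 = d3; s2 = d1 * d2; }
  else                { n = d3; sa = d1 * d2; n2 = d1; s1 = 1;       n3 = d2; s2 = d1; }
  for (int k = 0; k < n3; ++k) {
    for (int j = 0; j < n2; ++j) {
      const int base = j * s1 + k * s2;
      for (int i = 0; i < n; ++i) {
        double acc = 0.0, ksum = 0.0;
        const int lo = std::max(-rad, -i), hi = std::min(rad, n - 1 - i);
        for (int t = lo; t <= hi; ++t) {
          const double w = kernel[t + rad];
          acc += w * vol[base + (i + t) * sa];
          ksum += w;
        }
        out[base + i * sa] = acc / ksum;
      }
    }
  }
  return out;
}

static inline double catmull_rom(double p0, double p1, double p2, double p3,
                                 double t) {
  return p1 + 0.5 * t * (p2 - p0 +
         t * (2.0 * p0 - 5.0 * p1 + 4.0 * p2 - p3 +
         t * (3.0 * (p1 - p2) + p3 - p0)));
}

// Resample a 3-D volume along one axis at positions `newpos` given in the
// 0-based index space of the old axis. method: 0 = linear, 1 = Catmull-Rom
// cubic. Positions outside the axis are clamped to the boundary samples.
// [[Rcpp::export]]
NumericVector cpp_resample_axis(NumericVector vol, IntegerVector dim,
                                int axis, NumericVector newpos, int method) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  int n, s1, s2, n2, n3, sa;
  if (axis == 1)      { n = d1; sa = 1;       n2 = d2; s1 = d1;      n3 = d3; s2 = d1 * d2; }
  else if (axis == 2) { n = d2; sa = d1;      n2 = d1; s1 = 1;       n3 = d3; s2 = d1 * d2; }
  else                { n = d3; sa = d1 * d2; n2 = d1; s1 = 1;       n3 = d2; s2 = d1; }
  const int m = newpos.size();
  // output strides mirror the input layout with axis length m
  int o1 = (axis == 1) ? m : d1;
  int o2 = (axis == 2) ? m : d2;
  int os1, os2, osa;
  if (axis == 1)      { osa = 1;       os1 = o1;      os2 = o1 * o2; }
  else if (axis == 2) { osa = o1;      os1 = 1;       os2 = o1 * o2; }
  else                { osa = o1 * o2; os1 = 1;       os2 = o1; }
  NumericVector out((R_xlen_t)m * n2 * n3);
  for (int k = 0; k < n3; ++k) {
    for (int j = 0; j < n2; ++j) {
      const int base = j * s1 + k * s2;
      const int obase = j * os1 + k * os2;
      for (int i = 0; i < m; ++i) {
        double x = newpos[i];
        if (x < 0) x = 0;
        if (x > n - 1) x = n - 1;
        const int i0 = (int)std::floor(x);
        const double t = x - i0;
        double v;
        if (method == 0 || n == 1) {
          const int i1 = std::min(i0 + 1, n - 1);
          v = (1.0 - t) * vol[base + i0 * sa] + t * vol[base + i1 * sa];
        } else {
          const int im1 = std::max(i0 - 1, 0);
          const int i1 = std::min(i0 + 1, n - 1);
          const int i2 = std::min(i0 + 2, n - 1);
          v = catmull_rom(vol[base + im1 * sa], vol[base + i0 * sa],
                          vol[base + i1 * sa], vol[base + i2 * sa], t);
        }
        out[obase + i * osa] = v;
      }
    }
  }
  return out;
}

// Trilinear sampling at arbitrary points. coords: m x 3 matrix of 0-based
// voxel coordinates. Points outside the grid return `fill`.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, IntegerVector dim,
                            NumericMatrix coords, double fill) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t m = coords.nrow();
  NumericVector out(m);
  for (R_xlen_t p = 0; p < m; ++p) {
    const double x = coords(p, 0), y = coords(p, 1), z = coords(p, 2);
    if (x < 0 || y < 0 || z < 0 || x > d1 - 1 || y > d2 - 1 || z > d3 - 1) {
      out[p] = fill;
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 == d1 - 1) i0--;
    if (j0 == d2 - 1) j0--;
    if (k0 == d3 - 1) k0--;
    if (i0 < 0) i0 = 0;
    if (j0 < 0) j0 = 0;
    if (k0 < 0) k0 = 0;
    const double tx = x - i0, ty = y - j0, tz = z - k0;
    double acc = 0.0;
    for (int dz = 0; dz < 2; ++dz)
      for (int dy = 0; dy < 2; ++dy)
        for (int dx = 0; dx < 2; ++dx) {
          const double w = (dx ? tx : 1 - tx) * (dy ? ty : 1 - ty) *
                           (dz ? tz : 1 - tz);
          acc += w * vol[(i0 + dx) + d1 * ((j0 + dy) + (R_xlen_t)d2 * (k0 + dz))];
        }
    out[p] = acc;
  }
  return out;
}

// 26-connected component of a 3-D logical mask containing the (0-based)
// linear seed index. Returns a logical vector of the same length.
// [[Rcpp::export]]
LogicalVector cpp_component_from_seed(LogicalVector mask, IntegerVector dim,
                                      int seed) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  LogicalVector out(mask.size());
  if (seed < 0 || seed >= mask.size() || !mask[seed]) return out;
  std::vector<char> seen(mask.size(), 0);
  std::queue<int> q;
  q.push(seed);
  seen[seed] = 1;
  while (!q.empty()) {
    const int v = q.front();
    q.pop();
    out[v] = true;
    const int k = v / (d1 * d2);
    const int r = v % (d1 * d2);
    const int j = r / d1;
    const int i = r % d1;
    for (int dz = -1; dz <= 1; ++dz) {
      const int kk = k + dz;
      if (kk < 0 || kk >= d3) continue;
      for (int dy = -1; dy <= 1; ++dy) {
        const int jj = j + dy;
        if (jj < 0 || jj >= d2) continue;
        for (int dx = -1; dx <= 1; ++dx) {
          const int ii = i + dx;
          if (ii < 0 || ii >= d1 || (dx == 0 && dy == 0 && dz == 0)) continue;
          const int w = ii + d1 * (jj + d2 * kk);
          if (mask[w] && !seen[w]) {
            seen[w] = 1;
            q.push(w);
          }
        }
      }
    }
  }
  return out;
}
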