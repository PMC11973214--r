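// Trilinear resampling kernels for dense 3-D grids. Coordinates are 0-based
// voxel indices and are edge-clamped, matching the R-level convention.
#include <Rcpp.h>
using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Trilinear sample of one 3-D array at n points.
// [[Rcpp::export(name = ".sampleTrilinearCpp")]]
NumericVector sample_trilinear(NumericVector arr, IntegerVector dims,
                               NumericVector x, NumericVector y,
                               NumericVector z) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = x.size();
  NumericVector out(n);
  const double *a = arr.begin();
  for (R_xlen_t t = 0; t < n; ++t) {
    double xi = clampd(x[t], 0.0, d1 - 1.0);
    double yi = clampd(y[t], 0.0, d2 - 1.0);
    double zi = clampd(z[t], 0.0, d3 - 1.0);
    int i0 = (int)xi; if (i0 > d1 - 2) i0 = d1 > 1 ? d1 - 2 : 0;
    int j0 = (int)yi; if (j0 > d2 - 2) j0 = d2 > 1 ? d2 - 2 : 0;
    int k0 = (int)zi; if (k0 > d3 - 2) k0 = d3 > 1 ? d3 - 2 : 0;
    const double fx = xi - i0, fy = yi - j0, fz = zi - k0;
    const int i1 = i0 + (d1 > 1), j1 = j0 + (d2 > 1), k1 = k0 + (d3 > 1);
    const double gx = 1 - fx, gy = 1 - fy, gz = 1 - fz;
    const R_xlen_t s1 = d1, s12 = (R_xlen_t)d1 * d2;
    const R_xlen_t b00 = i0 + j0 * s1, b10 = i1 + j0 * s1;
    const R_xlen_t b01 = i0 + j1 * s1, b11 = i1 + j1 * s1;
    const R_xlen_t o0 = k0 * s12, o1 = k1 * s12;
    out[t] =
      (a[b00 + o0] * gx * gy + a[b10 + o0] * fx * gy +
       a[b01 + o0] * gx * fy + a[b11 + o0] * fx * fy) * gz +
      (a[b00 + o1] * gx * gy + a[b10 + o1] * fx * gy +
       a[b01 + o1] * gx * fy + a[b11 + o1] * fx * fy) * fz;
  }
  return out;
}

// Trilinear sample of all 3 components of a 4-D vector field at shared
// points; weights computed once per point. Returns an n x 3 matrix.
// [[Rcpp::export(name = ".sampleField4Cpp")]]
NumericMatrix sample_field4(NumericVector field, IntegerVector dims,
                            NumericVector x, NumericVector y,
                            NumericVector z) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = x.size();
  const R_xlen_t s123 = (R_xlen_t)d1 * d2 * d3;
  NumericMatrix out(n, 3);
  const double *a = field.begin();
  for (R_xlen_t t = 0; t < n; ++t) {
    double xi = clampd(x[t], 0.0, d1 - 1.0);
    double yi = clampd(y[t], 0.0, d2 - 1.0);
    double zi = clampd(z[t], 0.0, d3 - 1.0);
    int i0 = (int)xi; if (i0 > d1 - 2) i0 = d1 > 1 ? d1 - 2 : 0;
    int j0 = (int)yi; if (j0 > d2 - 2) j0 = d2 > 1 ? d2 - 2 : 0;
    int k0 = (int)zi; if (k0 > d3 - 2) k0 = d3 > 1 ? d3 - 2 : 0;
    const double fx = xi - i0, fy = yi - j0, fz = zi - k0;
    const int i1 = i0 + (d1 > 1), j1 = j0 + (d2 > 1), k1 = k0 + (d3 > 1);
    const double gx = 1 - fx, gy = 1 - fy, gz = 1 - fz;
    const double w000 = gx * gy * gz, w100 = fx * gy * gz;
    const double w010 = gx * fy * gz, w110 = fx * fy * gz;
    const double w001 = gx * gy * fz, w101 = fx * gy * fz;
    const double w011 = gx * fy * fz, w111 = fx * fy * fz;
    const R_xlen_t s1 = d1, s12 = (R_xlen_t)d1 * d2;
    const R_xlen_t b000 = i0 + j0 * s1 + k0 * s12;
    const R_xlen_t b100 = i1 + j0 * s1 + k0 * s12;
    const R_xlen_t b010 = i0 + j1 * s1 + k0 * s12;
    const R_xlen_t b110 = i1 + j1 * s1 + k0 * s12;
    const R_xlen_t b001 = i0 + j0 * s1 + k1 * s12;
    const R_xlen_t b101 = i1 + j0 * s1 + k1 * s12;
    const R_xlen_t b011 = i0 + j1 * s1 + k1 * s12;
    const R_xlen_t b111 = i1 + j1 * s1 + k1 * s12;
    for (int c = 0; c < 3; ++c) {
      const double *f = a + c * s123;
      out(t, c) = f[b000] * w000 + f[b100] * w100 + f[b010] * w010 +
                  f[b110] * w110 + f[b001] * w001 + f[b101] * w101 +
                  f[b011] * w011 + f[b111] * w111;
    }
  }
  return out;
}
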