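// Trilinear patch extraction on transformed 16^3 lattices.
//
// Coordinates are 0-based (z, y, x) matching a volume array of dim (D, H, W).
// A patch lattice has m points per axis spanning a cube of edge `a`
// (spacing a/(m-1)) centered on a continuous center; offsets are mapped by a
// 3x3 matrix A (rotation * deformation). Out-of-range coordinates are
// reflected about the volume faces (mirror padding), which for piecewise
// folds aligned to the lattice is identical to interpolating a
// reflect-padded volume.

#include <Rcpp.h>
using namespace Rcpp;

static inline double reflect_coord(double t, int n) {
  if (n == 1) return 0.0;
  const double period = 2.0 * (n - 1);
  t -= std::floor(t / period) * period;  // into [0, period)
  if (t > n - 1) t = period - t;
  return t;
}

// [[Rcpp::export]]
NumericMatrix extract_patches_cpp(NumericVector vol, IntegerVector vdim,
                                  NumericMatrix centers, NumericMatrix A,
                                  NumericVector sizes, int m) {
  const int D = vdim[0], H = vdim[1], W = vdim[2];
  const int N = centers.nrow();
  const double* v = REAL(vol);
  NumericMatrix out(m * m * m, N);
  std::vector<double> g(m);
  for (int n = 0; n < N; ++n) {
    const double a = sizes[n];
    for (int p = 0; p < m; ++p) g[p] = a * ((double)p / (m - 1) - 0.5);
    const double cz = centers(n, 0), cy = centers(n, 1), cx = centers(n, 2);
    const double a00 = A(n, 0), a01 = A(n, 1), a02 = A(n, 2);
    const double a10 = A(n, 3), a11 = A(n, 4), a12 = A(n, 5);
    const double a20 = A(n, 6), a21 = A(n, 7), a22 = A(n, 8);
    double* col = &out(0, n);
    for (int px = 0; px < m; ++px) {
      for (int py = 0; py < m; ++py) {
        for (int pz = 0; pz < m; ++pz) {
          const double gz = g[pz], gy = g[py], gx = g[px];
          double z = cz + a00 * gz + a01 * gy + a02 * gx;
          double y = cy + a10 * gz + a11 * gy + a12 * gx;
          double x = cx + a20 * gz + a21 * gy + a22 * gx;
          z = reflect_coord(z, D);
          y = reflect_coord(y, H);
          x = reflect_coord(x, W);
          int z0 = (int)std::floor(z), y0 = (int)std::floor(y),
              x0 = (int)std::floor(x);
          if (z0 > D - 2) z0 = D - 2;
          if (y0 > H - 2) y0 = H - 2;
          if (x0 > W - 2) x0 = W - 2;
          if (z0 < 0) z0 = 0;
          if (y0 < 0) y0 = 0;
          if (x0 < 0) x0 = 0;
          const int z1 = (D == 1) ? 0 : z0 + 1;
          const int y1 = (H == 1) ? 0 : y0 + 1;
          const int x1 = (W == 1) ? 0 : x0 + 1;
          const double fz = z - z0, fy = y - y0, fx = x - x0;
#define V(zz, yy, xx) v[(zz) + D * ((yy) + (size_t)H * (xx))]
          const double c00 = V(z0, y0, x0) * (1 - fz) + V(z1, y0, x0) * fz;
          const double c10 = V(z0, y1, x0) * (1 - fz) + V(z1, y1, x0) * fz;
          const double c01 = V(z0, y0, x1) * (1 - fz) + V(z1, y0, x1) * fz;
          const double c11 = V(z0, y1, x1) * (1 - fz) + V(z1, y1, x1) * fz;
#undef V
          const double c0 = c00 * (1 - fy) + c10 * fy;
          const double c1 = c01 * (1 - fy) + c11 * fy;
          col[pz + m * (py + m * px)] = c0 * (1 - fx) + c1 * fx;
        }
      }
    }
  }
  return out;
}
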