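// Interpolation-heavy operators for helical reconstruction:
// volume projection, image rotation/shift, helical resampling,
// weighted back-projection, and FFT-based exhaustive alignment.
//
// Conventions (shared with the R side):
//  * volumes are nx x ny x nz arrays; x is the fastest index, z the
//    filament axis; all rotations are right-handed about +z (azimuth)
//    or +x (out-of-plane tilt); centre of rotation is (n-1)/2 per axis.
//  * projection at (phi, theta): rotate the volume by Rz(phi), then
//    Rx(theta), then integrate along +y.  The image is an n x n matrix
//    with rows = x, columns = z.
//  * rotate_shift_image(img, angle, dx, dy): shift by (dx, dy) pixels,
//    THEN rotate by angle (CCW, degrees) about the image centre.

#include <Rcpp.h>
using namespace Rcpp;

static const double DEG = M_PI / 180.0;

static const double EDGE_EPS = 1e-9;

static inline double clamp_edge(double x, int n) {
  // rotations by multiples of 90 degrees land exactly on the grid up
  // to ~1e-15 rounding; do not let that fall off the boundary
  if (x < 0 && x > -EDGE_EPS) return 0.0;
  if (x > n - 1 && x < n - 1 + EDGE_EPS) return n - 1;
  return x;
}

// trilinear sample; ok=false when outside the grid
static inline double tri_sample(const double* v, int nx, int ny, int nz,
                                double x, double y, double z, bool& ok) {
  x = clamp_edge(x, nx);
  y = clamp_edge(y, ny);
  z = clamp_edge(z, nz);
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    ok = false;
    return 0.0;
  }
  ok = true;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  double fx = x - x0, fy = y - y0, fz = z - z0;
  const double* p = v + (size_t)z0 * nx * ny + (size_t)y0 * nx + x0;
  size_t sx = 1, sy = nx, sz = (size_t)nx * ny;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

static inline double bi_sample(const double* img, int nr, int nc,
                               double r, double c, bool& ok) {
  r = clamp_edge(r, nr);
  c = clamp_edge(c, nc);
  if (r < 0 || c < 0 || r > nr - 1 || c > nc - 1) {
    ok = false;
    return 0.0;
  }
  ok = true;
  int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  if (r0 == nr - 1) r0--;
  if (c0 == nc - 1) c0--;
  double fr = r - r0, fc = c - c0;
  const double* p = img + (size_t)c0 * nr + r0;
  double v00 = p[0], v10 = p[1], v01 = p[nr], v11 = p[nr + 1];
  return (v00 * (1 - fr) + v10 * fr) * (1 - fc) +
         (v01 * (1 - fr) + v11 * fr) * fc;
}

// [[Rcpp::export]]
NumericMatrix project_volume_cpp(NumericVector vol, double phi_deg,
                                 double theta_deg) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  double cp = std::cos(phi_deg * DEG), sp = std::sin(phi_deg * DEG);
  double ct = std::cos(theta_deg * DEG), st = std::sin(theta_deg * DEG);
  // source = Rz(-phi) * Rx(-theta) * p
  NumericMatrix img(nx, nz);
  const double* v = vol.begin();
  for (int k = 0; k < nz; k++) {
    for (int j = 0; j < ny; j++) {
      for (int i = 0; i < nx; i++) {
        double X = i - cx, Y = j - cy, Z = k - cz;
        // Rx(-theta): y' = ct*Y + st*Z ; z' = -st*Y + ct*Z
        double y1 = ct * Y + st * Z;
        double z1 = -st * Y + ct * Z;
        // Rz(-phi): x'' = cp*X + sp*y1 ; y'' = -sp*X + cp*y1
        double x2 = cp * X + sp * y1;
        double y2 = -sp * X + cp * y1;
        bool ok;
        double val = tri_sample(v, nx, ny, nz, x2 + cx, y2 + cy, z1 + cz, ok);
        if (ok) img(i, k) += val;
      }
    }
  }
  return img;
}

// [[Rcpp::export]]
NumericMatrix rotate_shift_image_cpp(NumericMatrix img, double angle_deg,
                                     double dx, double dy) {
  int nr = img.nrow(), nc = img.ncol();
  double cr = (nr - 1) / 2.0, cc = (nc - 1) / 2.0;
  double ca = std::cos(angle_deg * DEG), sa = std::sin(angle_deg * DEG);
  NumericMatrix out(nr, nc);
  const double* p = img.begin();
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) {
      double X = i - cr, Y = j - cc;
      // inverse map: un-rotate, then un-shift
      double xs = ca * X + sa * Y - dx + cr;
      double ys = -sa * X + ca * Y - dy + cc;
      bool ok;
      double val = bi_sample(p, nr, nc, xs, ys, ok);
      out(i, j) = ok ? val : 0.0;
    }
  }
  return out;
}

// Resample a volume under the helical operator g(twist, rise):
// out(p) = vol(Rz(-twist) * (p - rise*ez)).  Returns values and an
// in-bounds indicator so callers can weight-normalise.
// [[Rcpp::export]]
List resample_volume_cpp(NumericVector vol, double twist_deg,
                         double rise_px) {
  IntegerVector d = vol.attr("dim");
  int nx = d[0], ny = d[1], nz = d[2];
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  double ca = std::cos(twist_deg * DEG), sa = std::sin(twist_deg * DEG);
  NumericVector vals((size_t)nx * ny * nz);
  NumericVector wt((size_t)nx * ny * nz);
  vals.attr("dim") = d;
  wt.attr("dim") = d;
  const double* v = vol.begin();
  size_t idx = 0;
  for (int k = 0; k < nz; k++) {
    double Z = k - cz - rise_px;
    for (int j = 0; j < ny; j++) {
      double Y = j - cy;
      for (int i = 0; i < nx; i++, idx++) {
        double X = i - cx;
        double xs = ca * X + sa * Y + cx;   // Rz(-twist)
        double ys = -sa * X + ca * Y + cy;
        bool ok;
        double val = tri_sample(v, nx, ny, nz, xs, ys, Z + cz, ok);
        if (ok) {
          vals[idx] = val;
          wt[idx] = 1.0;
        }
      }
    }
  }
  return List::create(_["values"] = vals, _["weight"] = wt);
}

// Weighted back-projection of canonical-frame segments (in-plane
// rotation and shifts already removed, r-weighting already applied).
// imgs: n x n x S array; phi/theta: per-segment degrees.
// [[Rcpp::export]]
List backproject_cpp(NumericVector imgs, NumericVector phi_deg,
                     NumericVector theta_deg, IntegerVector voldim) {
  IntegerVector d = imgs.attr("dim");
  int nr = d[0], ncol = d[1];
  int S = d[2];
  int nx = voldim[0], ny = voldim[1], nz = voldim[2];
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  double cr = (nr - 1) / 2.0, cc = (ncol - 1) / 2.0;
  NumericVector acc((size_t)nx * ny * nz), wt((size_t)nx * ny * nz);
  acc.attr("dim") = voldim;
  wt.attr("dim") = voldim;
  for (int s = 0; s < S; s++) {
    const double* img = imgs.begin() + (size_t)s * nr * ncol;
    double cp = std::cos(phi_deg[s] * DEG), sp = std::sin(phi_deg[s] * DEG);
    double ct = std::cos(theta_deg[s] * DEG), st = std::sin(theta_deg[s] * DEG);
    size_t idx = 0;
    for (int k = 0; k < nz; k++) {
      double Z = k - cz;
      for (int j = 0; j < ny; j++) {
        double Y = j - cy;
        for (int i = 0; i < nx; i++, idx++) {
          double X = i - cx;
          // u = Rx(theta) * Rz(phi) * p ; image coords are (u.x, u.z)
          double x1 = cp * X - sp * Y;
          double y1 = sp * X + cp * Y;
          double z1 = Z;
          double y2 = ct * y1 - st * z1;
          double z2 = st * y1 + ct * z1;
          (void)y2;
          bool ok;
          double val = bi_sample(img, nr, ncol, x1 + cr, z2 + cc, ok);
          if (ok) {
            acc[idx] += val;
            wt[idx] += 1.0;
          }
        }
      }
    }
  }
  return List::create(_["sum"] = acc, _["weight"] = wt);
}
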