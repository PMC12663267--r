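// Ray-marching kernels: terrain horizon scan and canopy thickness scan.
//
// Grids are R matrices in column-major storage with row 1 = northernmost
// row; (xmin, ymax) is the outer corner of the top-left cell. Elevation is
// sampled bilinearly between cell centres (constant extrapolation within
// the outer half-cell margin); canopy height and foliage density use
// nearest-cell lookup so that a 1 m CHM cell acts as a vertical column.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  const double* v;
  int ny, nx;
  double res, xmin, ymax;

  Grid(const NumericMatrix& m, double res_, double xmin_, double ymax_)
      : v(&m[0]), ny(m.nrow()), nx(m.ncol()), res(res_), xmin(xmin_),
        ymax(ymax_) {}

  bool contains(double x, double y) const {
    return x >= xmin && x <= xmin + nx * res && y <= ymax &&
           y >= ymax - ny * res;
  }

  double nearest(double x, double y) const {
    int c = (int)std::floor((x - xmin) / res);
    int r = (int)std::floor((ymax - y) / res);
    if (c < 0 || c >= nx || r < 0 || r >= ny) return NA_REAL;
    return v[r + (size_t)c * ny];
  }

  double bilinear(double x, double y) const {
    double u = (x - xmin) / res - 0.5;
    double w = (ymax - y) / res - 0.5;
    int c0 = (int)std::floor(u), r0 = (int)std::floor(w);
    double fu = u - c0, fw = w - r0;
    if (c0 < -1 || c0 > nx - 1 || r0 < -1 || r0 > ny - 1) return NA_REAL;
    int c1 = c0 + 1, r1 = r0 + 1;
    if (c0 < 0) c0 = 0;
    if (r0 < 0) r0 = 0;
    if (c1 > nx - 1) c1 = nx - 1;
    if (r1 > ny - 1) r1 = ny - 1;
    double z00 = v[r0 + (size_t)c0 * ny], z01 = v[r0 + (size_t)c1 * ny];
    double z10 = v[r1 + (size_t)c0 * ny], z11 = v[r1 + (size_t)c1 * ny];
    double top = z00 + fu * (z01 - z00);
    double bot = z10 + fu * (z11 - z10);
    return top + fw * (bot - top);
  }
};

const double DEG = M_PI / 180.0;

}  // namespace

// Per-azimuth maximum terrain elevation angle (degrees) out to `radius`.
// Nodata samples are skipped; an azimuth with no valid sample yields NA.
// [[Rcpp::export]]
NumericVector horizon_scan_cpp(NumericMatrix z, double res, double xmin,
                               double ymax, double px, double py, double zv,
                               double radius, int naz, double step) {
  Grid g(z, res, xmin, ymax);
  NumericVector out(naz);
  for (int a = 0; a < naz; ++a) {
    double az = (a + 0.5) * (360.0 / naz) * DEG;
    double dx = std::sin(az), dy = std::cos(az);
    double best = NA_REAL;
    bool seen = false;
    for (double d = step; d <= radius + 1e-9; d += step) {
      double zs = g.bilinear(px + d * dx, py + d * dy);
      if (ISNAN(zs)) continue;
      double ang = std::atan2(zs - zv, d) / DEG;
      if (!seen || ang > best) {
        best = ang;
        seen = true;
      }
    }
    out[a] = seen ? best : NA_REAL;
  }
  return out;
}

// Canopy thickness scan. For every (zenith, azimuth) direction the ray is
// marched in 3-D at `step` metres; the returned `l` accumulates the length
// spent inside canopy (ground <= h <= ground + chm), and one `laml` matrix
// per foliage-density grid accumulates sum(lambda * l). `top` is the
// canopy-top elevation angle per azimuth (NA where no canopy intersects).
// [[Rcpp::export]]
List canopy_scan_cpp(NumericMatrix dtm, double dres, double dxmin,
                     double dymax, NumericMatrix chm, double cres,
                     double cxmin, double cymax, List lambdas, double px,
                     double py, double zv, int nzen, int naz, double step,
                     double max_range, double max_surf) {
  Grid gd(dtm, dres, dxmin, dymax);
  Grid gc(chm, cres, cxmin, cymax);
  int nlam = lambdas.size();
  std::vector<Grid> gl;
  std::vector<NumericMatrix> lam_mats;
  for (int k = 0; k < nlam; ++k) {
    lam_mats.push_back(as<NumericMatrix>(lambdas[k]));
    gl.emplace_back(lam_mats[k], cres, cxmin, cymax);
  }
  NumericMatrix l(nzen, naz);
  List laml_out(nlam);
  std::vector<NumericMatrix> laml;
  for (int k = 0; k < nlam; ++k) laml.push_back(NumericMatrix(nzen, naz));
  NumericVector top(naz);

  double zstep = 90.0 / nzen;
  for (int a = 0; a < naz; ++a) {
    double az = (a + 0.5) * (360.0 / naz) * DEG;
    double dx = std::sin(az), dy = std::cos(az);

    // top-of-canopy elevation angle along this azimuth
    double best_top = NA_REAL;
    bool seen_top = false;
    for (double d = step; d <= max_range + 1e-9; d += step) {
      double hx = px + d * dx, hy = py + d * dy;
      if (!gd.contains(hx, hy) && !gc.contains(hx, hy)) break;
      double ch = gc.nearest(hx, hy);
      if (ISNAN(ch) || ch <= 0) continue;
      double gz = gd.bilinear(hx, hy);
      if (ISNAN(gz)) continue;
      double ang = std::atan2(gz + ch - zv, d) / DEG;
      if (!seen_top || ang > best_top) {
        best_top = ang;
        seen_top = true;
      }
    }
    top[a] = seen_top ? best_top : NA_REAL;

    for (int zi = 0; zi < nzen; ++zi) {
      double t = (zi + 0.5) * zstep * DEG;  // zenith angle
      double sinT = std::sin(t), cosT = std::cos(t);
      double acc = 0.0;
      std::vector<double> accl(nlam, 0.0);
      for (double s = step * 0.5; s <= max_range; s += step) {
        double h = zv + s * cosT;
        if (h > max_surf) break;
        double hx = px + s * sinT * dx, hy = py + s * sinT * dy;
        if (!gd.contains(hx, hy) && !gc.contains(hx, hy)) break;
        double ch = gc.nearest(hx, hy);
        if (ISNAN(ch) || ch <= 0) continue;
        double gz = gd.bilinear(hx, hy);
        if (ISNAN(gz)) continue;
        if (h >= gz && h <= gz + ch) {
          acc += step;
          for (int k = 0; k < nlam; ++k) {
            double lv = gl[k].nearest(hx, hy);
            if (!ISNAN(lv)) accl[k] += lv * step;
          }
        }
      }
      l(zi, a) = acc;
      for (int k = 0; k < nlam; ++k) laml[k](zi, a) = accl[k];
    }
  }
  for (int k = 0; k < nlam; ++k) laml_out[k] = laml[k];
  return List::create(_["l"] = l, _["laml"] = laml_out, _["top"] = top);
}
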