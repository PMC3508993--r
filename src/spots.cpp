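#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Images follow the [x, y] convention (nrow = nx): element (ix, iy), 1-based
// in R, covers the pixel [ix-1, ix) x [iy-1, iy) in pixel units, so its
// center is (ix - 0.5, iy - 0.5). All positions passed in and out of these
// routines are in that pixel-center coordinate system.

static inline long long cell_key(int cx, int cy) {
  return (static_cast<long long>(cx) << 32) ^
         static_cast<long long>(static_cast<unsigned int>(cy));
}

// Matern-II dependent thinning: candidate i survives unless some other
// candidate within distance r carries a smaller mark (ties broken by index).
// Comparison is against all candidates, kept or not, which is what makes the
// retained intensity analytically invertible.
// [[Rcpp::export]]
LogicalVector cpp_matern2_keep(NumericVector x, NumericVector y,
                               NumericVector mark, double r) {
  int n = x.size();
  LogicalVector keep(n, true);
  if (r <= 0 || n == 0) return keep;
  double r2 = r * r;
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(n * 2);
  std::vector<int> cx(n), cy(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)std::floor(x[i] / r);
    cy[i] = (int)std::floor(y[i] / r);
    grid[cell_key(cx[i], cy[i])].push_back(i);
  }
  for (int i = 0; i < n; ++i) {
    bool killed = false;
    for (int dx = -1; dx <= 1 && !killed; ++dx) {
      for (int dy = -1; dy <= 1 && !killed; ++dy) {
        std::unordered_map<long long, std::vector<int> >::iterator it =
            grid.find(cell_key(cx[i] + dx, cy[i] + dy));
        if (it == grid.end()) continue;
        const std::vector<int>& cell = it->second;
        for (size_t k = 0; k < cell.size(); ++k) {
          int j = cell[k];
          if (j == i) continue;
          double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (ddx * ddx + ddy * ddy >= r2) continue;
          if (mark[j] < mark[i] || (mark[j] == mark[i] && j < i)) {
            killed = true;
            break;
          }
        }
      }
    }
    if (killed) keep[i] = false;
  }
  return keep;
}

// Render isotropic Gaussian spots (peak amplitude amp, s.d. sigma, pixels)
// onto an nx x ny raster by direct evaluation, truncated at 5 sigma.
// [[Rcpp::export]]
NumericMatrix cpp_render_spots(NumericVector px, NumericVector py,
                               double sigma, double amp, int nx, int ny) {
  NumericMatrix out(nx, ny);
  int n = px.size();
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  int w = (int)std::ceil(5.0 * sigma);
  for (int s = 0; s < n; ++s) {
    double x0 = px[s], y0 = py[s];
    int ix0 = (int)std::floor(x0);
    int iy0 = (int)std::floor(y0);
    int xlo = std::max(0, ix0 - w), xhi = std::min(nx - 1, ix0 + w);
    int ylo = std::max(0, iy0 - w), yhi = std::min(ny - 1, iy0 + w);
    for (int iy = ylo; iy <= yhi; ++iy) {
      double dy = (iy + 0.5) - y0;
      for (int ix = xlo; ix <= xhi; ++ix) {
        double dx = (ix + 0.5) - x0;
        out(ix, iy) += amp * std::exp(-(dx * dx + dy * dy) * inv2s2);
      }
    }
  }
  return out;
}

static inline double parabolic_offset(double fl, double f0, double fr) {
  double denom = fl - 2.0 * f0 + fr;
  if (denom >= 0) return 0.0;  // not a proper maximum
  double d = 0.5 * (fl - fr) / denom;
  if (d > 1.0) d = 1.0;
  if (d < -1.0) d = -1.0;
  return d;
}

// Greedy template subtraction (CLEAN-style matching pursuit): repeatedly find
// the residual maximum, refine it to sub-pixel by parabolic interpolation,
// subtract one unit template (Gaussian, s.d. sigma, peak amp), and record
// the position. Stops when the residual maximum falls below `stop`. The
// template amplitude is fixed, so the number of subtractions is
// flux-quantized: two spots merged into a single maximum are still counted
// twice because the first subtraction leaves one template's worth of signal
// behind. `flat` is subtracted uniformly from the whole residual at each
// iteration (tracked as a scalar offset); with flat = template flux /
// n_pixels this makes cleaning exact on mean-subtracted images, so no
// background estimate is needed.
// [[Rcpp::export]]
List cpp_clean_detect(NumericMatrix img, double sigma, double amp,
                      double flat, double stop, int max_iter) {
  int nx = img.nrow(), ny = img.ncol();
  NumericMatrix res = clone(img);
  double offset = 0.0;  // accumulated uniform subtraction
  std::vector<double> colmax(ny);
  std::vector<int> colarg(ny);
  for (int iy = 0; iy < ny; ++iy) {
    double m = res(0, iy);
    int a = 0;
    for (int ix = 1; ix < nx; ++ix)
      if (res(ix, iy) > m) { m = res(ix, iy); a = ix; }
    colmax[iy] = m;
    colarg[iy] = a;
  }
  std::vector<double> ox, oy, opk;
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  int w = (int)std::ceil(4.0 * sigma);
  for (int iter = 0; iter < max_iter; ++iter) {
    int by = 0;
    for (int iy = 1; iy < ny; ++iy)
      if (colmax[iy] > colmax[by]) by = iy;
    int bx = colarg[by];
    double pk = colmax[by] + offset;
    if (pk < stop) break;
    double pkraw = res(bx, by);
    double fl, fr;
    fl = (bx > 0) ? res(bx - 1, by) : pkraw;
    fr = (bx < nx - 1) ? res(bx + 1, by) : pkraw;
    double dx = parabolic_offset(fl, pkraw, fr);
    fl = (by > 0) ? res(bx, by - 1) : pkraw;
    fr = (by < ny - 1) ? res(bx, by + 1) : pkraw;
    double dy = parabolic_offset(fl, pkraw, fr);
    double x0 = bx + 0.5 + dx, y0 = by + 0.5 + dy;
    int xlo = std::max(0, bx - w), xhi = std::min(nx - 1, bx + w);
    int ylo = std::max(0, by - w), yhi = std::min(ny - 1, by + w);
    for (int iy = ylo; iy <= yhi; ++iy) {
      double ddy = (iy + 0.5) - y0;
      for (int ix = xlo; ix <= xhi; ++ix) {
        double ddx = (ix + 0.5) - x0;
        res(ix, iy) -= amp * std::exp(-(ddx * ddx + ddy * ddy) * inv2s2);
      }
    }
    offset += flat;
    for (int iy = ylo; iy <= yhi; ++iy) {
      double m = res(0, iy);
      int a = 0;
      for (int ix = 1; ix < nx; ++ix)
        if (res(ix, iy) > m) { m = res(ix, iy); a = ix; }
      colmax[iy] = m;
      colarg[iy] = a;
    }
    ox.push_back(x0);
    oy.push_back(y0);
    opk.push_back(pk);
  }
  return List::create(_["x"] = wrap(ox), _["y"] = wrap(oy),
                      _["peak"] = wrap(opk));
}

// Strict local maxima within a Chebyshev radius, at or above `thresh`.
// Plateau ties are broken by linear index so a flat top yields one maximum.
// [[Rcpp::export]]
List cpp_local_maxima(NumericMatrix img, double thresh, int radius) {
  int nx = img.nrow(), ny = img.ncol();
  std::vector<double> ox, oy, ov;
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) {
      double v = img(ix, iy);
      if (v < thresh) continue;
      bool ismax = true;
      long lin = ix + (long)iy * nx;
      for (int dy = -radius; dy <= radius && ismax; ++dy) {
        int jy = iy + dy;
        if (jy < 0 || jy >= ny) continue;
        for (int dx = -radius; dx <= radius; ++dx) {
          int jx = ix + dx;
          if (jx < 0 || jx >= nx || (dx == 0 && dy == 0)) continue;
          double u = img(jx, jy);
          long lin2 = jx + (long)jy * nx;
          if (u > v || (u == v && lin2 < lin)) { ismax = false; break; }
        }
      }
      if (ismax) {
        ox.push_back(ix + 0.5);
        oy.push_back(iy + 0.5);
        ov.push_back(v);
      }
    }
  }
  return List::create(_["x"] = wrap(ox), _["y"] = wrap(oy),
                      _["value"] = wrap(ov));
}

static void run_min_1d(const std::vector<double>& in, std::vector<double>& out,
                       int n, int r, bool take_min) {
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - r), hi = std::min(n - 1, i + r);
    double m = in[lo];
    for (int j = lo + 1; j <= hi; ++j)
      m = take_min ? std::min(m, in[j]) : std::max(m, in[j]);
    out[i] = m;
  }
}

static NumericMatrix box_filter(NumericMatrix img, int radius, bool take_min) {
  int nx = img.nrow(), ny = img.ncol();
  NumericMatrix tmp(nx, ny), out(nx, ny);
  std::vector<double> buf(std::max(nx, ny)), res(std::max(nx, ny));
  for (int iy = 0; iy < ny; ++iy) {
    for (int ix = 0; ix < nx; ++ix) buf[ix] = img(ix, iy);
    run_min_1d(buf, res, nx, radius, take_min);
    for (int ix = 0; ix < nx; ++ix) tmp(ix, iy) = res[ix];
  }
  for (int ix = 0; ix < nx; ++ix) {
    for (int iy = 0; iy < ny; ++iy) buf[iy] = tmp(ix, iy);
    run_min_1d(buf, res, ny, radius, take_min);
    for (int iy = 0; iy < ny; ++iy) out(ix, iy) = res[iy];
  }
  return out;
}

// Grey-scale opening with a (2r+1)^2 square structuring element:
// erosion (running min) followed by dilation (running max). Used as a
// rolling-ball-style background estimator on montages.
// [[Rcpp::export]]
NumericMatrix cpp_box_open(NumericMatrix img, int radius) {
  NumericMatrix er = box_filter(img, radius, true);
  return box_filter(er, radius, false);
}
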