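// Siddon ray tracing: exact pixel-intersection lengths of straight rays on a
// regular grid. Pixel (i, j) (1-based, row-major meaning row i ~ y, col j ~ x)
// is the square centred at (x0 + (j-1) h, y0 + (i-1) h) with side h.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".siddon_rays_cpp")]]
List siddon_rays_cpp(NumericMatrix p0, NumericMatrix p1,
                     double x0, double y0, double h, int m, int n) {
  const int nray = p0.nrow();
  std::vector<int> out_ray, out_pix;
  std::vector<double> out_len;
  out_ray.reserve(nray * (m + n));
  out_pix.reserve(nray * (m + n));
  out_len.reserve(nray * (m + n));

  const double xmin = x0 - 0.5 * h, xmax = x0 + (n - 0.5) * h;
  const double ymin = y0 - 0.5 * h, ymax = y0 + (m - 0.5) * h;

  for (int r = 0; r < nray; ++r) {
    const double ax = p0(r, 0), ay = p0(r, 1);
    const double dx = p1(r, 0) - ax, dy = p1(r, 1) - ay;
    const double L = std::sqrt(dx * dx + dy * dy);
    if (L == 0.0) continue;

    // clip the parametric interval [0,1] to the grid box
    double t_lo = 0.0, t_hi = 1.0;
    bool ok = true;
    if (dx != 0.0) {
      double t1 = (xmin - ax) / dx, t2 = (xmax - ax) / dx;
      if (t1 > t2) std::swap(t1, t2);
      t_lo = std::max(t_lo, t1); t_hi = std::min(t_hi, t2);
    } else if (ax < xmin || ax > xmax) ok = false;
    if (dy != 0.0) {
      double t1 = (ymin - ay) / dy, t2 = (ymax - ay) / dy;
      if (t1 > t2) std::swap(t1, t2);
      t_lo = std::max(t_lo, t1); t_hi = std::min(t_hi, t2);
    } else if (ay < ymin || ay > ymax) ok = false;
    if (!ok || t_lo >= t_hi) continue;

    std::vector<double> alphas;
    alphas.push_back(t_lo);
    alphas.push_back(t_hi);
    if (dx != 0.0) {
      for (int k = 0; k <= n; ++k) {
        double t = (xmin + k * h - ax) / dx;
        if (t > t_lo && t < t_hi) alphas.push_back(t);
      }
    }
    if (dy != 0.0) {
      for (int k = 0; k <= m; ++k) {
        double t = (ymin + k * h - ay) / dy;
        if (t > t_lo && t < t_hi) alphas.push_back(t);
      }
    }
    std::sort(alphas.begin(), alphas.end());

    for (size_t s = 0; s + 1 < alphas.size(); ++s) {
      double da = alphas[s + 1] - alphas[s];
      if (da <= 0.0) continue;
      double tm = 0.5 * (alphas[s] + alphas[s + 1]);
      double xm = ax + tm * dx, ym = ay + tm * dy;
      int j = (int)std::floor((xm - xmin) / h);
      int i = (int)std::floor((ym - ymin) / h);
      if (i < 0) i = 0; if (i >= m) i = m - 1;
      if (j < 0) j = 0; if (j >= n) j = n - 1;
      out_ray.push_back(r + 1);
      out_pix.push_back(j * m + i + 1);   // column-major linear index
      out_len.push_back(da * L);
    }
  }
  return List::create(_["ray"] = wrap(out_ray),
                      _["pixel"] = wrap(out_pix),
                      _["length"] = wrap(out_len));
}
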