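#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Weighted zero-mean normalized cross-correlation of a DR window against a
// DRR sampled at a set of candidate offsets.
//
// All coordinates here are 0-based; the R wrappers convert.  Matrices are
// indexed (row, col) = (y, x).  `valid` flags usable DR pixels (collimated
// pixels are false).  The window is the inclusive box [x0,x1] x [y0,y1].
// For each candidate offset d = (dx[k], dy[k]) the DRR is sampled at p + d
// (bilinear for fractional d); window pixels whose sample would fall outside
// the DRR are excluded from the sums, as are invalid DR pixels.  Intensities
// on both sides are multiplied by the Gaussian weight w(p + d) centered on
// the isocenter (sigma <= 0 or non-finite selects the uniform weight w = 1);
// the weight is separable, so the two 1-D factors are precomputed per
// candidate.  Candidates with fewer than min_valid contributing pixels or
// with zero variance on either side are returned as NA ("undefined
// correlation").
//
// Returns a k x 2 matrix: column 0 the correlation, column 1 the number of
// contributing pixels.
// [[Rcpp::export]]
NumericMatrix zncc_scan_cpp(const NumericMatrix& drr, const NumericMatrix& dr,
                            const LogicalMatrix& valid,
                            const NumericVector& dx, const NumericVector& dy,
                            double icx, double icy, double sigma,
                            int x0, int x1, int y0, int y1, int min_valid) {
  const int H = drr.nrow(), W = drr.ncol();
  if (dr.nrow() != H || dr.ncol() != W)
    stop("DR and DRR dimensions differ");
  if (valid.nrow() != H || valid.ncol() != W)
    stop("valid mask dimensions differ from images");
  if (x0 < 0 || y0 < 0 || x1 >= W || y1 >= H || x0 > x1 || y0 > y1)
    stop("window out of bounds");

  const int k = dx.size();
  const int wx_n = x1 - x0 + 1, wy_n = y1 - y0 + 1;
  const bool uniform = !std::isfinite(sigma) || sigma <= 0.0;
  const double inv2s2 = uniform ? 0.0 : 1.0 / (2.0 * sigma * sigma);
  const double eps = 1e-12;

  NumericMatrix out(k, 2);
  std::vector<double> wxv(wx_n), wyv(wy_n);

  for (int c = 0; c < k; ++c) {
    const double dxc = dx[c], dyc = dy[c];

    if (uniform) {
      std::fill(wxv.begin(), wxv.end(), 1.0);
      std::fill(wyv.begin(), wyv.end(), 1.0);
    } else {
      for (int i = 0; i < wx_n; ++i) {
        const double t = icx - (x0 + i) - dxc;
        wxv[i] = std::exp(-t * t * inv2s2);
      }
      for (int i = 0; i < wy_n; ++i) {
        const double t = icy - (y0 + i) - dyc;
        wyv[i] = std::exp(-t * t * inv2s2);
      }
    }

    // constant fractional part across the window: resolve corners once
    const double fx = dxc - std::floor(dxc), fy = dyc - std::floor(dyc);
    const int idx = (int)std::floor(dxc), idy = (int)std::floor(dyc);
    const bool frac_x = fx > 1e-12, frac_y = fy > 1e-12;
    const double c00 = (1 - fx) * (1 - fy), c10 = fx * (1 - fy),
                 c01 = (1 - fx) * fy,       c11 = fx * fy;

    long n = 0;
    double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;

    for (int y = y0; y <= y1; ++y) {
      const int sy = y + idy;
      if (sy < 0 || sy > H - 1 - (frac_y ? 1 : 0)) continue;
      const double wy = wyv[y - y0];
      for (int x = x0; x <= x1; ++x) {
        if (!valid(y, x)) continue;
        const int sx = x + idx;
        if (sx < 0 || sx > W - 1 - (frac_x ? 1 : 0)) continue;
        double a = drr(sy, sx);
        if (frac_x || frac_y) {
          const double a00 = a;
          const double a10 = frac_x ? drr(sy, sx + 1) : a00;
          const double a01 = frac_y ? drr(sy + 1, sx) : a00;
          const double a11 = (frac_x && frac_y) ? drr(sy + 1, sx + 1)
                             : (frac_x ? a10 : a01);
          a = c00 * a00 + c10 * a10 + c01 * a01 + c11 * a11;
        }
        const double w = wxv[x - x0] * wy;
        const double A = a * w;
        const double B = dr(y, x) * w;
        ++n;
        sa += A; sb += B;
        saa += A * A; sbb += B * B; sab += A * B;
      }
    }

    out(c, 1) = (double)n;
    if (n < min_valid) { out(c, 0) = NA_REAL; continue; }
    const double va = saa - sa * sa / n;
    const double vb = sbb - sb * sb / n;
    if (va <= eps || vb <= eps) { out(c, 0) = NA_REAL; continue; }
    double r = (sab - sa * sb / n) / std::sqrt(va * vb);
    if (r > 1.0) r = 1.0;
    if (r < -1.0) r = -1.0;
    out(c, 0) = r;
  }
  return out;
}
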