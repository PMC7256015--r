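// Parallel-beam projection and back-projection kernels.
//
// Conventions (voxel units, 0-based): grid centre c0 = (n-1)/2; detector j
// sits at t_j = (j - (nd-1)/2) * pitch along the direction (cos a, sin a);
// the ray direction is (-sin a, cos a). Forward projection samples the image
// bilinearly along the ray (rotate-and-sum equivalent); back-projection is
// pixel-driven with linear interpolation between detector samples.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double bilinear(const NumericMatrix& img, double row, double col) {
  const int n1 = img.nrow() - 1, n2 = img.ncol() - 1;
  if (row < 0.0 || col < 0.0 || row > n1 || col > n2) return 0.0;
  int r0 = (int)std::floor(row), c0 = (int)std::floor(col);
  if (r0 >= n1) r0 = n1 - 1;
  if (c0 >= n2) c0 = n2 - 1;
  const double fr = row - r0, fc = col - c0;
  return (1 - fr) * (1 - fc) * img(r0, c0) +
         (1 - fr) * fc       * img(r0, c0 + 1) +
         fr       * (1 - fc) * img(r0 + 1, c0) +
         fr       * fc       * img(r0 + 1, c0 + 1);
}

// [[Rcpp::export]]
NumericMatrix cpp_forward_project(const NumericMatrix& img,
                                  const NumericVector& angles,
                                  const int n_det,
                                  const double pitch_vox,
                                  const double step_vox) {
  const int n = img.nrow();
  const double c0 = (n - 1) / 2.0;
  const double t0 = (n_det - 1) / 2.0;
  const double smax = 0.75 * n;        // covers the grid diagonal
  const int nstep = (int)std::ceil(2.0 * smax / step_vox) + 1;
  NumericMatrix out(angles.size(), n_det);
  for (int ia = 0; ia < angles.size(); ++ia) {
    const double ca = std::cos(angles[ia]), sa = std::sin(angles[ia]);
    for (int j = 0; j < n_det; ++j) {
      const double t = (j - t0) * pitch_vox;
      double acc = 0.0;
      for (int k = 0; k < nstep; ++k) {
        const double s = -smax + k * step_vox;
        const double x = t * ca - s * sa;   // column direction
        const double y = t * sa + s * ca;   // row direction
        acc += bilinear(img, y + c0, x + c0);
      }
      out(ia, j) = acc * step_vox;          // line integral in voxel lengths
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_back_project(const NumericMatrix& filt,
                               const NumericVector& angles,
                               const int n,
                               const double pitch_vox) {
  const int n_det = filt.ncol();
  const double c0 = (n - 1) / 2.0;
  const double t0 = (n_det - 1) / 2.0;
  NumericMatrix img(n, n);
  for (int ia = 0; ia < angles.size(); ++ia) {
    const double ca = std::cos(angles[ia]), sa = std::sin(angles[ia]);
    for (int r = 0; r < n; ++r) {
      const double y = r - c0;
      for (int c = 0; c < n; ++c) {
        const double x = c - c0;
        const double u = (x * ca + y * sa) / pitch_vox + t0;
        if (u < 0.0 || u > n_det - 1) continue;
        int u0 = (int)std::floor(u);
        if (u0 >= n_det - 1) u0 = n_det - 2;
        const double fu = u - u0;
        img(r, c) += (1 - fu) * filt(ia, u0) + fu * filt(ia, u0 + 1);
      }
    }
  }
  const double w = M_PI / angles.size();
  for (int r = 0; r < n; ++r)
    for (int c = 0; c < n; ++c) img(r, c) *= w;
  return img;
}

// Back-project only selected pixels (rows/cols 0-based). Identical formula
// to cpp_back_project at those pixels; used by the detection-limit scan.
// [[Rcpp::export]]
NumericVector cpp_back_project_pixels(const NumericMatrix& filt,
                                      const NumericVector& angles,
                                      const int n,
                                      const double pitch_vox,
                                      const IntegerVector& rows,
                                      const IntegerVector& cols) {
  const int n_det = filt.ncol();
  const double c0 = (n - 1) / 2.0;
  const double t0 = (n_det - 1) / 2.0;
  const double w = M_PI / angles.size();
  NumericVector out(rows.size());
  for (int p = 0; p < rows.size(); ++p) {
    const double y = rows[p] - c0, x = cols[p] - c0;
    double acc = 0.0;
    for (int ia = 0; ia < angles.size(); ++ia) {
      const double ca = std::cos(angles[ia]), sa = std::sin(angles[ia]);
      const double u = (x * ca + y * sa) / pitch_vox + t0;
      if (u < 0.0 || u > n_det - 1) continue;
      int u0 = (int)std::floor(u);
      if (u0 >= n_det - 1) u0 = n_det - 2;
      const double fu = u - u0;
      acc += (1 - fu) * filt(ia, u0) + fu * filt(ia, u0 + 1);
    }
    out[p] = acc * w;
  }
  return out;
}
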