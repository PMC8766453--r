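#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Discrete parallel-beam projector pair and a pixel-driven backprojector.
//
// Conventions (shared with the R level):
//   image: n x n, pixel (r, c) centered at x = -1 + (c + 0.5) * ps,
//          y = -1 + (r + 0.5) * ps, ps = 2 / n
//   detector: column j senses signed offset s_j = (j + 0.5 - n_cols / 2) * det_ps
//   ray(theta, s): { s * (cos t, sin t) + u * (-sin t, cos t) }
//
// The forward operator samples the image by bilinear interpolation at unit
// pixel steps along each ray and multiplies by the step length; the adjoint
// scatters with the same weights, so <Ax, y> == <x, A^T y> holds to rounding.

static inline void bilin_weights(double x, double y, int n, double ps,
                                 int idx[4], double w[4], int& cnt) {
  // continuous pixel coordinates
  const double fc = (x + 1.0) / ps - 0.5;
  const double fr = (y + 1.0) / ps - 0.5;
  const int c0 = (int)std::floor(fc), r0 = (int)std::floor(fr);
  const double ac = fc - c0, ar = fr - r0;
  cnt = 0;
  const double ww[4] = { (1 - ar) * (1 - ac), ar * (1 - ac), (1 - ar) * ac, ar * ac };
  const int rr[4] = { r0, r0 + 1, r0, r0 + 1 };
  const int cc[4] = { c0, c0, c0 + 1, c0 + 1 };
  for (int k = 0; k < 4; ++k) {
    if (rr[k] >= 0 && rr[k] < n && cc[k] >= 0 && cc[k] < n && ww[k] != 0.0) {
      idx[cnt] = rr[k] + n * cc[k];
      w[cnt] = ww[k];
      ++cnt;
    }
  }
}

// [[Rcpp::export]]
NumericMatrix radon_forward_cpp(NumericMatrix img, NumericVector angles,
                                int n_cols, double det_ps) {
  const int n = img.nrow();
  const double ps = 2.0 / n;
  const int na = angles.size();
  NumericMatrix sino(na, n_cols);
  const double tmax = std::sqrt(2.0);
  const int nstep = (int)std::ceil(2.0 * tmax / ps);
  const double* im = REAL(img);
  int idx[4]; double w[4]; int cnt;
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int j = 0; j < n_cols; ++j) {
      const double s = (j + 0.5 - n_cols / 2.0) * det_ps;
      double acc = 0.0;
      for (int k = 0; k < nstep; ++k) {
        const double u = -tmax + (k + 0.5) * (2.0 * tmax / nstep);
        const double x = s * ct - u * st;
        const double y = s * st + u * ct;
        bilin_weights(x, y, n, ps, idx, w, cnt);
        for (int q = 0; q < cnt; ++q) acc += w[q] * im[idx[q]];
      }
      sino(a, j) = acc * (2.0 * tmax / nstep);
    }
  }
  return sino;
}

// [[Rcpp::export]]
NumericMatrix radon_adjoint_cpp(NumericMatrix sino, NumericVector angles,
                                int n, double det_ps) {
  const double ps = 2.0 / n;
  const int na = angles.size();
  const int n_cols = sino.ncol();
  NumericMatrix img(n, n);
  double* im = REAL(img);
  const double tmax = std::sqrt(2.0);
  const int nstep = (int)std::ceil(2.0 * tmax / ps);
  int idx[4]; double w[4]; int cnt;
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int j = 0; j < n_cols; ++j) {
      const double v = sino(a, j) * (2.0 * tmax / nstep);
      if (v == 0.0) continue;
      const double s = (j + 0.5 - n_cols / 2.0) * det_ps;
      for (int k = 0; k < nstep; ++k) {
        const double u = -tmax + (k + 0.5) * (2.0 * tmax / nstep);
        const double x = s * ct - u * st;
        const double y = s * st + u * ct;
        bilin_weights(x, y, n, ps, idx, w, cnt);
        for (int q = 0; q < cnt; ++q) im[idx[q]] += w[q] * v;
      }
    }
  }
  return img;
}

// [[Rcpp::export]]
NumericMatrix backproject_cpp(NumericMatrix filtered, NumericVector angles,
                              int n, double det_ps) {
  // pixel-driven backprojection with linear interpolation along the detector
  const double ps = 2.0 / n;
  const int na = angles.size();
  const int n_cols = filtered.ncol();
  NumericMatrix img(n, n);
  double* im = REAL(img);
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    const double* row = REAL(filtered) + a;  // row a, stride = na
    for (int c = 0; c < n; ++c) {
      const double x = -1.0 + (c + 0.5) * ps;
      double* col = im + (size_t)c * n;
      for (int r = 0; r < n; ++r) {
        const double y = -1.0 + (r + 0.5) * ps;
        const double s = x * ct + y * st;
        const double fj = s / det_ps + n_cols / 2.0 - 0.5;
        const int j0 = (int)std::floor(fj);
        const double aj = fj - j0;
        double v = 0.0;
        if (j0 >= 0 && j0 < n_cols) v += (1.0 - aj) * row[(size_t)j0 * na];
        if (j0 + 1 >= 0 && j0 + 1 < n_cols) v += aj * row[(size_t)(j0 + 1) * na];
        col[r] += v;
      }
    }
  }
  return img;
}
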