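#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Mixed-Scale Dense network primitives.
//
// Images are H x W doubles in R's column-major layout. The network has one
// channel per layer: channel 0 is the input image, channels 1..L are the layer
// outputs. Layer i applies one dilated 3x3 kernel to every existing channel
// (0..i-1), adds a scalar bias and a ReLU. The final map is a 1x1 linear
// combination of all L+1 channels plus a scalar bias.
//
// Flat parameter layout (matches msd_unflatten_params() on the R side):
//   for i in 1..L:   9*i kernel entries (channel-major, each 3x3 column-major
//                    as k = kr + 3*kc), then 1 bias
//   then L+1 final weights (channels 0..L), then 1 final bias.

static inline void dil_conv_acc(const double* in, double* out, const double* K,
                                const int H, const int W, const int d) {
  // out += K (*) in, zero padding, dilation d
  for (int kc = 0; kc < 3; ++kc) {
    const int dc = (kc - 1) * d;
    for (int kr = 0; kr < 3; ++kr) {
      const int dr = (kr - 1) * d;
      const double w = K[kr + 3 * kc];
      if (w == 0.0) continue;
      const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
      const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      for (int c = c0; c < c1; ++c) {
        const double* icol = in + (size_t)(c + dc) * H + dr;
        double* ocol = out + (size_t)c * H;
        for (int r = r0; r < r1; ++r) ocol[r] += w * icol[r];
      }
    }
  }
}

static inline void dil_conv_acc_transpose(const double* g, double* gin,
                                          const double* K, const int H,
                                          const int W, const int d) {
  // gin += K (*)^T g : adjoint of dil_conv_acc w.r.t. the input image
  for (int kc = 0; kc < 3; ++kc) {
    const int dc = -(kc - 1) * d;
    for (int kr = 0; kr < 3; ++kr) {
      const int dr = -(kr - 1) * d;
      const double w = K[kr + 3 * kc];
      if (w == 0.0) continue;
      const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
      const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      for (int c = c0; c < c1; ++c) {
        const double* gcol = g + (size_t)(c + dc) * H + dr;
        double* ocol = gin + (size_t)c * H;
        for (int r = r0; r < r1; ++r) ocol[r] += w * gcol[r];
      }
    }
  }
}

static inline void dil_conv_wgrad(const double* ga, const double* in,
                                  double* gK, const int H, const int W,
                                  const int d) {
  // gK[kr,kc] += sum over valid pixels of ga(r,c) * in(r+dr, c+dc)
  for (int kc = 0; kc < 3; ++kc) {
    const int dc = (kc - 1) * d;
    for (int kr = 0; kr < 3; ++kr) {
      const int dr = (kr - 1) * d;
      const int c0 = std::max(0, -dc), c1 = std::min(W, W - dc);
      const int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
      double acc = 0.0;
      for (int c = c0; c < c1; ++c) {
        const double* icol = in + (size_t)(c + dc) * H + dr;
        const double* gcol = ga + (size_t)c * H;
        for (int r = r0; r < r1; ++r) acc += gcol[r] * icol[r];
      }
      gK[kr + 3 * kc] += acc;
    }
  }
}

static void msd_forward_stack(const double* x, const double* par,
                              const int H, const int W, const int L,
                              const IntegerVector& dil,
                              std::vector<double>& stack,   // (L+1) images
                              std::vector<double>& out) {
  const size_t npix = (size_t)H * W;
  std::copy(x, x + npix, stack.data());  // channel 0
  size_t off = 0;
  for (int i = 1; i <= L; ++i) {
    double* zi = stack.data() + (size_t)i * npix;
    const double b = par[off + 9 * (size_t)i];
    std::fill(zi, zi + npix, b);
    const int d = dil[(i - 1) % dil.size()];
    for (int c = 0; c < i; ++c)
      dil_conv_acc(stack.data() + (size_t)c * npix, zi, par + off + 9 * (size_t)c,
                   H, W, d);
    for (size_t p = 0; p < npix; ++p)
      if (zi[p] < 0.0) zi[p] = 0.0;
    off += 9 * (size_t)i + 1;
  }
  const double* wfin = par + off;
  const double bout = par[off + L + 1];
  out.assign(npix, bout);
  for (int c = 0; c <= L; ++c) {
    const double w = wfin[c];
    if (w == 0.0) continue;
    const double* zc = stack.data() + (size_t)c * npix;
    for (size_t p = 0; p < npix; ++p) out[p] += w * zc[p];
  }
}

// [[Rcpp::export]]
NumericMatrix msd_forward_cpp(NumericMatrix x, NumericVector params,
                              int depth, IntegerVector dilations) {
  const int H = x.nrow(), W = x.ncol();
  const size_t npix = (size_t)H * W;
  std::vector<double> stack((size_t)(depth + 1) * npix), out;
  msd_forward_stack(REAL(x), REAL(params), H, W, depth, dilations, stack, out);
  NumericMatrix res(H, W);
  std::copy(out.begin(), out.end(), REAL(res));
  return res;
}

// [[Rcpp::export]]
List msd_loss_grad_cpp(NumericMatrix x, NumericMatrix y, LogicalMatrix defined,
                       NumericVector params, int depth, IntegerVector dilations) {
  const int H = x.nrow(), W = x.ncol();
  const int L = depth;
  const size_t npix = (size_t)H * W;
  const double* par = REAL(params);

  std::vector<double> stack((size_t)(L + 1) * npix), out;
  msd_forward_stack(REAL(x), par, H, W, L, dilations, stack, out);

  // masked sum-of-squares loss and output gradient
  std::vector<double> g(npix, 0.0);
  double loss = 0.0;
  const int* def = LOGICAL(defined);
  const double* yv = REAL(y);
  long ndef = 0;
  for (size_t p = 0; p < npix; ++p) {
    if (def[p] == TRUE) {
      const double r = out[p] - yv[p];
      loss += r * r;
      g[p] = 2.0 * r;
      ++ndef;
    }
  }

  NumericVector grad(params.size());
  double* gpar = REAL(grad);

  // offsets of each layer's parameter block
  std::vector<size_t> loff(L + 1, 0);
  for (int i = 1; i <= L; ++i) loff[i] = loff[i - 1] + (i > 1 ? 9 * (size_t)(i - 1) + 1 : 0);
  // loff[i] = start of layer i block; recompute plainly:
  size_t off = 0;
  for (int i = 1; i <= L; ++i) { loff[i] = off; off += 9 * (size_t)i + 1; }
  const size_t fin_off = off;

  // final-map gradients and channel gradients
  std::vector<double> gz((size_t)(L + 1) * npix, 0.0);
  const double* wfin = par + fin_off;
  double gsum = 0.0;
  for (size_t p = 0; p < npix; ++p) gsum += g[p];
  gpar[fin_off + L + 1] = gsum;  // final bias
  for (int c = 0; c <= L; ++c) {
    const double* zc = stack.data() + (size_t)c * npix;
    double acc = 0.0;
    for (size_t p = 0; p < npix; ++p) acc += g[p] * zc[p];
    gpar[fin_off + c] = acc;
    if (wfin[c] != 0.0) {
      double* gzc = gz.data() + (size_t)c * npix;
      const double w = wfin[c];
      for (size_t p = 0; p < npix; ++p) gzc[p] += w * g[p];
    }
  }

  // backprop through layers
  std::vector<double> ga(npix);
  for (int i = L; i >= 1; --i) {
    const double* zi = stack.data() + (size_t)i * npix;
    const double* gzi = gz.data() + (size_t)i * npix;
    // ReLU: zi > 0 iff pre-activation > 0
    for (size_t p = 0; p < npix; ++p) ga[p] = (zi[p] > 0.0) ? gzi[p] : 0.0;
    const int d = dilations[(i - 1) % dilations.size()];
    double bacc = 0.0;
    for (size_t p = 0; p < npix; ++p) bacc += ga[p];
    gpar[loff[i] + 9 * (size_t)i] = bacc;
    for (int c = 0; c < i; ++c) {
      const double* zc = stack.data() + (size_t)c * npix;
      dil_conv_wgrad(ga.data(), zc, gpar + loff[i] + 9 * (size_t)c, H, W, d);
      dil_conv_acc_transpose(ga.data(), gz.data() + (size_t)c * npix,
                             par + loff[i] + 9 * (size_t)c, H, W, d);
    }
  }

  return List::create(_["loss"] = loss, _["grad"] = grad, _["n_defined"] = (double)ndef);
}
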