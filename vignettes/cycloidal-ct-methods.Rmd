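---
title: "Cycloidal CT simulation and in-scan learned sinogram completion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cycloidal CT simulation and in-scan learned sinogram completion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The imaging problem

In masked-beam micro-CT a mask with period $p$ and aperture width $w$
structures the x-ray beam into narrow beamlets, giving access to spatial
frequencies that the source focal spot and detector point spread function
would otherwise destroy. The price is undersampling: with $w : p$ typically
between 1:3 and 1:10, each projection measures only the fraction $w/p$ of
the detector columns. The classical remedy, *dithering*, steps the sample
laterally at every rotation angle until all column positions are covered —
a complete sinogram at $p/w$ times the frames and dose.

*Cycloidal* acquisition instead translates the sample continuously while it
rotates. Each angle measures one column-residue class of the mask period,
so the acquired entries of the sinogram form an interlaced two-dimensional
lattice rather than full rows. The sinogram is incomplete (fraction $w/p$
of entries measured, e.g. 1/8), but — unlike angular subsampling, which
discards whole projections — the missing information is spread evenly over
both sinogram axes, which is what makes restoration tractable.

This package simulates such acquisitions end to end and restores the
incomplete sinograms in two ways: bicubic interpolation, and a Mixed-Scale
Dense (MS-D) convolutional network trained *in-scan* — the training data
are a handful of dithered projections interleaved into the same scan, so no
external reference images are needed.

# Sampling model and dose accounting

`build_mask()` realizes each acquisition mode as a boolean mask over the
$n_{\theta} \times n_{col}$ sinogram. For a cycloidal plan with period $p$,
aperture $w$, per-angle shift $s$ and initial offset $o$, entry $(k, j)$
(0-based) is measured iff $(j - o - k s) \bmod p < w$. With
$\gcd(s, p) = 1$ any $p$ consecutive angles jointly cover all $p$ column
residues. Rotation-only scanning is the degenerate case $s = 0$ (every
angle sees the same columns); angular subsampling keeps every $m$-th full
row; low-exposure scanning keeps everything at a reduced per-frame
exposure.

`dose_fraction()` accounts doses relative to a complete dithered scan
($n_{\theta}\, p/w$ frames at unit exposure). A cycloidal scan takes one
frame per angle, hence $w/p$ of the dose (12.5% for $p = 8$, $w = 1$). Each
interleaved training projection is a full dithering and is counted as
wholly additional frames: 33 training projections on a 1024-angle scan add
$33 \cdot 8 / 8192 = 3.2\%$, giving 15.7% total. This bookkeeping choice
(not crediting the cycloidal frame already taken at a training angle)
reproduces the printed dose columns of the benchmark exactly and
over-counts by at most $n_{train}/n_{\theta} \cdot w/p$, well below 0.1
percentage points at scale.

# The synthetic study

## Foam phantom

`generate_phantom()` removes non-overlapping spherical voids from a uniform
cylinder (axis = $z$, lateral field of view $[-1, 1]^2$). The void-size law
is not prescribed by the benchmark beyond "varying sizes"; we draw radii as
$r = r_{\min} (r_{\max}/r_{\min})^{u^{e}}$ with $u \sim U(0,1)$ and default
exponent $e = 3$ — many small voids, few large ones, the qualitative
signature of solid foams. Placement is rejection sampling, uniform in the
cylinder volume, largest-first (which makes dense packings feasible);
generation fails loudly when a sphere cannot be placed within the attempt
budget. Everything is deterministic given the spec (the seed is part of
it).

## Forward model and noise

`project_analytic()` evaluates line integrals in closed form (ray-circle
chords through the cylinder minus chords through each void), one
infinitesimally thin ray per detector column; `subrays > 1` averages
across the column width instead. `project_voxelized()` provides the
voxel-driven counterpart (bilinear sampling along rays at pixel steps) and
agrees with the analytic form to well under 1% relative RMS; the analytic
form is the reference.

The attenuation scale is not a free choice: `calibrate_attenuation()`
root-finds $\mu$ such that the mean absorbed fraction
$\langle 1 - e^{-\mu \ell} \rangle$ over the sinogram equals a target (0.5
by default — the sample absorbs roughly half of the incident photons).
Counting noise follows the photon-counting model: counts
$c \sim \mathrm{Poisson}(I_0 e^{-p})$ per pixel with $I_0 = 1000$ photons
at full exposure, and the returned line integral is
$-\ln(\max(c, c_{\min})/I_0)$. The clamp $c_{\min} = 0.5$ counts keeps the
log finite when zero photons arrive; it matters only beyond ~7.6
attenuation lengths at $I_0 = 1000$.

# Bicubic completion of interlaced sinograms

`bicubic_interpolate()` is the non-learned baseline. Two regimes:

* **Cycloidal lattices.** The acquired points form a lattice whose reduced
  basis is short in *both* directions (for $p = 8$, $s = 3$: $(-2, 2)$ and
  $(1, 3)$ pixels — about 3 px spacing isotropically, against 8 px along
  one axis for angular subsampling). Every missing pixel of a given column
  residue sees the same constellation of acquired neighbours, so we
  precompute, per residue class, one weight stencil: a Gaussian-weighted
  least-squares fit of a full bicubic polynomial (10 monomials up to degree
  3) over the acquired lattice points within a radius of ~7 px
  ($\sigma = 2$ px). The stencil reproduces cubic surfaces exactly — in
  particular bilinear ramps to machine precision — and one gather per class
  completes the sinogram. Axis-aligned spline schemes were rejected on
  measurement: any separable scheme on this lattice degenerates to 1-D
  (interpolation targets are always on-grid in the angle index), and
  per-column splines leave residue-staggered errors that the FBP ramp
  filter amplifies into streaks, scoring *below* angular subsampling at
  equal dose — inverting the ordering the lattice geometry should produce.
* **Row-structured masks** (angular subsampling, rotation-only, border
  bands of cycloidal masks where stencils would overhang): natural cubic
  splines along the angle axis per column, then across columns for columns
  with no data. Natural splines extrapolate linearly beyond the first/last
  knot; we prefer this over constant extension for the (at most one mask
  period wide) angular boundary band because it preserves linear trends
  exactly.

In all regimes acquired entries are returned byte-identically
(interpolation, not smoothing, at data points).

# The MS-D network

`msd_forward()` implements a width-1 Mixed-Scale Dense network: layer $i$
applies one dilated $3\times3$ convolution to the input image and to every
previous layer's output (dense connectivity), adds a scalar bias, and
applies a ReLU; dilations cycle through a fixed list (1..10 by default) so
different layers see different scales without any down/upsampling. The
output is a learned $1\times1$ linear map over all $L + 1$ channels. For
depth $L$ this costs $\sum_{i=1}^{L}(9i + 1) + (L + 1) + 1$ parameters —
45,652 at $L = 100$, orders of magnitude below encoder-decoder
architectures, which is what makes training on a few dithered projections
feasible. The network is fully convolutional: any image size is processed
whole.

Numerical choices: zero padding inside the dilated convolutions (output
size = input size); He-style initialization with variance $2/(9\,c_{in})$
per kernel, biases and final weights zero, so a fresh network outputs
exactly zero; inputs and targets are standardized to zero mean and unit
variance with statistics stored in the checkpoint and undone on
application. Forward and reverse passes are hand-written C++; the gradient
is exact (verified against finite differences to $10^{-4}$ relative).

# In-scan training

The training pair for slice $i$ is: input $x_i$ = bicubic completion of
the *pure* cycloidal subsample; target $y_i$ = the "partial sinogram"
holding the dithered training projections (13 at desk scale, 33 at full
scale, evenly spread over the angular range), undefined elsewhere. The
loss is restricted to the measured pixels $D$:

$$L_{cyc}(f_\phi(x_i),\, y_i) \;=\; \sum_{j \in D}\bigl(f_\phi(x_i)^j - y_i^j\bigr)^2 .$$

The input deliberately does *not* include the dithered rows: if it did,
input and target would agree on all of $D$ and the identity map would be a
global minimizer — the network would have nothing to learn. With the pure
cycloidal input, the supervised pixels compare interpolated against
measured values, which is exactly the restoration error the network is
meant to remove. (The measured lattice entries within training rows do
coincide between input and target; they are 1/8 of $D$ and harmless.)

Optimization is ADAM at the benchmark's learning rate $10^{-3}$, one whole
sinogram per step (no patching), sinogram order reshuffled every epoch,
90%/10% train/validation split of the slices. After every epoch the mean
per-pixel masked loss on the validation slices is evaluated and the
parameters with the lowest validation loss within the budget are kept —
training longer can only improve or retain the checkpoint. Divergence
(non-finite loss) aborts with a diagnostic. Reported losses are divided by
$|D|$ for comparability; the optimizer uses the raw sum.

# Reconstruction

`fbp()` is classical filtered back projection: each projection is
convolved (via FFT on a zero-padded axis) with the band-limited Ram-Lak
kernel $h(0) = 1/(4\tau^2)$, $h(n\ \mathrm{odd}) = -1/(\pi n \tau)^2$,
then back-projected pixel-driven with linear detector interpolation and
scaled by $\pi / n_{\theta}$, so values estimate attenuation. Pixels
outside the detector field-of-view circle receive only partial angular
coverage and are masked to zero — without this the corner artifacts
dominate any image-wide error metric.

`tv_reconstruct()` minimizes
$\tfrac12\|A u - b\|^2 + \lambda\,\mathrm{TV}(u)$ (isotropic TV, forward
differences, Neumann boundary) with the Chambolle-Pock primal-dual method.
$A$ is the matrix-free bilinear-sampling projector whose adjoint is exact
by construction (verified to machine precision); $\|A\|$ comes from 20
power iterations, steps $\sigma = \tau = 0.99/\sqrt{\|A\|^2 + 8}$. The
iteration warm-starts from the FBP image. With $\lambda = 0$ the TV dual
is inactive and the data term's convex conjugate is 1-strongly convex, so
the accelerated $O(1/N^2)$ schedule (dual extrapolation with shrinking
$\sigma$) is used; this path matches a conjugate-gradient least-squares
solve to under 1% in residual. `tune_tv_parameter()` reconstructs over a
$\lambda$ grid and keeps the weight maximizing PSNR or MS-SSIM against the
ground truth (ties toward smaller $\lambda$), mirroring how TV baselines
are usually given their best case in benchmarks.

# Metrics

* **PSNR**: $10\log_{10}(\mathrm{peak}^2/\mathrm{MSE})$ with peak = max of
  the ground-truth reference. The reference is always the second argument.
* **Dice**: overlap of thresholded segmentations; the default threshold is
  $\mu/2$, the midpoint of the two-material phantom. Otsu and a
  Dice-maximizing sweep are available alternatives.
* **MS-SSIM**: the standard 5-scale form (11x11 Gaussian window,
  $\sigma = 1.5$, canonical weights 0.0448/0.2856/0.3001/0.2363/0.1333,
  2x2 mean-pool between scales), with the luminance term on the coarsest
  scale only and negative contrast-structure means clamped at zero. The
  single-scale form matches an independent reference implementation to
  $10^{-6}$. Images too small for the requested scale count reduce it with
  a warning and renormalized weights; at $128^2$ four scales are used.

Metrics are evaluated on the central slice against the rasterized phantom
definition, consistent with how the TV weight is tuned.

# Desk-scale study conditions

The full-scale benchmark ($1024^3$ data, 100 layers, tens of hours of
training) is not a desk-scale object. `preset_tiny()` fixes the scaled
study this package runs routinely:

* 500-sphere foam, cylinder radius 0.8, void radii 0.01–0.12 (exponent
  2.5), attenuation calibrated to 50% mean absorption;
* 128 detector columns, 128 projections over 180°, $p = 8$, $w = 1$,
  shift 3; $I_0 = 1000$ photons;
* 32 axial slices (the training corpus; 29/3 split), 13 interleaved
  training projections;
* depth-30 MS-D with dilations 1–10, 30 ADAM epochs at learning rate
  $10^{-3}$ (about 900 parameter updates — minutes on one CPU).

These sizes were chosen once as the smallest configuration in which the
phenomena of interest (interlacing vs angular subsampling, learned
restoration vs interpolation, in-scan supervision from 13 projections) are
cleanly measurable; they are the conditions under which the package's
quantitative claims are stated.

# What the simulation does and does not emulate

Emulated: parallel-beam geometry, mask-structured sampling with
interleaved dithered projections, photon-counting noise at calibrated
absorption, the restoration-training-reconstruction-evaluation chain, and
paired comparisons of dose-reduction strategies (same phantom, same noise
realization where the exposure matches; low-exposure scans draw fresh
counts at reduced $I_0$, as they physically must).

Not emulated: source/detector blur (the resolution benefit that motivates
masked-beam hardware is not itself simulated — sampling and dose are),
edge-illumination phase contrast, detector cross-talk, fan/cone geometry,
continuous-motion blur in flyscans, sample drift and registration errors,
and polychromatic spectra. A passing test suite therefore certifies the
computational pipeline under the stated noise and sampling models, not
performance on any particular instrument's data.

# Known limitations

* The lattice completion stencils require $\gcd(\mathrm{shift}, p) = 1$;
  other shifts fall back to the per-column spline scheme.
* PSNR of sharp-edged phantoms is partly an edge-band quantity: the
  one-pixel transition band around every interface dominates the MSE at
  any resolution. Comparisons between methods at a fixed grid are
  unaffected, but absolute values should not be read across grid sizes.
* Training uses one CPU thread; bit-reproducibility is guaranteed only on
  a fixed platform and BLAS.
* The projection-denoising comparison mode assembles projection images
  across slices and retrains the same architecture; it is off by default
  because it doubles the training cost of a comparison run.
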