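# cycloidct

Simulation and reconstruction toolkit for **cycloidal computed tomography**
— masked-beam CT in which the sample translates laterally while it rotates —
with **CNN-based sinogram completion trained in-scan**.

## The problem

Structuring the x-ray beam with a mask (period *p*, aperture *w*, typically
*w:p* between 1:3 and 1:10) lets a CT scanner resolve beyond its source and
detector blur, but each projection then samples only a fraction *w/p* of
the detector columns. Full sampling by lateral stepping ("dithering")
multiplies the dose and scan time by *p/w*. Cycloidal scanning instead
shifts the sample a few pixels per rotation angle, so the acquired sinogram
entries form an interlaced lattice at *w/p* of the dose. The missing
entries must be restored before reconstruction.

This package is for researchers in computational imaging and biomedical
micro-CT who want to study that restoration problem quantitatively: it
simulates the whole chain on numerical foam phantoms and benchmarks
dose-reduction strategies against each other on common ground truth.

## The method

1. **Bicubic completion.** Acquired cycloidal entries form a lattice with
   short basis vectors in both sinogram directions (for *p* = 8, shift 3:
   (−2, 2) and (1, 3) pixels). Missing entries are filled by precomputed
   local bicubic least-squares stencils on that lattice — exact for cubic
   surfaces and at every acquired entry.
2. **In-scan learned restoration.** A Mixed-Scale Dense (MS-D) network
   `f_φ` — dilated 3×3 convolutions, every layer densely connected, one
   channel per layer, ~46k parameters at depth 100 — is trained on pairs
   (interpolated cycloidal sinogram `x_i`, "partial" sinogram `y_i` holding
   a few interleaved dithered projections) by minimizing the loss
   restricted to measured pixels *D*:

   L_cyc(f_φ(x_i), y_i) = Σ_{j∈D} (f_φ(x_i)^j − y_i^j)²

   The training data are acquired as part of the same scan (a handful of
   dithered projections, a few percent extra dose), so no external
   reference images are needed; ADAM optimization with validation-loss
   checkpointing over a 90/10 slice split.
3. **Reconstruction and metrics.** Ram-Lak filtered back projection and
   Chambolle–Pock total-variation reconstruction; PSNR, Dice and
   multiscale SSIM against the rasterized phantom, plus exact dose
   accounting per acquisition plan.

All core numerics (analytic sphere projector, MS-D forward/backprop,
Radon operator pair, FBP) are implemented in R/Rcpp inside the package.

## Worked example

Dose arithmetic of the benchmark plans (1024 angles, *p* = 8, *w* = 1):

```r
library(cycloidct)
plan <- acquisition_plan("cycloidal", period = 8, aperture = 1,
                         shift_per_angle = 3, n_train = 33)
dose_fraction(plan, 1024)                 # 15.72266  (% of a dithered scan)
dose_fraction(acquisition_plan("cycloidal"), 1024)   # 12.5
split_train_val(1024, 0.9, seed = 1)      # 922 train / 102 validation
```

The desk-scale foam benchmark (500-sphere phantom, 128×128 detector/grid,
128 angles, 13 interleaved training projections, depth-30 MS-D, a few minutes on
one CPU):

```r
cmp <- run_comparison(preset_tiny(seed = 1),
                      methods = c("complete", "angular_bicubic",
                                  "cycloidal_bicubic", "cycloidal_msd"))
cmp$report
#>              method dose_percent psnr_db     dice  ms_ssim
#> 1          complete     100.0000 14.4857 0.985221 0.799317
#> 2   angular_bicubic      12.5000 12.7479 0.961236 0.696329
#> 3 cycloidal_bicubic      12.5000 15.4679 0.977737 0.741451
#> 4     cycloidal_msd      22.6562 18.5361 0.983387 0.802854
```

Reading the table: at one-eighth of the dose, cycloidal sampling plus
bicubic completion (15.47 dB) already beats discarding projections
(angular subsampling, 12.75 dB) because the interlaced lattice preserves
resolution in both sinogram directions. Adding the in-scan trained MS-D
network (≈10 percentage points of extra dose for the 13 dithered training
projections at this small scale) raises PSNR by a further 3 dB and brings
MS-SSIM above the full-dose reconstruction — the network also suppresses
the photon-counting noise that the complete scan reconstructs faithfully.

A thin command-line wrapper over the same functions is installed at
`inst/cli/cycloidct` (verbs `compare`, `pipeline`, `fixtures`; YAML
configuration via `--config`).

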