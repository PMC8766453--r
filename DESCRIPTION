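Package: cycloidct
Title: Cycloidal Computed Tomography Simulation and CNN-Based Sinogram Completion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for cycloidal (roto-translational)
    computed tomography with masked-beam acquisition. Generates numerical foam
    phantoms, simulates parallel-beam projection with Poisson photon-counting
    noise, constructs interlaced cycloidal sampling masks with interleaved
    dithered training projections, completes incomplete sinograms by cubic-spline
    interpolation or by a Mixed-Scale Dense convolutional network trained in-scan
    with a loss restricted to measured pixels, reconstructs slices by filtered
    back projection or Chambolle-Pock total-variation minimization, and benchmarks
    dose-reduction strategies by PSNR, Dice and multiscale SSIM against dose
    fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    withr,
    tiff,
    yaml,
    optparse
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
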