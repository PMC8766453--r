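#' Filtered back projection
#'
#' Ram-Lak (ramp) filtering of each projection via FFT with the standard
#' band-limited discrete filter kernel, followed by pixel-driven
#' back projection with linear detector interpolation, scaled by
#' \eqn{\pi / n_{angles}} so values estimate the attenuation map.
#'
#' @param sino a complete `sinogram` (no missing entries).
#' @param grid_n reconstruction grid side length (default: detector columns).
#' @return an object of class `recon_image`: list with `values`
#'   (grid_n x grid_n), `pixel_size` and `provenance`.
#' @export
fbp <- function(sino, grid_n = sino$geometry$n_cols) {
  stopifnot(inherits(sino, "sinogram"))
  if (anyNA(sino$values)) {
    stop("sinogram has missing entries: complete it before reconstruction")
  }
  q <- ramp_filter(sino$values, sino$geometry$pixel_size)
  img <- backproject_cpp(q, geometry_angles(sino$geometry), as.integer(grid_n),
                         sino$geometry$pixel_size)
  img <- img * pi / sino$geometry$n_angles
  # pixels beyond the detector field of view see only partial angular
  # coverage; mask the standard reconstruction circle
  fov <- min(1, sino$geometry$n_cols / 2 * sino$geometry$pixel_size)
  coord <- -1 + (seq_len(grid_n) - 0.5) * 2 / grid_n
  img[outer(coord^2, coord^2, "+") > fov^2] <- 0
  structure(list(values = img, pixel_size = 2 / grid_n,
                 provenance = list(method = "fbp", filter = "ram-lak",
                                   n_angles = sino$geometry$n_angles)),
            class = "recon_image")
}

# Discrete Ram-Lak filtering of sinogram rows (angles x columns), detector
# spacing tau. Uses the band-limited spatial kernel h(0) = 1/(4 tau^2),
# h(n odd) = -1 / (pi n tau)^2, h(n even) = 0, applied by circular FFT
# convolution on a zero-padded axis; convolution is multiplied by tau.
ramp_filter <- function(values, tau) {
  nc <- ncol(values)
  npad <- 2^ceiling(log2(2 * nc))
  n <- c(0:(npad / 2), (npad / 2 - 1):1 * -1)
  h <- numeric(npad)
  h[n == 0] <- 1 / (4 * tau^2)
  odd <- n %% 2 != 0
  h[odd] <- -1 / (pi * n[odd] * tau)^2
  H <- fft(h)
  P <- matrix(0, nrow(values), npad)
  P[, seq_len(nc)] <- values
  Q <- t(apply(P, 1, function(row) Re(fft(fft(row) * H, inverse = TRUE)) / npad))
  Q[, seq_len(nc), drop = FALSE] * tau
}

#' Configuration for total-variation reconstruction
#'
#' @param tv_weight nonnegative weight \eqn{\lambda} of the isotropic TV term
#'   in \eqn{\frac12 \|A u - b\|^2 + \lambda \, TV(u)}.
#' @param n_iterations primal-dual iterations.
#' @param step_scale fraction of the step-size contract
#'   \eqn{\sigma \tau \|K\|^2 \le 1} to use (must be in (0, 1]).
#' @return an object of class `tv_config`.
#' @export
tv_config <- function(tv_weight = 0.1, n_iterations = 200L, step_scale = 0.99) {
  stopifnot(tv_weight >= 0, n_iterations >= 1, step_scale > 0, step_scale <= 1)
  structure(list(tv_weight = tv_weight,
                 n_iterations = as.integer(n_iterations),
                 step_scale = step_scale),
            class = "tv_config")
}

# forward differences with Neumann boundary; returns list(dx, dy)
grad2d <- function(u) {
  n <- nrow(u)
  dx <- cbind(u[, -1] - u[, -ncol(u)], numeric(n))
  dy <- rbind(u[-1, ] - u[-n, ], numeric(ncol(u)))
  list(dx = dx, dy = dy)
}

# negative adjoint of grad2d (discrete divergence)
div2d <- function(px, py) {
  n <- nrow(px); m <- ncol(px)
  dx <- px - cbind(numeric(n), px[, -m])
  dx[, m] <- -px[, m - 1]
  dx[, 1] <- px[, 1]
  dy <- py - rbind(numeric(m), py[-n, ])
  dy[n, ] <- -py[n - 1, ]
  dy[1, ] <- py[1, ]
  dx + dy
}

# operator norm of the discrete projector by power iteration
estimate_projector_norm <- function(angles, grid_n, n_cols, det_ps,
                                    n_iter = 20L, seed = 7L) {
  local_seed(seed)
  x <- matrix(rnorm(grid_n^2), grid_n, grid_n)
  x <- x / sqrt(sum(x^2))
  lam <- 1
  for (i in seq_len(n_iter)) {
    y <- radon_forward_cpp(x, angles, n_cols, det_ps)
    x <- radon_adjoint_cpp(y, angles, grid_n, det_ps)
    lam <- sqrt(sum(x^2))  # ||A^T A x|| with unit x -> largest eigenvalue
    x <- x / lam
  }
  sqrt(lam)
}

#' Total-variation reconstruction by the Chambolle-Pock algorithm
#'
#' Approximately minimizes
#' \eqn{\frac12 \|A u - b\|^2 + \lambda \, TV(u)} (isotropic TV, forward
#' differences, Neumann boundary) with the primal-dual hybrid gradient
#' method; \eqn{A} is the package's bilinear-sampling discrete projector and
#' \eqn{\|K\|} is estimated by power iteration. With `tv_weight = 0` the TV
#' dual is inactive and the data term's convex conjugate is 1-strongly
#' convex, so the accelerated step-size schedule (dual extrapolation,
#' O(1/N^2)) is used and the iteration converges to a least-squares
#' reconstruction.
#'
#' @param sino a complete `sinogram`.
#' @param grid_n reconstruction grid side length.
#' @param cfg a [tv_config()].
#' @return a `recon_image`; provenance records the objective value and the
#'   primal optimality residual at the final iterate.
#' @export
tv_reconstruct <- function(sino, grid_n = sino$geometry$n_cols,
                           cfg = tv_config()) {
  stopifnot(inherits(sino, "sinogram"), inherits(cfg, "tv_config"))
  if (anyNA(sino$values)) {
    stop("sinogram has missing entries: complete it before reconstruction")
  }
  b <- sino$values
  th <- geometry_angles(sino$geometry)
  nc <- sino$geometry$n_cols
  ps <- sino$geometry$pixel_size
  grid_n <- as.integer(grid_n)
  nA <- estimate_projector_norm(th, grid_n, nc, ps)
  Lk <- sqrt(nA^2 + 8)  # ||grad||^2 <= 8 with unit spacing
  sig <- cfg$step_scale / Lk
  tau <- cfg$step_scale / Lk
  lam <- cfg$tv_weight

  # warm start from the FBP image: the primal-dual iteration then only has
  # to correct filter/regularization differences, not rebuild the image
  u <- fbp(sino, grid_n)$values
  ubar <- u
  q <- matrix(0, nrow(b), ncol(b))
  px <- matrix(0, grid_n, grid_n)
  py <- matrix(0, grid_n, grid_n)
  if (lam == 0) {
    # accelerated schedule (strongly convex dual of the quadratic data term)
    sig <- cfg$step_scale / nA
    tau <- cfg$step_scale / nA
    qbar <- q
    for (it in seq_len(cfg$n_iterations)) {
      u <- u - tau * radon_adjoint_cpp(qbar, th, grid_n, ps)
      q_old <- q
      q <- (q + sig * (radon_forward_cpp(u, th, nc, ps) - b)) / (1 + sig)
      theta <- 1 / sqrt(1 + 2 * sig)
      qbar <- q + theta * (q - q_old)
      sig <- sig * theta
      tau <- tau / theta
    }
  } else {
    for (it in seq_len(cfg$n_iterations)) {
      q <- (q + sig * (radon_forward_cpp(ubar, th, nc, ps) - b)) / (1 + sig)
      g <- grad2d(ubar)
      px2 <- px + sig * g$dx
      py2 <- py + sig * g$dy
      mag <- pmax(1, sqrt(px2^2 + py2^2) / lam)
      px <- px2 / mag
      py <- py2 / mag
      u_old <- u
      u <- u - tau * (radon_adjoint_cpp(q, th, grid_n, ps) - div2d(px, py))
      ubar <- 2 * u - u_old
    }
  }
  r <- radon_forward_cpp(u, th, nc, ps) - b
  g <- grad2d(u)
  obj <- 0.5 * sum(r^2) + lam * sum(sqrt(g$dx^2 + g$dy^2))
  resid <- radon_adjoint_cpp((q), th, grid_n, ps) - div2d(px, py)
  structure(list(values = u, pixel_size = 2 / grid_n,
                 provenance = list(method = "tv", tv_weight = lam,
                                   n_iterations = cfg$n_iterations,
                                   objective = obj,
                                   optimality_residual = sqrt(mean(resid^2)))),
            class = "recon_image")
}

#' Select the TV weight that maximizes a metric against a reference
#'
#' Reconstructs the sinogram at every weight on the grid and returns the
#' weight (and its reconstruction) maximizing PSNR or MS-SSIM against the
#' ground-truth reference; ties break toward the smaller weight.
#'
#' @param sino a complete `sinogram`.
#' @param reference ground-truth image (`recon_image`, `voxel_slice` or
#'   matrix).
#' @param metric `"psnr"` or `"ms_ssim"`.
#' @param lambdas numeric grid of candidate TV weights.
#' @param grid_n reconstruction grid side length.
#' @param n_iterations iterations per candidate reconstruction.
#' @return list with `lambda`, `recon` (the winning `recon_image`), `metric`,
#'   `values` (metric per candidate).
#' @export
tune_tv_parameter <- function(sino, reference, metric = c("psnr", "ms_ssim"),
                              lambdas, grid_n = sino$geometry$n_cols,
                              n_iterations = 200L) {
  metric <- match.arg(metric)
  stopifnot(length(lambdas) >= 1)
  ref <- as_image_matrix(reference)
  lambdas <- sort(lambdas)
  vals <- numeric(length(lambdas))
  recs <- vector("list", length(lambdas))
  for (i in seq_along(lambdas)) {
    rec <- tv_reconstruct(sino, grid_n,
                          tv_config(lambdas[i], n_iterations = n_iterations))
    vals[i] <- if (metric == "psnr") psnr(rec$values, ref)
               else ms_ssim(rec$values, ref)
    recs[[i]] <- rec
  }
  k <- which.max(vals)  # first max -> smallest lambda on ties
  list(lambda = lambdas[k], recon = recs[[k]], metric = metric,
       values = stats::setNames(vals, lambdas))
}

as_image_matrix <- function(x) {
  if (is.matrix(x)) x
  else if (inherits(x, "recon_image") || inherits(x, "voxel_slice")) x$values
  else stop("cannot interpret object as an image")
}

#' Write a reconstruction as 32-bit TIFF with a JSON provenance sidecar
#' @param recon a `recon_image`.
#' @param path basename; writes `<path>.tif` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_recon <- function(recon, path) {
  sc <- write_scaled_tiff(recon$values, paste0(path, ".tif"))
  jsonlite::write_json(c(recon$provenance,
                         list(pixel_size = recon$pixel_size,
                              data_min = sc[1], data_max = sc[2])),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
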