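#' Specification of a numerical foam phantom
#'
#' A foam phantom is a uniform cylinder of attenuating material from which
#' non-overlapping spherical voids are removed. The cylinder axis is the
#' z-axis and the lateral field of view is the square \eqn{[-1, 1]^2}.
#'
#' @param n_spheres number of spherical voids.
#' @param cylinder_radius cylinder radius as a fraction of the half field of
#'   view (must be < 1 so the cylinder fits the reconstruction grid).
#' @param radius_min,radius_max smallest and largest void radius.
#' @param radius_exponent shape of the void-size distribution: radii are drawn
#'   as \eqn{r = r_{min} (r_{max}/r_{min})^{u^e}} with \eqn{u \sim U(0,1)};
#'   larger exponents give many small and few large voids, mimicking foam.
#' @param attenuation linear attenuation coefficient \eqn{\mu} of the bulk
#'   material (inverse field-of-view units).
#' @param z_half half-extent of sphere centers along the cylinder axis.
#' @param seed integer seed; the same spec always yields the same phantom.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_spheres, cylinder_radius = 0.8,
                         radius_min = 0.01, radius_max = 0.1,
                         radius_exponent = 3, attenuation = 1,
                         z_half = 0.5, seed = 1L) {
  stopifnot(n_spheres >= 0, cylinder_radius > 0, cylinder_radius < 1,
            radius_min > 0, radius_min <= radius_max,
            radius_max < cylinder_radius, attenuation > 0,
            radius_exponent > 0, z_half > 0)
  structure(list(n_spheres = as.integer(n_spheres),
                 cylinder_radius = cylinder_radius,
                 radius_min = radius_min, radius_max = radius_max,
                 radius_exponent = radius_exponent,
                 attenuation = attenuation, z_half = z_half,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a foam phantom by rejection sampling
#'
#' Draws `n_spheres` void radii from the spec's size distribution and places
#' them largest-first, uniformly in the cylinder volume, rejecting candidates
#' that overlap an already placed sphere or protrude laterally from the
#' cylinder. Deterministic for a given spec (seed included).
#'
#' @param spec a [phantom_spec()].
#' @param max_attempts rejection-sampling budget per sphere; generation aborts
#'   with a diagnostic if a sphere cannot be placed (packing too dense).
#' @return an object of class `sphere_set`: list with `centers` (n x 3 matrix,
#'   columns x, y, z), `radii` (length n) and `spec`.
#' @export
generate_phantom <- function(spec, max_attempts = 10000L) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$n_spheres
  if (n == 0L) {
    return(structure(list(centers = matrix(numeric(0), 0, 3,
                                           dimnames = list(NULL, c("x", "y", "z"))),
                          radii = numeric(0), spec = spec),
                     class = "sphere_set"))
  }
  rng <- local_seed(spec$seed)
  u <- runif(n)
  radii <- spec$radius_min *
    (spec$radius_max / spec$radius_min)^(u^spec$radius_exponent)
  radii <- sort(radii, decreasing = TRUE)  # largest-first eases packing
  centers <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  R <- spec$cylinder_radius
  for (i in seq_len(n)) {
    r <- radii[i]
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      # uniform in the admissible cylinder (lateral radius R - r)
      rho <- (R - r) * sqrt(runif(1))
      phi <- runif(1, 0, 2 * pi)
      cand <- c(rho * cos(phi), rho * sin(phi),
                runif(1, -spec$z_half, spec$z_half))
      if (i > 1L) {
        prev <- seq_len(i - 1L)
        d2 <- (centers[prev, 1] - cand[1])^2 + (centers[prev, 2] - cand[2])^2 +
          (centers[prev, 3] - cand[3])^2
        if (any(d2 < (radii[prev] + r)^2)) next
      }
      centers[i, ] <- cand
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(sprintf(paste0("could not place sphere %d of %d (radius %.4g) ",
                          "within %d attempts: packing too dense"),
                   i, n, r, max_attempts))
    }
  }
  structure(list(centers = centers, radii = radii, spec = spec),
            class = "sphere_set")
}

#' @export
print.sphere_set <- function(x, ...) {
  cat(sprintf("<sphere_set> %d voids, cylinder radius %.3g, mu = %.4g\n",
              length(x$radii), x$spec$cylinder_radius, x$spec$attenuation))
  invisible(x)
}

#' Rasterize an axial slice of a foam phantom
#'
#' Pixel values are \eqn{\mu} times the area fraction of the pixel lying
#' inside the cylinder and outside every void, estimated with
#' `supersample`^2 regularly spaced subsamples per pixel.
#'
#' @param spheres a [generate_phantom()] result.
#' @param z axial position of the slice.
#' @param grid_n image side length in pixels (field of view \eqn{[-1,1]^2}).
#' @param supersample subsamples per pixel edge (>= 1).
#' @return an object of class `voxel_slice`: list with `values`
#'   (grid_n x grid_n matrix, row index = y, column index = x), `pixel_size`
#'   and `z`.
#' @export
rasterize_slice <- function(spheres, z = 0, grid_n = 128L, supersample = 2L) {
  stopifnot(inherits(spheres, "sphere_set"), grid_n >= 1, supersample >= 1)
  grid_n <- as.integer(grid_n)
  supersample <- as.integer(supersample)
  fine_n <- grid_n * supersample
  ps_fine <- 2 / fine_n
  coord <- -1 + (seq_len(fine_n) - 0.5) * ps_fine
  xs <- matrix(coord, fine_n, fine_n, byrow = TRUE)  # column index = x
  ys <- matrix(coord, fine_n, fine_n)                # row index = y
  R <- spheres$spec$cylinder_radius
  inside <- (xs^2 + ys^2) <= R^2
  if (length(spheres$radii)) {
    dz2 <- (spheres$centers[, 3] - z)^2
    hit <- which(dz2 < spheres$radii^2)
    for (i in hit) {
      rho2 <- spheres$radii[i]^2 - dz2[i]
      cx <- spheres$centers[i, 1]; cy <- spheres$centers[i, 2]
      # restrict to the sphere's bounding box on the fine grid
      rho <- sqrt(rho2)
      jx <- which(abs(coord - cx) <= rho)
      jy <- which(abs(coord - cy) <= rho)
      if (!length(jx) || !length(jy)) next
      sub <- outer((coord[jy] - cy)^2, (coord[jx] - cx)^2, "+") <= rho2
      inside[jy, jx][sub] <- FALSE
    }
  }
  fine <- matrix(0, fine_n, fine_n)
  fine[inside] <- spheres$spec$attenuation
  # average-pool supersample x supersample blocks
  if (supersample > 1L) {
    vals <- .block_mean(fine, supersample)
  } else {
    vals <- fine
  }
  structure(list(values = vals, pixel_size = 2 / grid_n, z = z),
            class = "voxel_slice")
}

.block_mean <- function(m, k) {
  n <- nrow(m) / k
  # collapse rows then columns
  m1 <- matrix(colMeans(matrix(m, nrow = k)), nrow = n)       # n x (n*k)
  t(matrix(colMeans(matrix(t(m1), nrow = k)), nrow = n))
}

#' Binary void/material ground truth for a slice
#'
#' Threshold of the rasterized slice at half the bulk attenuation, the
#' midpoint of the two-material phantom.
#' @param slice a [rasterize_slice()] result.
#' @param mu bulk attenuation (defaults to the maximum of the slice).
#' @return logical matrix, `TRUE` = material.
#' @export
slice_segmentation <- function(slice, mu = max(slice$values)) {
  slice$values > mu / 2
}

#' Write a sphere set to plain-text files
#'
#' `centers`/`radii` as CSV plus the spec as a JSON sidecar.
#' @param spheres a `sphere_set`.
#' @param path basename; writes `<path>.csv` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_sphere_set <- function(spheres, path) {
  df <- data.frame(x = spheres$centers[, 1], y = spheres$centers[, 2],
                   z = spheres$centers[, 3], r = spheres$radii)
  write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(unclass(spheres$spec), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sphere set written by [write_sphere_set()]
#' @param path basename used when writing.
#' @return a `sphere_set`.
#' @export
read_sphere_set <- function(path) {
  df <- read.csv(paste0(path, ".csv"))
  sp <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  spec <- do.call(phantom_spec, sp[c("n_spheres", "cylinder_radius",
                                     "radius_min", "radius_max",
                                     "radius_exponent", "attenuation",
                                     "z_half", "seed")])
  structure(list(centers = as.matrix(df[, c("x", "y", "z")]),
                 radii = df$r, spec = spec),
            class = "sphere_set")
}

# Seed the RNG for the calling function's scope, restoring the caller's
# RNG state when that scope exits.
local_seed <- function(seed, env = parent.frame()) {
  withr::local_seed(as.integer(seed) %% .Machine$integer.max,
                    .local_envir = env)
  invisible(seed)
}
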