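#' Parallel-beam acquisition geometry
#'
#' Projection angle k (1-based) is \eqn{(k-1) \cdot range / n_{angles}}
#' degrees; detector column j senses the signed lateral offset
#' \eqn{s_j = (j - 0.5 - n_{cols}/2) \cdot pixel\_size} (1-based j), rotated
#' counter-clockwise with the angle.
#'
#' @param n_angles number of projections.
#' @param n_cols number of detector columns.
#' @param angular_range total angular range in degrees (default 180).
#' @param pixel_size detector pixel size in field-of-view units
#'   (default `2 / n_cols`, matching the \eqn{[-1,1]} field of view).
#' @return an object of class `ct_geometry`.
#' @export
ct_geometry <- function(n_angles, n_cols, angular_range = 180,
                        pixel_size = 2 / n_cols) {
  stopifnot(n_angles >= 1, n_cols >= 1, angular_range > 0, pixel_size > 0)
  structure(list(n_angles = as.integer(n_angles), n_cols = as.integer(n_cols),
                 angular_range = angular_range, pixel_size = pixel_size),
            class = "ct_geometry")
}

#' Projection angles of a geometry, in radians
#' @param geometry a [ct_geometry()].
#' @return numeric vector of length `n_angles`.
#' @export
geometry_angles <- function(geometry) {
  (seq_len(geometry$n_angles) - 1) * geometry$angular_range /
    geometry$n_angles * pi / 180
}

new_sinogram <- function(values, geometry, slice_z = 0) {
  structure(list(values = values, geometry = geometry, slice_z = slice_z),
            class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d angles x %d columns, z = %.3g, %d missing\n",
              nrow(x$values), ncol(x$values), x$slice_z, sum(is.na(x$values))))
  invisible(x)
}

#' Analytic parallel-beam projection of a foam phantom
#'
#' Computes each sinogram entry in closed form as \eqn{\mu} times the chord
#' length of the ray through the cylinder minus the chord lengths through all
#' voids it intersects at slice height `z` (one infinitesimally thin ray per
#' detector column, through the column center). Entries are never negative:
#' voids lie inside the cylinder.
#'
#' @param spheres a [generate_phantom()] result.
#' @param geometry a [ct_geometry()].
#' @param z axial position of the slice.
#' @param attenuation override for the spec's bulk attenuation \eqn{\mu}.
#' @param subrays rays averaged across the width of each detector column.
#'   The default single ray through the column center models a narrow
#'   aperture; larger values integrate over the column width, band-limiting
#'   the sinogram (useful when reconstruction quality at the grid scale is
#'   the object of study).
#' @return a `sinogram` (values: n_angles x n_cols line integrals).
#' @export
project_analytic <- function(spheres, geometry, z = 0,
                             attenuation = spheres$spec$attenuation,
                             subrays = 1L) {
  stopifnot(inherits(spheres, "sphere_set"), inherits(geometry, "ct_geometry"),
            subrays >= 1)
  if (subrays > 1L) {
    geo_fine <- ct_geometry(geometry$n_angles, geometry$n_cols * subrays,
                            geometry$angular_range,
                            geometry$pixel_size / subrays)
    fine <- project_analytic(spheres, geo_fine, z, attenuation)
    vals <- fine$values %*% kronecker(diag(geometry$n_cols),
                                      rep(1 / subrays, subrays))
    return(new_sinogram(vals, geometry, z))
  }
  th <- geometry_angles(geometry)
  nc <- geometry$n_cols
  s <- (seq_len(nc) - 0.5 - nc / 2) * geometry$pixel_size
  R <- spheres$spec$cylinder_radius
  # circles cut by the slice plane
  act <- integer(0); rho <- numeric(0); cx <- numeric(0); cy <- numeric(0)
  if (length(spheres$radii)) {
    dz2 <- (spheres$centers[, 3] - z)^2
    act <- which(dz2 < spheres$radii^2)
    rho <- sqrt(spheres$radii[act]^2 - dz2[act])
    cx <- spheres$centers[act, 1]
    cy <- spheres$centers[act, 2]
  }
  vals <- matrix(0, geometry$n_angles, nc)
  for (k in seq_along(th)) {
    ct <- cos(th[k]); st <- sin(th[k])
    chord <- 2 * sqrt(pmax(R^2 - s^2, 0))
    if (length(act)) {
      proj <- cx * ct + cy * st  # detector coordinate of each circle center
      for (i in seq_along(act)) {
        d2 <- (proj[i] - s)^2
        inside <- d2 < rho[i]^2
        if (any(inside)) {
          chord[inside] <- chord[inside] - 2 * sqrt(rho[i]^2 - d2[inside])
        }
      }
    }
    vals[k, ] <- attenuation * chord
  }
  new_sinogram(vals, geometry, z)
}

#' Calibrate bulk attenuation to a target mean absorption
#'
#' Finds \eqn{\mu} such that the mean over sinogram entries of
#' \eqn{1 - e^{-\mu \ell}} (the absorbed photon fraction for path length
#' \eqn{\ell}) equals `target_absorption`, by a monotone scalar root-find.
#' Emulates choosing the exposure so the sample absorbs a given fraction of
#' the incident photons on average.
#'
#' @param spheres a [generate_phantom()] result.
#' @param geometry a [ct_geometry()].
#' @param target_absorption fraction in (0, 1) (e.g. 0.5 = half absorbed).
#' @param z slice height used for the calibration projection.
#' @param tol absolute tolerance on the achieved mean absorption.
#' @return the calibrated attenuation \eqn{\mu}.
#' @export
calibrate_attenuation <- function(spheres, geometry, target_absorption = 0.5,
                                  z = 0, tol = 1e-4) {
  stopifnot(target_absorption > 0, target_absorption < 1)
  ell <- project_analytic(spheres, geometry, z, attenuation = 1)$values
  if (all(ell <= 0)) stop("phantom contains no material along any ray")
  f <- function(mu) mean(1 - exp(-mu * ell)) - target_absorption
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  uniroot(f, c(0, hi), tol = tol * 1e-2)$root
}

#' Photon-counting noise model
#'
#' @param incident_photons expected photon count per detector pixel before
#'   the sample (the paper-style virtual exposure).
#' @param count_floor clamp applied to zero measured counts before the log
#'   (in counts, in (0, 1]); keeps post-log values finite.
#' @param seed integer seed.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(incident_photons = 1000, count_floor = 0.5, seed = 1L) {
  stopifnot(incident_photons > 0, count_floor > 0, count_floor <= 1)
  structure(list(incident_photons = incident_photons,
                 count_floor = count_floor, seed = as.integer(seed)),
            class = "noise_model")
}

#' Apply Poisson counting noise to a noiseless sinogram
#'
#' Draws independent counts \eqn{c_j \sim Poisson(I_0 e^{-p_j})} for every
#' entry and returns \eqn{-\ln(\max(c_j, c_{min}) / I_0)}. Missing entries
#' (NA) are passed through untouched. Deterministic for a fixed seed.
#'
#' @param sino a noiseless `sinogram` (values >= 0).
#' @param noise a [noise_model()].
#' @return a `sinogram` of noisy line-integral estimates.
#' @export
apply_counting_noise <- function(sino, noise) {
  stopifnot(inherits(sino, "sinogram"), inherits(noise, "noise_model"))
  v <- sino$values
  ok <- !is.na(v)
  if (any(v[ok] < 0)) stop("input sinogram must be noiseless (values >= 0)")
  local_seed(noise$seed)
  expected <- noise$incident_photons * exp(-v[ok])
  counts <- rpois(length(expected), expected)
  v[ok] <- -log(pmax(counts, noise$count_floor) / noise$incident_photons)
  out <- sino
  out$values <- v
  out
}

#' Voxelized projection of a rasterized slice
#'
#' Discrete Radon transform of a [rasterize_slice()] image using the
#' package's bilinear-sampling line integrator. Serves as the voxel-driven
#' counterpart of [project_analytic()].
#'
#' @param slice a `voxel_slice`.
#' @param geometry a [ct_geometry()].
#' @return a `sinogram`.
#' @export
project_voxelized <- function(slice, geometry) {
  stopifnot(inherits(slice, "voxel_slice"), inherits(geometry, "ct_geometry"))
  vals <- radon_forward_cpp(slice$values, geometry_angles(geometry),
                            geometry$n_cols, geometry$pixel_size)
  new_sinogram(vals, geometry, slice$z)
}

#' Write / read a sinogram as 32-bit float TIFF with a JSON sidecar
#' @param sino a `sinogram`.
#' @param path basename; writes `<path>.tif` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_sinogram <- function(sino, path) {
  sc <- write_scaled_tiff(sino$values, paste0(path, ".tif"))
  meta <- c(unclass(sino$geometry),
            list(slice_z = sino$slice_z, data_min = sc[1], data_max = sc[2],
                 missing_idx = which(is.na(sino$values))))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sinogram
#' @export
read_sinogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- read_scaled_tiff(paste0(path, ".tif"), meta$data_min, meta$data_max)
  idx <- unlist(meta$missing_idx)
  if (length(idx)) v[idx] <- NA_real_
  geo <- ct_geometry(meta$n_angles, meta$n_cols, meta$angular_range,
                     meta$pixel_size)
  new_sinogram(v, geo, meta$slice_z)
}

# TIFF float storage is defined on [0, 1]; arrays are stored affinely scaled
# with the (min, max) recorded in the JSON sidecar. NA marks missing entries
# and travels as NaN.
write_scaled_tiff <- function(v, file) {
  lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
  scaled <- if (hi > lo) (v - lo) / (hi - lo) else v * 0
  scaled[is.na(scaled)] <- NaN
  tiff::writeTIFF(scaled, file, bits.per.sample = 32L, reduce = TRUE)
  c(lo, hi)
}

read_scaled_tiff <- function(file, lo, hi) {
  v <- tiff::readTIFF(file)
  v[is.nan(v)] <- NA_real_
  if (hi > lo) v * (hi - lo) + lo else v + lo
}
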