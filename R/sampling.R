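#' Acquisition plan for masked-beam scanning
#'
#' Describes how a masked-beam scan samples the sinogram. Modes:
#' \describe{
#'   \item{`dithered`}{the sample is stepped laterally at every angle so all
#'     column positions behind the mask are measured: complete sinogram,
#'     full dose.}
#'   \item{`cycloidal`}{the sample translates `shift_per_angle` pixels per
#'     projection while rotating; each angle measures one column residue of
#'     the mask period: interlaced incomplete sinogram.}
#'   \item{`rotation_only`}{cycloidal with zero shift: every angle measures
#'     the same columns.}
#'   \item{`angular_subsampled`}{every `angular_step_keep`-th projection is
#'     kept in full (dithered), the rest discarded.}
#'   \item{`low_exposure`}{complete sampling at `exposure_fraction` of the
#'     full exposure per frame.}
#' }
#' `n_train` interleaved dithered training projections (rows sampled in full)
#' can be added to any mode; they are what the in-scan training scheme learns
#' from.
#'
#' @param mode one of the modes above.
#' @param period mask period p in detector pixels.
#' @param aperture aperture width w in detector pixels (1 <= w <= p). A w:p
#'   ratio outside the typical 1:3 to 1:10 masked-beam regime triggers a
#'   warning, not an error.
#' @param shift_per_angle lateral sample shift per projection, in pixels.
#' @param initial_offset column residue sampled at the first angle.
#' @param angular_step_keep keep every this-many-th projection
#'   (`angular_subsampled` mode).
#' @param exposure_fraction per-frame exposure relative to full
#'   (`low_exposure` mode).
#' @param n_train number of interleaved training projections.
#' @return an object of class `acquisition_plan`.
#' @export
acquisition_plan <- function(mode = c("cycloidal", "dithered", "rotation_only",
                                      "angular_subsampled", "low_exposure"),
                             period = 8L, aperture = 1L, shift_per_angle = 3L,
                             initial_offset = 0L, angular_step_keep = 8L,
                             exposure_fraction = 1, n_train = 0L) {
  mode <- match.arg(mode)
  stopifnot(aperture >= 1, aperture <= period,
            shift_per_angle >= 0, shift_per_angle < period,
            initial_offset >= 0, initial_offset < period,
            angular_step_keep >= 1,
            exposure_fraction > 0, exposure_fraction <= 1, n_train >= 0)
  ratio <- period / aperture
  if (mode %in% c("cycloidal", "rotation_only") && (ratio < 3 || ratio > 10)) {
    warning(sprintf("aperture:period ratio 1:%.3g is outside the typical 1:3 to 1:10 masked-beam regime", ratio))
  }
  structure(list(mode = mode, period = as.integer(period),
                 aperture = as.integer(aperture),
                 shift_per_angle = as.integer(shift_per_angle),
                 initial_offset = as.integer(initial_offset),
                 angular_step_keep = as.integer(angular_step_keep),
                 exposure_fraction = exposure_fraction,
                 n_train = as.integer(n_train)),
            class = "acquisition_plan")
}

#' Evenly distributed training-projection angles
#'
#' Indices (1-based) of `n_train` projections distributed evenly across the
#' total angular range: `round(i * n_angles / n_train) + 1` for
#' `i = 0 .. n_train - 1`, clamped to `[1, n_angles]` and strictly increasing.
#'
#' @param n_angles total number of projections.
#' @param n_train number of training projections (0 <= n_train <= n_angles).
#' @return sorted integer vector of angle indices.
#' @export
select_training_angles <- function(n_angles, n_train) {
  stopifnot(n_train >= 0, n_train <= n_angles)
  if (n_train == 0L) return(integer(0))
  idx <- round((seq_len(n_train) - 1) * n_angles / n_train) + 1
  idx <- pmin(pmax(as.integer(idx), 1L), as.integer(n_angles))
  stopifnot(!anyDuplicated(idx))
  idx
}

#' Build the boolean sampling mask of an acquisition plan
#'
#' For a cycloidal plan, entry (k, j) (1-based) is sampled iff
#' `(j - 1 - initial_offset - (k - 1) * shift_per_angle) mod period <
#' aperture`, except on training rows, which are sampled in full. The other
#' modes follow their definitions in [acquisition_plan()].
#'
#' @param plan an [acquisition_plan()].
#' @param n_angles,n_cols sinogram dimensions.
#' @return an object of class `sampling_pattern`: list with `mask`
#'   (n_angles x n_cols logical), `plan` and `training_angles`.
#' @export
build_mask <- function(plan, n_angles, n_cols) {
  stopifnot(inherits(plan, "acquisition_plan"))
  train <- select_training_angles(n_angles, plan$n_train)
  mask <- switch(plan$mode,
    dithered = ,
    low_exposure = matrix(TRUE, n_angles, n_cols),
    angular_subsampled = {
      m <- matrix(FALSE, n_angles, n_cols)
      m[seq(1L, n_angles, by = plan$angular_step_keep), ] <- TRUE
      m
    },
    cycloidal = ,
    rotation_only = {
      shift <- if (plan$mode == "rotation_only") 0L else plan$shift_per_angle
      k <- seq_len(n_angles) - 1L
      j <- seq_len(n_cols) - 1L
      res <- outer(-k * shift, j - plan$initial_offset, "+") %% plan$period
      res < plan$aperture
    })
  if (length(train)) mask[train, ] <- TRUE
  structure(list(mask = mask, plan = plan, training_angles = train),
            class = "sampling_pattern")
}

#' Apply a sampling pattern to a complete sinogram
#'
#' Copies values where the mask is `TRUE` and writes the `NA` missing marker
#' elsewhere; training rows are copied in full (their rows are `TRUE` in the
#' mask). Idempotent.
#'
#' @param full a complete `sinogram`.
#' @param pattern a [build_mask()] result of matching shape.
#' @return an incomplete `sinogram`.
#' @export
apply_pattern <- function(full, pattern) {
  stopifnot(inherits(full, "sinogram"), inherits(pattern, "sampling_pattern"))
  if (!all(dim(full$values) == dim(pattern$mask))) {
    stop("sinogram and sampling mask shapes differ")
  }
  out <- full
  out$values[!pattern$mask] <- NA_real_
  out
}

#' Arrange training projections into a partial sinogram
#'
#' A partial sinogram has the shape of the full sinogram but carries data only
#' on the rows of the training angles; all other entries are undefined. It is
#' the target of the in-scan masked training loss.
#'
#' @param full a `sinogram` (complete, or at least complete on training rows).
#' @param training_angles integer vector of angle indices (1-based).
#' @return an object of class `partial_sinogram`: list with `values`
#'   (NA off the training rows), `defined` (logical matrix) and
#'   `training_angles`.
#' @export
extract_partial <- function(full, training_angles) {
  stopifnot(inherits(full, "sinogram"),
            all(training_angles >= 1), all(training_angles <= nrow(full$values)))
  defined <- matrix(FALSE, nrow(full$values), ncol(full$values))
  defined[training_angles, ] <- TRUE
  vals <- matrix(NA_real_, nrow(full$values), ncol(full$values))
  vals[training_angles, ] <- full$values[training_angles, ]
  if (anyNA(vals[defined])) stop("training rows contain missing values")
  structure(list(values = vals, defined = defined,
                 training_angles = as.integer(training_angles)),
            class = "partial_sinogram")
}

#' Dose fraction of an acquisition plan
#'
#' Frames-and-exposure-weighted dose relative to a complete dithered
#' full-exposure scan, which takes `n_angles * period / aperture` frames at
#' unit exposure. A cycloidal or rotation-only scan takes one frame per angle;
#' angular subsampling dithers every kept angle; low exposure dithers every
#' angle at reduced exposure. Each interleaved training projection is counted
#' as one wholly additional full dithering (`period / aperture` frames at
#' unit exposure).
#'
#' @param plan an [acquisition_plan()].
#' @param n_angles total number of projections.
#' @return dose as a percentage of the complete scan.
#' @export
dose_fraction <- function(plan, n_angles) {
  stopifnot(inherits(plan, "acquisition_plan"))
  frames_full <- n_angles * plan$period / plan$aperture
  base <- switch(plan$mode,
    dithered = frames_full,
    cycloidal = ,
    rotation_only = n_angles,
    angular_subsampled =
      length(seq(1L, n_angles, by = plan$angular_step_keep)) *
        plan$period / plan$aperture,
    low_exposure = frames_full * plan$exposure_fraction)
  overhead <- plan$n_train * plan$period / plan$aperture
  100 * (base + overhead) / frames_full
}

#' Write / read a sampling pattern (mask TIFF + plan JSON)
#' @param pattern a `sampling_pattern`.
#' @param path basename; writes `<path>.tif` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_pattern <- function(pattern, path) {
  tiff::writeTIFF(pattern$mask * 1, paste0(path, ".tif"),
                  bits.per.sample = 8L)
  jsonlite::write_json(c(unclass(pattern$plan),
                         list(training_angles = pattern$training_angles)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pattern
#' @export
read_pattern <- function(path) {
  m <- tiff::readTIFF(paste0(path, ".tif"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  plan <- do.call(acquisition_plan,
                  meta[c("mode", "period", "aperture", "shift_per_angle",
                         "initial_offset", "angular_step_keep",
                         "exposure_fraction", "n_train")])
  structure(list(mask = m > 0.5, plan = plan,
                 training_angles = as.integer(meta$training_angles)),
            class = "sampling_pattern")
}
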