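#' Complete an incomplete sinogram with bicubic interpolation
#'
#' Baseline bicubic completion of interlaced sinograms. The scheme depends on
#' the sampling structure:
#'
#' * Cycloidal masks (`gcd(shift, period) = 1`, shift > 0): the acquired
#'   points form a two-dimensional lattice with short basis vectors in both
#'   the angle and column directions (e.g. (-2, 2) and (1, 3) pixels for
#'   period 8, shift 3). Each missing entry is filled by a local bicubic
#'   polynomial fitted to the surrounding lattice samples (Gaussian-weighted
#'   least squares, one precomputed stencil per column-residue class). This
#'   uses both sinogram directions at the lattice's ~3-pixel resolution — the
#'   property that makes interlaced sampling easier to restore than angular
#'   subsampling — and reproduces cubic surfaces, in particular linear ramps,
#'   exactly.
#' * All other masks (angular subsampling, rotation-only, partial masks): a
#'   natural cubic spline along the angle axis through each column's acquired
#'   points, followed by cubic splines across columns for columns with no
#'   samples. The same per-column scheme also fills the image border band of
#'   cycloidal masks, where the lattice stencils would overhang the sinogram.
#'
#' In every case acquired entries are returned exactly (interpolation, not
#' smoothing, at the data points). Beyond the first/last acquired point of a
#' column the natural spline extrapolates linearly, a gentle treatment of the
#' (at most one mask period wide) angular boundary band.
#'
#' @param incomplete an incomplete `sinogram` (NA at unacquired entries).
#' @param pattern the [build_mask()] pattern that produced it; its mask is
#'   the source of truth for which entries are data.
#' @param stencil_radius half-width in pixels of the lattice stencil
#'   neighbourhood (cycloidal masks).
#' @param stencil_sigma Gaussian weighting scale in pixels for the local fit.
#' @return a complete `sinogram`; acquired entries are returned unchanged.
#' @export
bicubic_interpolate <- function(incomplete, pattern, stencil_radius = 5L,
                                stencil_sigma = 2) {
  stopifnot(inherits(incomplete, "sinogram"),
            inherits(pattern, "sampling_pattern"))
  v <- incomplete$values
  mask <- pattern$mask
  if (!all(dim(v) == dim(mask))) stop("sinogram and mask shapes differ")
  if (anyNA(v[mask])) stop("mask marks entries as acquired but values are missing")
  if (sum(mask) < 16) stop("insufficient support for interpolation (< 16 acquired points)")
  out <- spline_complete(v, mask)
  plan <- pattern$plan
  if (plan$mode == "cycloidal" && plan$shift_per_angle > 0 &&
      gcd(plan$shift_per_angle, plan$period) == 1L) {
    out <- lattice_cubic_fill(v, out, plan, stencil_radius, stencil_sigma)
  }
  out[mask] <- v[mask]
  res <- incomplete
  res$values <- out
  res
}

gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)

# per-column natural splines along the angle axis; cross-column splines for
# empty columns
spline_complete <- function(v, mask) {
  na <- nrow(v); nc <- ncol(v)
  out <- v
  rows <- seq_len(na)
  need_col_pass <- logical(nc)
  for (j in seq_len(nc)) {
    kn <- which(mask[, j])
    if (length(kn) == na) next
    if (length(kn) < 2L) { need_col_pass[j] <- TRUE; next }
    f <- splinefun(kn, v[kn, j], method = "natural")
    miss <- rows[!mask[, j]]
    out[miss, j] <- f(miss)
  }
  if (any(need_col_pass)) {
    have <- which(!need_col_pass)
    if (length(have) < 2L) stop("insufficient support: fewer than two columns carry data")
    for (k in seq_len(na)) {
      f <- splinefun(have, out[k, have], method = "natural")
      out[k, need_col_pass] <- f(which(need_col_pass))
    }
  }
  out
}

# Local bicubic least-squares stencils on the cycloidal sampling lattice.
# For each column-residue class r = (j - offset - k shift) mod p != 0, the
# relative positions of nearby acquired samples are identical for every
# missing pixel, so one weight vector per class (exact for cubic surfaces)
# serves all of them. `base` supplies the border band where stencils would
# leave the sinogram.
lattice_cubic_fill <- function(v, base, plan, R = 5L, sigma = 2) {
  p <- plan$period; shift <- plan$shift_per_angle; off <- plan$initial_offset
  na <- nrow(v); nc <- ncol(v)
  out <- base
  jr <- as.integer(R + p - 1)  # stencil reach along columns
  offs <- expand.grid(dk = -R:R, dj = -jr:jr)
  offs <- offs[offs$dk^2 + offs$dj^2 <= (R + 2)^2, ]
  tk <- rep(seq_len(na), times = nc)
  tj <- rep(seq_len(nc), each = na)
  cls_all <- ((tj - 1L) - off - shift * (tk - 1L)) %% p
  interior <- tk > R & tk <= na - R & tj > jr & tj <= nc - jr
  basis <- function(x, y) {
    cbind(1, x, y, x^2, x * y, y^2, x^3, x^2 * y, x * y^2, y^3)
  }
  for (r in seq_len(p - 1L)) {
    st <- offs[((offs$dj - shift * offs$dk) %% p) == ((p - r) %% p), ]
    if (nrow(st) < 12L) next
    W <- exp(-(st$dk^2 + st$dj^2) / (2 * sigma^2))
    P <- basis(st$dk, st$dj)
    wvec <- tryCatch(
      W * (P %*% solve(t(P) %*% (W * P), c(1, rep(0, ncol(P) - 1L)))),
      error = function(e) NULL)  # degenerate stencil: keep the spline fill
    if (is.null(wvec)) next
    sel <- which(cls_all == r & interior)
    if (!length(sel)) next
    acc <- numeric(length(sel))
    for (i in seq_len(nrow(st))) {
      acc <- acc + wvec[i] * v[cbind(tk[sel] + st$dk[i], tj[sel] + st$dj[i])]
    }
    out[sel] <- acc
  }
  out
}

#' Nearest-neighbour completion of an incomplete sinogram
#'
#' Fills each missing entry with the value of the nearest acquired entry in
#' its column (along the angle axis), falling back to the nearest acquired
#' column within the row. A deliberately crude reference against which spline
#' completion is compared.
#'
#' @inheritParams bicubic_interpolate
#' @return a complete `sinogram`.
#' @export
nearest_interpolate <- function(incomplete, pattern) {
  stopifnot(inherits(incomplete, "sinogram"),
            inherits(pattern, "sampling_pattern"))
  v <- incomplete$values
  mask <- pattern$mask
  out <- v
  na <- nrow(v)
  rows <- seq_len(na)
  for (j in seq_len(ncol(v))) {
    kn <- which(mask[, j])
    if (!length(kn)) next
    if (length(kn) == na) next
    nearest <- kn[pmax(1L, findInterval(rows + 0.5, kn + 0.5) ) ]
    # findInterval gives the last knot <= row; compare with the next knot
    nxt <- kn[pmin(length(kn), findInterval(rows + 0.5, kn + 0.5) + 1L)]
    use_next <- abs(nxt - rows) < abs(nearest - rows)
    pick <- ifelse(use_next, nxt, nearest)
    out[, j] <- v[pick, j]
    out[kn, j] <- v[kn, j]
  }
  empty <- which(colSums(mask) == 0L)
  if (length(empty)) {
    have <- which(colSums(mask) > 0L)
    for (j in empty) out[, j] <- out[, have[which.min(abs(have - j))]]
  }
  res <- incomplete
  res$values <- out
  res
}
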