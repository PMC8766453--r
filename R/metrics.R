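#' Peak signal-to-noise ratio
#'
#' \eqn{10 \log_{10}(peak^2 / MSE)} where the peak defaults to the maximum of
#' the reference image (the ground truth); the second argument is the
#' reference. Identical images yield `Inf` with a message.
#'
#' @param image image under test (matrix, `recon_image` or `voxel_slice`).
#' @param reference reference image, same shape.
#' @param peak peak value convention; default `max(reference)`.
#' @return PSNR in decibels.
#' @export
psnr <- function(image, reference, peak = NULL) {
  a <- as_image_matrix(image); b <- as_image_matrix(reference)
  stopifnot(all(dim(a) == dim(b)))
  if (is.null(peak)) peak <- max(b)
  mse <- mean((a - b)^2)
  if (mse == 0) {
    message("images are identical: PSNR is infinite")
    return(Inf)
  }
  10 * log10(peak^2 / mse)
}

#' Threshold segmentation of a grayscale image
#'
#' @param image image to segment.
#' @param method `"fixed"` (threshold `t`), `"otsu"` (Otsu's method via
#'   EBImage), or `"sweep"` (the threshold maximizing Dice against
#'   `reference` over `n_sweep` quantile candidates).
#' @param t threshold for `method = "fixed"`.
#' @param reference logical reference mask for `method = "sweep"`.
#' @param n_sweep number of candidate thresholds for the sweep.
#' @return logical matrix (`TRUE` = foreground, i.e. value above threshold).
#' @export
threshold_segment <- function(image, method = c("fixed", "otsu", "sweep"),
                              t = NULL, reference = NULL, n_sweep = 64L) {
  method <- match.arg(method)
  img <- as_image_matrix(image)
  stopifnot(all(is.finite(img)))
  if (method == "fixed") {
    stopifnot(!is.null(t))
    return(img > t)
  }
  if (method == "otsu") {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("method 'otsu' requires the EBImage package")
    }
    rng <- range(img)
    if (rng[1] == rng[2]) return(img > rng[1])
    scaled <- (img - rng[1]) / (rng[2] - rng[1])
    th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    return(scaled > th)
  }
  # sweep: maximize Dice against the reference mask
  stopifnot(is.logical(reference), all(dim(reference) == dim(img)))
  cand <- unique(stats::quantile(img, probs = seq(0.01, 0.99,
                                                  length.out = n_sweep),
                                 names = FALSE))
  scores <- vapply(cand, function(tt) dice(img > tt, reference), numeric(1))
  img > cand[which.max(scores)]
}

#' Dice similarity coefficient of two binary masks
#'
#' \eqn{2 |a \cap b| / (|a| + |b|)}; symmetric; defined as 1 when both masks
#' are empty.
#'
#' @param a,b logical matrices of equal shape.
#' @return overlap fraction in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(is.logical(a), is.logical(b), all(dim(a) == dim(b)))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

# 11x11 Gaussian window, sigma 1.5 (the standard SSIM window)
ssim_window <- function(size = 11L, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

# 'valid' 2-D correlation with a separable-symmetric window via two passes
filter_valid <- function(m, w1d) {
  k <- length(w1d)
  nr <- nrow(m) - k + 1L; nc <- ncol(m) - k + 1L
  tmp <- matrix(0, nr, ncol(m))
  for (i in seq_len(k)) tmp <- tmp + w1d[i] * m[i:(i + nr - 1L), , drop = FALSE]
  out <- matrix(0, nr, nc)
  for (i in seq_len(k)) out <- out + w1d[i] * tmp[, i:(i + nc - 1L), drop = FALSE]
  out
}

# single-scale SSIM: returns mean luminance term and mean contrast-structure
ssim_components <- function(x, y, data_range, k1 = 0.01, k2 = 0.03,
                            size = 11L, sigma = 1.5) {
  c1 <- (k1 * data_range)^2
  c2 <- (k2 * data_range)^2
  g <- seq_len(size) - (size + 1) / 2
  w <- exp(-g^2 / (2 * sigma^2)); w <- w / sum(w)
  mx <- filter_valid(x, w); my <- filter_valid(y, w)
  sxx <- filter_valid(x * x, w) - mx^2
  syy <- filter_valid(y * y, w) - my^2
  sxy <- filter_valid(x * y, w) - mx * my
  l <- (2 * mx * my + c1) / (mx^2 + my^2 + c1)
  cs <- (2 * sxy + c2) / (sxx + syy + c2)
  list(l = mean(l), cs = mean(cs), ssim = mean(l * cs))
}

# 2x2 average-pooling downsample (odd trailing row/column dropped)
downsample2 <- function(m) {
  nr <- nrow(m) %/% 2L; nc <- ncol(m) %/% 2L
  m <- m[seq_len(2L * nr), seq_len(2L * nc), drop = FALSE]
  0.25 * (m[seq(1, 2 * nr, 2), seq(1, 2 * nc, 2)] +
          m[seq(2, 2 * nr, 2), seq(1, 2 * nc, 2)] +
          m[seq(1, 2 * nr, 2), seq(2, 2 * nc, 2)] +
          m[seq(2, 2 * nr, 2), seq(2, 2 * nc, 2)])
}

#' Single-scale structural similarity index
#'
#' Standard SSIM with an 11x11 Gaussian window (sigma 1.5); the second
#' argument is the reference and sets the data range.
#'
#' @param image,reference images of equal shape.
#' @param data_range dynamic range (default: max of the reference).
#' @return mean SSIM over the valid window positions.
#' @export
ssim <- function(image, reference, data_range = NULL) {
  a <- as_image_matrix(image); b <- as_image_matrix(reference)
  stopifnot(all(dim(a) == dim(b)))
  if (is.null(data_range)) data_range <- max(b)
  ssim_components(a, b, data_range)$ssim
}

#' Multiscale structural similarity index
#'
#' Five-scale MS-SSIM with the canonical per-scale weights
#' (0.0448, 0.2856, 0.3001, 0.2363, 0.1333): contrast-structure terms on
#' every scale, the luminance term on the coarsest, each image downsampled by
#' 2x2 mean pooling between scales. If the images are too small for the
#' requested number of scales (coarsest side < 11), the scale count is
#' reduced with a warning and the weights renormalized. Negative
#' contrast-structure means are clamped at zero, so strongly anti-correlated
#' images score ~0.
#'
#' @param image,reference images of equal shape; the second argument is the
#'   reference and sets the data range.
#' @param scales number of dyadic scales (default 5).
#' @param data_range dynamic range (default: max of the reference).
#' @return similarity in \[0, 1\].
#' @export
ms_ssim <- function(image, reference, scales = 5L, data_range = NULL) {
  a <- as_image_matrix(image); b <- as_image_matrix(reference)
  stopifnot(all(dim(a) == dim(b)))
  if (is.null(data_range)) data_range <- max(b)
  weights <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)[seq_len(scales)]
  max_scales <- max(1L, floor(log2(min(dim(a)) / 11)) + 1L)
  if (scales > max_scales) {
    warning(sprintf("images support only %d dyadic scales (requested %d)",
                    max_scales, scales))
    scales <- max_scales
    weights <- weights[seq_len(scales)]
  }
  weights <- weights / sum(weights)
  terms <- numeric(scales)
  for (s in seq_len(scales)) {
    comp <- ssim_components(a, b, data_range)
    terms[s] <- if (s == scales) comp$l * comp$cs else comp$cs
    if (s < scales) { a <- downsample2(a); b <- downsample2(b) }
  }
  terms <- pmax(terms, 0)
  prod(terms^weights)
}

#' Assemble a metric report row
#'
#' The machine-readable analogue of a dose-comparison table row: method
#' label, dose fraction and the three image-quality metrics of a
#' reconstruction against the ground truth.
#'
#' @param label method name.
#' @param recon reconstruction (`recon_image` or matrix).
#' @param reference ground-truth image.
#' @param dose_percent dose fraction in percent (see [dose_fraction()]).
#' @param seg_threshold threshold for the Dice segmentation (default: half
#'   the reference maximum, the midpoint of the two-material phantom).
#' @param ms_ssim_scales dyadic scales for MS-SSIM.
#' @return one-row data.frame: method, dose_percent, psnr_db, dice, ms_ssim.
#' @export
metric_report <- function(label, recon, reference, dose_percent,
                          seg_threshold = NULL, ms_ssim_scales = 5L) {
  img <- as_image_matrix(recon)
  ref <- as_image_matrix(reference)
  if (is.null(seg_threshold)) seg_threshold <- max(ref) / 2
  data.frame(method = label,
             dose_percent = dose_percent,
             psnr_db = psnr(img, ref),
             dice = dice(img > seg_threshold, ref > seg_threshold),
             ms_ssim = ms_ssim(img, ref, scales = ms_ssim_scales),
             stringsAsFactors = FALSE)
}
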