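#' Mixed-Scale Dense network configuration
#'
#' An MS-D network has one channel per layer. Layer \eqn{i} applies a dilated
#' 3x3 convolution (dilation cycling through `dilations`) to the input image
#' and to every previous layer's output, sums, adds a scalar bias and a ReLU.
#' The output is a learned 1x1 linear combination of the input and all layer
#' outputs plus a bias, so any image size can be processed whole — the
#' property that makes this architecture practical for large sinograms and
#' very small training sets.
#'
#' @param depth number of layers L.
#' @param dilations integer dilation cycle; layer i uses
#'   `dilations[((i - 1) %% length(dilations)) + 1]`.
#' @param seed integer seed for parameter initialization.
#' @return an object of class `msd_config`.
#' @export
msd_config <- function(depth = 100L, dilations = 1:10, seed = 1L) {
  stopifnot(depth >= 1, all(dilations >= 1))
  structure(list(depth = as.integer(depth), dilations = as.integer(dilations),
                 seed = as.integer(seed)),
            class = "msd_config")
}

#' Number of learnable parameters of an MS-D configuration
#'
#' Closed form for width-1, single-channel input:
#' \eqn{\sum_{i=1}^{L} (9 i + 1) + (L + 1) + 1} — per layer one 3x3 kernel
#' per incoming channel plus a bias, then L + 1 final weights and one final
#' bias.
#'
#' @param config an [msd_config()].
#' @return integer parameter count.
#' @export
msd_count_parameters <- function(config) {
  L <- config$depth
  as.integer(sum(9 * seq_len(L) + 1) + (L + 1) + 1)
}

#' Initialize MS-D parameters
#'
#' Convolution weights are drawn zero-mean Gaussian with variance
#' \eqn{2 / n_{in}}, where \eqn{n_{in} = 9 \times} (number of incoming
#' channels of the layer) is the number of incoming values per output pixel
#' (He-style scaling for ReLU). Biases and all final-map weights start at
#' zero, so the freshly initialized network outputs exactly zero everywhere.
#'
#' @param config an [msd_config()].
#' @return a flat numeric parameter vector (see [msd_unflatten_params()] for
#'   the structured view).
#' @export
msd_init_parameters <- function(config) {
  stopifnot(inherits(config, "msd_config"))
  local_seed(config$seed)
  L <- config$depth
  par <- numeric(msd_count_parameters(config))
  off <- 0L
  for (i in seq_len(L)) {
    nw <- 9L * i
    par[off + seq_len(nw)] <- rnorm(nw, sd = sqrt(2 / nw))
    # bias at off + nw + 1 stays 0
    off <- off + nw + 1L
  }
  # final weights and bias stay 0
  par
}

#' Structured view of a flat MS-D parameter vector
#'
#' @param params flat parameter vector.
#' @param config the matching [msd_config()].
#' @return list with `layers` (per layer: `kernels`, a 3 x 3 x i array, and
#'   `bias`), `final_weights` (length L + 1) and `final_bias`.
#' @export
msd_unflatten_params <- function(params, config) {
  L <- config$depth
  stopifnot(length(params) == msd_count_parameters(config))
  off <- 0L
  layers <- vector("list", L)
  for (i in seq_len(L)) {
    nw <- 9L * i
    layers[[i]] <- list(kernels = array(params[off + seq_len(nw)], c(3, 3, i)),
                        bias = params[off + nw + 1L])
    off <- off + nw + 1L
  }
  list(layers = layers,
       final_weights = params[off + seq_len(L + 1L)],
       final_bias = params[off + L + 2L])
}

#' @rdname msd_unflatten_params
#' @param structured a structured parameter list.
#' @export
msd_flatten_params <- function(structured, config) {
  L <- config$depth
  par <- numeric(msd_count_parameters(config))
  off <- 0L
  for (i in seq_len(L)) {
    nw <- 9L * i
    par[off + seq_len(nw)] <- as.numeric(structured$layers[[i]]$kernels)
    par[off + nw + 1L] <- structured$layers[[i]]$bias
    off <- off + nw + 1L
  }
  par[off + seq_len(L + 1L)] <- structured$final_weights
  par[off + L + 2L] <- structured$final_bias
  par
}

#' MS-D forward pass
#'
#' Fully convolutional: accepts any H x W matrix, returns a matrix of the
#' same shape (zero padding in the dilated convolutions).
#'
#' @param x input image (finite numeric matrix).
#' @param params flat parameter vector.
#' @param config the matching [msd_config()].
#' @return output image, same shape as `x`.
#' @export
msd_forward <- function(x, params, config) {
  stopifnot(is.matrix(x), inherits(config, "msd_config"))
  if (!all(is.finite(x))) stop("non-finite input image")
  stopifnot(length(params) == msd_count_parameters(config))
  msd_forward_cpp(x, params, config$depth, config$dilations)
}

#' Masked loss and gradient of an MS-D network
#'
#' Computes the sum of squared differences between the network output on `x`
#' and `target`, restricted to the pixels where `defined` is `TRUE`, together
#' with its gradient with respect to every parameter (reverse-mode, exact).
#'
#' @param x input image.
#' @param target target image (values needed only where `defined`).
#' @param defined logical matrix of supervised pixels.
#' @param params flat parameter vector.
#' @param config the matching [msd_config()].
#' @return list with `loss`, `grad` (flat, same length as `params`) and
#'   `n_defined`.
#' @export
msd_loss_grad <- function(x, target, defined, params, config) {
  stopifnot(all(dim(x) == dim(target)), all(dim(x) == dim(defined)))
  if (!any(defined)) stop("empty supervision domain: no defined target pixels")
  tgt <- target
  tgt[!defined] <- 0  # values outside the domain must not matter (nor be NA)
  msd_loss_grad_cpp(x, tgt, defined, params, config$depth, config$dilations)
}

#' Save / load an MS-D model checkpoint
#'
#' The checkpoint carries the configuration, the flat parameter vector, the
#' input/target normalization constants and the training log; the round trip
#' is bit-exact.
#'
#' @param model an `msd_model` (see [msd_train()]).
#' @param path file path (`.rds`).
#' @return `path`, invisibly.
#' @export
write_msd_model <- function(model, path) {
  stopifnot(inherits(model, "msd_model"))
  saveRDS(model, path, version = 3)
  invisible(path)
}

#' @rdname write_msd_model
#' @export
read_msd_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "msd_model"))
  model
}
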