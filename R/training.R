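#' Masked sum-of-squares loss over the measured pixels
#'
#' The in-scan training loss: the sum of squared differences between a
#' predicted sinogram and a partial sinogram target, restricted to the
#' pixels where the partial sinogram carries a measurement. Pixels outside
#' the measured domain contribute nothing.
#'
#' @param pred predicted image (numeric matrix).
#' @param target a [extract_partial()] `partial_sinogram`, or a list with
#'   `values` and logical `defined` of matching shape.
#' @param normalize if `TRUE`, divide by the number of defined pixels (for
#'   reporting across sinograms); optimization uses the raw sum.
#' @return nonnegative scalar.
#' @export
masked_loss <- function(pred, target, normalize = FALSE) {
  stopifnot(all(dim(pred) == dim(target$values)))
  d <- target$defined
  if (!any(d)) stop("empty supervision domain: target defines no pixels")
  s <- sum((pred[d] - target$values[d])^2)
  if (normalize) s / sum(d) else s
}

#' Deterministic train/validation split
#'
#' Disjoint, exhaustive split of `1:n` with `round(train_fraction * n)`
#' training indices, drawn uniformly at random under the given seed.
#'
#' @param n number of items (>= 1).
#' @param train_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @return list with sorted integer vectors `train` and `val`.
#' @export
split_train_val <- function(n, train_fraction = 0.9, seed = 1L) {
  stopifnot(n >= 1, train_fraction > 0, train_fraction < 1)
  local_seed(seed)
  n_train <- round(train_fraction * n)
  tr <- sort(sample.int(n, n_train))
  list(train = tr, val = setdiff(seq_len(n), tr))
}

#' Training configuration for in-scan MS-D training
#'
#' @param epochs epoch budget (0 returns the initial parameters untouched).
#' @param learning_rate ADAM step size.
#' @param train_fraction fraction of sinograms used for parameter updates;
#'   the rest monitor validation loss for checkpoint selection.
#' @param max_seconds optional wall-clock budget; training stops after the
#'   first epoch that exceeds it (whichever of epochs/wall-clock comes first).
#' @param seed integer seed (split and per-epoch shuffling).
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 50L, learning_rate = 0.001,
                         train_fraction = 0.9, max_seconds = Inf, seed = 1L) {
  stopifnot(epochs >= 0, learning_rate > 0,
            train_fraction > 0, train_fraction < 1, max_seconds > 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 train_fraction = train_fraction, max_seconds = max_seconds,
                 seed = as.integer(seed)),
            class = "train_config")
}

as_image_list <- function(x) {
  if (is.matrix(x)) return(list(x))
  lapply(x, function(e) if (inherits(e, "sinogram")) e$values else e)
}

#' Train an MS-D network on interpolated/partial sinogram pairs
#'
#' In-scan supervised training: inputs are the interpolated incomplete
#' sinograms, targets the partial sinograms holding the dithered training
#' projections. One ADAM step is taken per training sinogram (images are
#' processed whole, no patching), sinogram order is reshuffled every epoch,
#' and after each epoch the mean per-pixel masked loss on the validation
#' subset is evaluated; the parameters with the lowest validation loss within
#' the budget are returned. Inputs and targets are standardized to zero mean
#' and unit variance (statistics stored in the model and undone on
#' application).
#'
#' @param inputs list of input images (matrices or `sinogram`s).
#' @param targets list of `partial_sinogram` targets (same length/shapes).
#' @param config an [msd_config()].
#' @param cfg a [train_config()].
#' @param params0 optional initial flat parameter vector (default:
#'   [msd_init_parameters()] under the config seed).
#' @param verbose print per-epoch losses.
#' @return an object of class `msd_model`: list with `config`, `params`
#'   (checkpoint with minimal validation loss), `normalization`, `log`
#'   (data.frame: epoch, train_loss, val_loss, wall_time), `best_epoch`,
#'   `split`.
#' @export
msd_train <- function(inputs, targets, config, cfg = train_config(),
                      params0 = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "msd_config"), inherits(cfg, "train_config"))
  X <- as_image_list(inputs)
  stopifnot(length(X) == length(targets), length(X) >= 1)
  for (i in seq_along(X)) {
    if (!any(targets[[i]]$defined)) {
      stop(sprintf("target %d has an empty supervision domain", i))
    }
  }
  n <- length(X)
  split <- if (n >= 2) {
    split_train_val(n, cfg$train_fraction, seed = cfg$seed)
  } else {
    list(train = 1L, val = integer(0))
  }

  # normalization statistics from the training subset
  xs <- unlist(lapply(X[split$train], as.numeric))
  ys <- unlist(lapply(split$train, function(i) {
    targets[[i]]$values[targets[[i]]$defined]
  }))
  norm <- list(x_mean = mean(xs), x_sd = max(sd(xs), 1e-12),
               y_mean = mean(ys), y_sd = max(sd(ys), 1e-12))
  Xn <- lapply(X, function(m) (m - norm$x_mean) / norm$x_sd)
  Yn <- lapply(targets, function(tg) {
    v <- (tg$values - norm$y_mean) / norm$y_sd
    v[!tg$defined] <- 0
    list(values = v, defined = tg$defined)
  })

  par <- if (is.null(params0)) msd_init_parameters(config) else params0
  stopifnot(length(par) == msd_count_parameters(config))

  val_loss_of <- function(p, idx) {
    if (!length(idx)) return(NA_real_)
    mean(vapply(idx, function(i) {
      out <- msd_forward_cpp(Xn[[i]], p, config$depth, config$dilations)
      d <- Yn[[i]]$defined
      sum((out[d] - Yn[[i]]$values[d])^2) / sum(d)
    }, numeric(1)))
  }

  monitor <- if (length(split$val)) split$val else split$train
  best <- list(params = par, loss = val_loss_of(par, monitor), epoch = 0L)
  log <- data.frame(epoch = 0L, train_loss = NA_real_, val_loss = best$loss,
                    wall_time = 0)

  if (cfg$epochs > 0L) {
    m <- numeric(length(par)); v <- numeric(length(par)); tstep <- 0L
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    local_seed(cfg$seed + 1L)
    t0 <- proc.time()[["elapsed"]]
    for (ep in seq_len(cfg$epochs)) {
      ord <- split$train[sample.int(length(split$train))]
      ep_loss <- 0; ep_n <- 0
      for (i in ord) {
        lg <- msd_loss_grad_cpp(Xn[[i]], Yn[[i]]$values, Yn[[i]]$defined,
                                par, config$depth, config$dilations)
        if (!is.finite(lg$loss) || lg$loss > 1e30) {
          stop(sprintf("training diverged (loss %g at epoch %d)", lg$loss, ep))
        }
        ep_loss <- ep_loss + lg$loss; ep_n <- ep_n + lg$n_defined
        tstep <- tstep + 1L
        g <- lg$grad
        m <- b1 * m + (1 - b1) * g
        v <- b2 * v + (1 - b2) * g * g
        mh <- m / (1 - b1^tstep)
        vh <- v / (1 - b2^tstep)
        par <- par - cfg$learning_rate * mh / (sqrt(vh) + eps)
      }
      vl <- val_loss_of(par, monitor)
      wt <- proc.time()[["elapsed"]] - t0
      log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / ep_n,
                                   val_loss = vl, wall_time = wt))
      if (verbose) {
        message(sprintf("epoch %3d  train %.5g  val %.5g  (%.1fs)",
                        ep, ep_loss / ep_n, vl, wt))
      }
      if (is.finite(vl) && vl < best$loss) {
        best <- list(params = par, loss = vl, epoch = ep)
      }
      if (wt > cfg$max_seconds) break
    }
  }

  structure(list(config = config, params = best$params,
                 normalization = norm, log = log,
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 split = split, train_cfg = cfg),
            class = "msd_model")
}

#' @export
print.msd_model <- function(x, ...) {
  cat(sprintf(paste0("<msd_model> depth %d, %d parameters, best epoch %d ",
                     "(val loss %.5g over %d epochs)\n"),
              x$config$depth, msd_count_parameters(x$config), x$best_epoch,
              x$best_val_loss, nrow(x$log)))
  invisible(x)
}

#' Apply a trained MS-D model to sinograms
#'
#' Normalizes with the model's stored statistics, runs the forward pass and
#' de-normalizes the output. Deterministic; shapes are preserved.
#'
#' @param model an `msd_model`.
#' @param sinograms a matrix, a `sinogram`, or a list of either.
#' @return restored image(s), matching the input container: matrices in,
#'   matrices out; `sinogram`s in, `sinogram`s out.
#' @export
msd_apply <- function(model, sinograms) {
  stopifnot(inherits(model, "msd_model"))
  one <- function(x) {
    sino_in <- inherits(x, "sinogram")
    m <- if (sino_in) x$values else x
    if (anyNA(m)) stop("cannot apply model to a sinogram with missing entries")
    nz <- model$normalization
    out <- msd_forward_cpp((m - nz$x_mean) / nz$x_sd, model$params,
                           model$config$depth, model$config$dilations)
    out <- out * nz$y_sd + nz$y_mean
    if (sino_in) { x$values <- out; x } else out
  }
  if (is.matrix(sinograms) || inherits(sinograms, "sinogram")) {
    one(sinograms)
  } else {
    lapply(sinograms, one)
  }
}

#' Write a training log as CSV
#' @param model an `msd_model`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(model, path) {
  write.csv(model$log, path, row.names = FALSE)
  invisible(path)
}
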