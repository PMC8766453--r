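test_that("parameter counts follow the dense-connection closed form", {
  expect_identical(msd_count_parameters(msd_config(depth = 1)), 13L)
  expect_identical(msd_count_parameters(msd_config(depth = 100)), 45652L)
  cfg <- msd_config(depth = 7, dilations = 1:3)
  p <- msd_init_parameters(cfg)
  expect_length(p, msd_count_parameters(cfg))
  # structural equality: flatten(unflatten(p)) == p
  expect_identical(msd_flatten_params(msd_unflatten_params(p, cfg), cfg), p)
})

test_that("degenerate parameter settings give constant and identity maps", {
  cfg <- msd_config(depth = 3, dilations = c(1L, 2L))
  st <- msd_unflatten_params(numeric(msd_count_parameters(cfg)), cfg)
  st$final_bias <- 2.5
  x <- matrix(rnorm(20 * 12), 20, 12)
  out <- msd_forward(x, msd_flatten_params(st, cfg), cfg)
  expect_true(all(out == 2.5))

  st$final_bias <- 0
  st$final_weights[1] <- 1  # weight on the input channel
  out2 <- msd_forward(x, msd_flatten_params(st, cfg), cfg)
  expect_equal(out2, x, tolerance = 1e-14)
})

test_that("forward pass matches a brute-force nested-loop oracle", {
  cfg <- msd_config(depth = 2, dilations = c(1L, 2L), seed = 3)
  set.seed(31)
  p <- rnorm(msd_count_parameters(cfg))
  x <- matrix(rnorm(64), 8, 8)
  st <- msd_unflatten_params(p, cfg)
  convd <- function(img, K, d) {
    H <- nrow(img); W <- ncol(img); o <- matrix(0, H, W)
    for (r in 1:H) for (c in 1:W) {
      acc <- 0
      for (u in -1:1) for (v in -1:1) {
        rr <- r + u * d; cc <- c + v * d
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W) {
          acc <- acc + K[u + 2, v + 2] * img[rr, cc]
        }
      }
      o[r, c] <- acc
    }
    o
  }
  chan <- list(x)
  for (i in 1:2) {
    d <- cfg$dilations[(i - 1) %% 2 + 1]
    a <- matrix(st$layers[[i]]$bias, 8, 8)
    for (cc in 1:i) a <- a + convd(chan[[cc]], st$layers[[i]]$kernels[, , cc], d)
    chan[[i + 1]] <- pmax(a, 0)
  }
  ref <- matrix(st$final_bias, 8, 8)
  for (cc in 1:3) ref <- ref + st$final_weights[cc] * chan[[cc]]
  out <- msd_forward(x, p, cfg)
  expect_lt(max(abs(out - ref)) / max(abs(ref)), 1e-5)
})

test_that("initialization scales variance with fan-in and is reproducible", {
  # aggregate layer-1 (fan-in 9) and layer-50 (fan-in 450) weights over seeds
  w1 <- c(); w50 <- c()
  for (s in 1:40) {
    cfg <- msd_config(depth = 50, dilations = 1:10, seed = s)
    st <- msd_unflatten_params(msd_init_parameters(cfg), cfg)
    w1 <- c(w1, as.numeric(st$layers[[1]]$kernels))
    w50 <- c(w50, as.numeric(st$layers[[50]]$kernels))
    if (s == 1) {
      expect_true(all(vapply(st$layers, function(l) l$bias == 0, logical(1))))
      expect_true(all(st$final_weights == 0))
      # zero final weights: initial output is identically zero
      expect_true(all(msd_forward(matrix(rnorm(64), 8, 8),
                                  msd_init_parameters(cfg), cfg) == 0))
    }
  }
  expect_lt(abs(var(w1) / var(w50) - 50) / 50, 0.1)
  cfgA <- msd_config(depth = 5, seed = 9)
  expect_identical(msd_init_parameters(cfgA), msd_init_parameters(cfgA))
})

test_that("the network is fully convolutional and shift-consistent on constants", {
  cfg <- msd_config(depth = 4, dilations = 1:2, seed = 2)
  p <- msd_init_parameters(cfg)
  st <- msd_unflatten_params(p, cfg)
  st$final_weights[] <- rnorm(5, sd = 0.3)
  p <- msd_flatten_params(st, cfg)
  small <- msd_forward(matrix(1, 24, 24), p, cfg)
  large <- msd_forward(matrix(1, 48, 48), p, cfg)
  # interior values (away from the zero-padding halo) coincide
  expect_equal(small[12, 12], large[24, 24], tolerance = 1e-12)
  expect_equal(small[12, 13], large[30, 17], tolerance = 1e-12)
})

test_that("autodiff gradients match finite differences", {
  cfg <- msd_config(depth = 3, dilations = c(1L, 2L, 4L), seed = 5)
  set.seed(6)
  p <- rnorm(msd_count_parameters(cfg), sd = 0.3)
  x <- matrix(rnorm(256), 16, 16)
  y <- matrix(rnorm(256), 16, 16)
  def <- matrix(runif(256) > 0.4, 16, 16)
  lg <- msd_loss_grad(x, y, def, p, cfg)
  idx <- sample(length(p), 20)
  for (k in idx) {
    e <- 1e-6
    pp <- p; pp[k] <- pp[k] + e
    pm <- p; pm[k] <- pm[k] - e
    fd <- (msd_loss_grad(x, y, def, pp, cfg)$loss -
           msd_loss_grad(x, y, def, pm, cfg)$loss) / (2 * e)
    expect_lt(abs(fd - lg$grad[k]) / (abs(fd) + 1e-6), 1e-4)
  }
})

test_that("model checkpoints round-trip bit-exactly", {
  cfg <- msd_config(depth = 3, seed = 4)
  model <- structure(list(config = cfg, params = msd_init_parameters(cfg),
                          normalization = list(x_mean = 0.1, x_sd = 2,
                                               y_mean = -1, y_sd = 0.5),
                          log = data.frame(epoch = 0L, train_loss = NA_real_,
                                           val_loss = 1, wall_time = 0),
                          best_epoch = 0L, best_val_loss = 1,
                          split = list(train = 1L, val = integer(0))),
                     class = "msd_model")
  f <- withr::local_tempfile(fileext = ".rds")
  write_msd_model(model, f)
  expect_identical(read_msd_model(f), model)
})
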