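toy_partial <- function(values, defined) list(values = values, defined = defined)

test_that("masked loss sums squared errors over exactly the measured domain", {
  set.seed(1)
  pred <- matrix(rnorm(100), 10, 10)
  target <- matrix(rnorm(100), 10, 10)
  d <- matrix(runif(100) > 0.5, 10, 10)

  expect_equal(masked_loss(target, toy_partial(target, d)), 0)

  one <- matrix(FALSE, 10, 10); one[3, 4] <- TRUE
  shifted <- target; shifted[3, 4] <- target[3, 4] + 0.37
  expect_equal(masked_loss(shifted, toy_partial(target, one)), 0.37^2)

  # full domain equals a naive double loop
  naive <- 0
  for (i in 1:10) for (j in 1:10) naive <- naive + (pred[i, j] - target[i, j])^2
  expect_equal(masked_loss(pred, toy_partial(target, matrix(TRUE, 10, 10))),
               naive)

  expect_error(masked_loss(pred, toy_partial(target, matrix(FALSE, 10, 10))),
               "empty")
})

test_that("pixels outside the domain never influence the masked loss", {
  set.seed(2)
  pred <- matrix(rnorm(64), 8, 8)
  target <- matrix(rnorm(64), 8, 8)
  d <- matrix(runif(64) > 0.6, 8, 8)
  ref <- masked_loss(pred, toy_partial(target, d))
  for (i in 1:20) {
    fuzz <- pred
    fuzz[!d] <- fuzz[!d] + rnorm(sum(!d), sd = 10)
    expect_identical(masked_loss(fuzz, toy_partial(target, d)), ref)
  }
  # and the same restriction holds for the network loss/gradient
  cfg <- msd_config(depth = 2, seed = 1)
  p <- msd_init_parameters(cfg)
  x <- matrix(rnorm(64), 8, 8)
  base <- msd_loss_grad(x, target, d, p, cfg)
  t2 <- target; t2[!d] <- 99
  again <- msd_loss_grad(x, t2, d, p, cfg)
  expect_identical(again$loss, base$loss)
  expect_identical(again$grad, base$grad)
})

test_that("train/validation splits are sized, disjoint and reproducible", {
  s <- split_train_val(1024, 0.9, seed = 5)
  expect_length(s$train, 922)
  expect_length(s$val, 102)
  expect_length(intersect(s$train, s$val), 0)
  expect_setequal(c(s$train, s$val), 1:1024)
  expect_identical(split_train_val(1024, 0.9, seed = 5), s)
  expect_false(identical(split_train_val(1024, 0.9, seed = 6)$train, s$train))
  s10 <- split_train_val(10, 0.9, seed = 1)
  expect_length(s10$train, 9)
  expect_length(s10$val, 1)
})

test_that("a zero-epoch budget returns the initial parameters", {
  cfg <- msd_config(depth = 2, seed = 7)
  x <- matrix(rnorm(64), 8, 8)
  tg <- toy_partial(x, matrix(TRUE, 8, 8))
  m <- msd_train(list(x), list(tg), cfg, train_config(epochs = 0))
  expect_identical(m$params, msd_init_parameters(cfg))
  expect_identical(m$best_epoch, 0L)
})

test_that("training learns the identity task to under 1% of the initial loss", {
  set.seed(3)
  x <- matrix(rnorm(64 * 64), 64, 64)
  tg <- toy_partial(x, matrix(TRUE, 64, 64))
  cfg <- msd_config(depth = 10, dilations = 1:3, seed = 1)
  m <- msd_train(list(x), list(tg), cfg,
                 train_config(epochs = 300, learning_rate = 0.005, seed = 2))
  expect_lt(m$best_val_loss, 0.01 * m$log$val_loss[m$log$epoch == 0])
  # the checkpoint is the argmin of the logged validation losses
  expect_equal(m$best_val_loss, min(m$log$val_loss))
  expect_true(all(m$best_val_loss <= m$log$val_loss))
})

test_that("gradients with a full domain equal plain sum-of-squares gradients", {
  cfg <- msd_config(depth = 2, seed = 4)
  set.seed(5)
  p <- rnorm(msd_count_parameters(cfg), sd = 0.3)
  x <- matrix(rnorm(144), 12, 12)
  y <- matrix(rnorm(144), 12, 12)
  lg <- msd_loss_grad(x, y, matrix(TRUE, 12, 12), p, cfg)
  expect_equal(lg$loss, sum((msd_forward(x, p, cfg) - y)^2), tolerance = 1e-12)
  # spot-check against finite differences of the unmasked loss
  for (k in sample(length(p), 5)) {
    e <- 1e-6
    pp <- p; pp[k] <- pp[k] + e
    pm <- p; pm[k] <- pm[k] - e
    fd <- (sum((msd_forward(x, pp, cfg) - y)^2) -
           sum((msd_forward(x, pm, cfg) - y)^2)) / (2 * e)
    expect_lt(abs(fd - lg$grad[k]) / (abs(fd) + 1e-6), 1e-4)
  }
})

test_that("seeded training is reproducible and divergence is detected", {
  set.seed(6)
  xs <- lapply(1:4, function(i) matrix(rnorm(256), 16, 16))
  tgs <- lapply(xs, function(x) toy_partial(x, matrix(TRUE, 16, 16)))
  cfg <- msd_config(depth = 3, seed = 2)
  tc <- train_config(epochs = 3, seed = 9)
  m1 <- msd_train(xs, tgs, cfg, tc)
  m2 <- msd_train(xs, tgs, cfg, tc)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$log[c("epoch", "train_loss", "val_loss")],
                   m2$log[c("epoch", "train_loss", "val_loss")])

  expect_error(msd_train(xs, tgs, cfg, train_config(epochs = 1,
                                                    learning_rate = 1e12)),
               "diverged")
})

test_that("applying a model preserves shape and undoes normalization", {
  cfg <- msd_config(depth = 2, seed = 3)
  st <- msd_unflatten_params(numeric(msd_count_parameters(cfg)), cfg)
  st$final_weights[1] <- 1  # identity network
  model <- structure(list(config = cfg,
                          params = msd_flatten_params(st, cfg),
                          normalization = list(x_mean = 0, x_sd = 1,
                                               y_mean = 0, y_sd = 1)),
                     class = "msd_model")
  x <- matrix(rnorm(15 * 23), 15, 23)
  expect_equal(msd_apply(model, x), x, tolerance = 1e-14)
  # with non-trivial normalization the identity map rescales accordingly
  model$normalization <- list(x_mean = 2, x_sd = 4, y_mean = -1, y_sd = 0.5)
  expect_equal(msd_apply(model, x), ((x - 2) / 4) * 0.5 - 1, tolerance = 1e-12)
  # output can be re-fed (shape-idempotent) and sinograms stay sinograms
  expect_equal(dim(msd_apply(model, msd_apply(model, x))), dim(x))
  s <- as_sino(x)
  out <- msd_apply(model, s)
  expect_s3_class(out, "sinogram")
  expect_error(msd_apply(model, as_sino(matrix(NA_real_, 4, 4))), "missing")
})
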