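#' Derive a stage-specific seed from a global experiment seed
#'
#' Counter-based fan-out: each named stage gets an independent stream, so
#' changing one stage's seed leaves the others unchanged.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage = c("phantom", "noise", "noise_low",
                                        "init", "train", "tune")) {
  stage <- match.arg(stage)
  k <- match(stage, c("phantom", "noise", "noise_low", "init", "train", "tune"))
  as.integer((as.numeric(seed) * 97 + k * 10007) %% 2147483629)
}

#' Experiment configuration
#'
#' Bundles every stage's settings for an end-to-end run. All randomness fans
#' out from the single `seed` via [derive_seed()].
#'
#' @param phantom a [phantom_spec()] (its attenuation is recalibrated to
#'   `target_absorption` unless `calibrate = FALSE`).
#' @param geometry a [ct_geometry()].
#' @param plan the cycloidal [acquisition_plan()] (with `n_train` interleaved
#'   training projections).
#' @param msd an [msd_config()].
#' @param train a [train_config()].
#' @param n_slices number of axial slices simulated (the training set size).
#' @param slice_span slices are placed evenly in `[-slice_span, slice_span]`.
#' @param grid_n reconstruction grid side length.
#' @param incident_photons full-exposure photons per detector pixel.
#' @param target_absorption mean absorbed fraction the attenuation is
#'   calibrated to.
#' @param calibrate recalibrate the phantom attenuation (default TRUE).
#' @param supersample ground-truth rasterization supersampling.
#' @param seed global seed.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(phantom, geometry, plan, msd, train,
                              n_slices = 32L, slice_span = 0.35,
                              grid_n = geometry$n_cols,
                              incident_photons = 1000,
                              target_absorption = 0.5, calibrate = TRUE,
                              supersample = 4L, seed = 1L) {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(geometry, "ct_geometry"),
            inherits(plan, "acquisition_plan"), inherits(msd, "msd_config"),
            inherits(train, "train_config"), n_slices >= 1)
  structure(list(phantom = phantom, geometry = geometry, plan = plan,
                 msd = msd, train = train, n_slices = as.integer(n_slices),
                 slice_span = slice_span, grid_n = as.integer(grid_n),
                 incident_photons = incident_photons,
                 target_absorption = target_absorption, calibrate = calibrate,
                 supersample = as.integer(supersample),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Desk-scale experiment preset
#'
#' A scaled-down version of the full foam benchmark: 500-sphere phantom,
#' 128 x 128 detector/grid, 128 projections over 180 degrees, mask period 8
#' with aperture 1 and a 3-pixel shift per angle, 13 interleaved training
#' projections, a depth-30 MS-D network and a short ADAM budget. Runs in
#' minutes on one CPU.
#'
#' @param seed global seed.
#' @param epochs training epoch budget.
#' @param n_slices number of simulated slices.
#' @return an `experiment_config`.
#' @export
preset_tiny <- function(seed = 1L, epochs = 30L, n_slices = 32L) {
  experiment_config(
    phantom = phantom_spec(n_spheres = 500, cylinder_radius = 0.8,
                           radius_min = 0.01, radius_max = 0.12,
                           radius_exponent = 2.5, attenuation = 1,
                           z_half = 0.6, seed = derive_seed(seed, "phantom")),
    geometry = ct_geometry(n_angles = 128, n_cols = 128),
    plan = acquisition_plan("cycloidal", period = 8, aperture = 1,
                            shift_per_angle = 3, n_train = 13),
    msd = msd_config(depth = 30, dilations = 1:10,
                     seed = derive_seed(seed, "init")),
    train = train_config(epochs = epochs, learning_rate = 0.001,
                         train_fraction = 0.9,
                         seed = derive_seed(seed, "train")),
    n_slices = n_slices, grid_n = 128,
    incident_photons = 1000, target_absorption = 0.5,
    seed = seed)
}

slice_positions <- function(config) {
  n <- config$n_slices
  if (n == 1L) return(0)
  seq(-config$slice_span, config$slice_span, length.out = n)
}

ms_scales_for <- function(grid_n) {
  max(1L, min(5L, floor(log2(grid_n / 11)) + 1L))
}

# Simulate the shared study inputs: phantom, calibrated attenuation,
# noiseless sinograms for every slice, full-dose noisy sinograms (the frames
# a dithered scan would record), and the central-slice ground truth.
simulate_study <- function(config, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("[phantom] placing %d spheres", config$phantom$n_spheres)
  spheres <- generate_phantom(config$phantom)
  if (config$calibrate) {
    mu <- calibrate_attenuation(spheres, config$geometry,
                                config$target_absorption, z = 0)
    spheres$spec$attenuation <- mu
    say("[phantom] calibrated attenuation mu = %.4f", mu)
  }
  zs <- slice_positions(config)
  central <- which.min(abs(zs))
  say("[project] %d slices x %d angles", length(zs), config$geometry$n_angles)
  noiseless <- lapply(zs, function(z) project_analytic(spheres, config$geometry, z))
  noisy <- lapply(seq_along(zs), function(i) {
    apply_counting_noise(noiseless[[i]],
                         noise_model(config$incident_photons,
                                     seed = derive_seed(config$seed, "noise") + i))
  })
  truth <- rasterize_slice(spheres, zs[central], config$grid_n,
                           config$supersample)
  list(spheres = spheres, zs = zs, central = central,
       noiseless = noiseless, noisy = noisy, truth = truth)
}

#' Run the in-scan cycloidal training pipeline end to end
#'
#' The full chain: phantom generation, analytic projection, counting noise,
#' cycloidal masking with interleaved training projections, cubic-spline
#' interpolation, in-scan MS-D training on (interpolated, partial) pairs,
#' application of the trained network, FBP reconstruction of the central
#' slice, and metric evaluation against the rasterized ground truth.
#'
#' @param config an [experiment_config()].
#' @param out_dir optional directory for stage artifacts; stages found there
#'   are reloaded instead of recomputed, so a run is resumable from any
#'   stage (delete downstream artifacts to redo them).
#' @param verbose print stage progress.
#' @return list with `report` (metric rows for bicubic and network), `model`,
#'   `recon_bicubic`, `recon_msd`, `truth`, `study`, `interpolated`,
#'   `pattern`.
#' @export
run_cycloidal_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, compute) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      f <- file.path(out_dir, paste0(name, ".rds"))
      if (file.exists(f)) {
        say("[%s] reusing %s", name, f)
        return(readRDS(f))
      }
      val <- compute()
      saveRDS(val, f, version = 3)
      return(val)
    }
    compute()
  }

  study <- stage("study", function() simulate_study(config, verbose))
  geo <- config$geometry
  pattern <- build_mask(config$plan, geo$n_angles, geo$n_cols)
  # The network input is the completion of the pure cycloidal subsample;
  # the dithered training projections enter only as the loss target, so the
  # supervised pixels compare interpolated against measured values.
  pattern_cyc <- build_mask(no_train(config$plan), geo$n_angles, geo$n_cols)

  interpolated <- stage("interpolated", function() {
    say("[interp] bicubic completion of %d sinograms", config$n_slices)
    lapply(study$noisy, function(s) {
      bicubic_interpolate(apply_pattern(s, pattern_cyc), pattern_cyc)
    })
  })
  partials <- lapply(study$noisy, function(s) {
    extract_partial(s, pattern$training_angles)
  })

  model <- stage("model", function() {
    say("[train] depth-%d MS-D, %d epochs", config$msd$depth,
        config$train$epochs)
    msd_train(interpolated, partials, config$msd, config$train,
              verbose = verbose)
  })

  restored <- stage("restored", function() {
    msd_apply(model, interpolated[[study$central]])
  })

  recon_bicubic <- stage("recon_bicubic", function() {
    fbp(interpolated[[study$central]], config$grid_n)
  })
  recon_msd <- stage("recon_msd", function() fbp(restored, config$grid_n))

  sc <- ms_scales_for(config$grid_n)
  mu <- study$spheres$spec$attenuation
  report <- rbind(
    metric_report("cycloidal_bicubic", recon_bicubic, study$truth,
                  dose_fraction(no_train(config$plan), geo$n_angles),
                  seg_threshold = mu / 2, ms_ssim_scales = sc),
    metric_report("cycloidal_msd", recon_msd, study$truth,
                  dose_fraction(config$plan, geo$n_angles),
                  seg_threshold = mu / 2, ms_ssim_scales = sc))
  if (!is.null(out_dir)) {
    write.csv(report, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    write_training_log(model, file.path(out_dir, "training_log.csv"))
  }
  list(report = report, model = model, recon_bicubic = recon_bicubic,
       recon_msd = recon_msd, truth = study$truth, study = study,
       interpolated = interpolated, pattern = pattern)
}

no_train <- function(plan) { plan$n_train <- 0L; plan }

#' Compare dose-reduction strategies on a shared phantom
#'
#' Runs the requested methods on the same phantom and, where the exposure
#' matches, the same noise realization (paired comparison), and evaluates
#' each central-slice reconstruction against the rasterized ground truth.
#' Methods: `complete` (dithered full-dose FBP), `low_exposure`,
#' `low_exposure_tv`, `angular` (FBP from the kept projections),
#' `angular_bicubic`, `angular_tv`, `cycloidal_bicubic`, `cycloidal_msd`,
#' `low_exposure_msd` (projection-denoising mode reusing the same network
#' machinery). Low-exposure methods draw fresh counts at reduced intensity
#' (reduced exposure cannot share frames with the full-dose scan).
#'
#' @param config an [experiment_config()].
#' @param methods character vector of method names (>= 1 of the above).
#' @param tv_lambdas candidate TV weights for the `_tv` methods; the weight
#'   maximizing PSNR of the central slice is kept (tied toward smaller).
#' @param tv_iterations Chambolle-Pock iterations per TV reconstruction.
#' @param verbose print stage progress.
#' @return list with `report` (one metric row per method, in the requested
#'   order), `study`, and `models` (any trained networks).
#' @export
run_comparison <- function(config,
                           methods = c("complete", "angular_bicubic",
                                       "cycloidal_bicubic", "cycloidal_msd"),
                           tv_lambdas = 10^seq(-3, 0, length.out = 7),
                           tv_iterations = 150L, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"), length(methods) >= 1)
  known <- c("complete", "low_exposure", "low_exposure_tv", "low_exposure_msd",
             "angular", "angular_bicubic", "angular_tv",
             "cycloidal_bicubic", "cycloidal_msd")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown methods: ", paste(bad, collapse = ", "))

  say <- function(...) if (verbose) message(sprintf(...))
  study <- simulate_study(config, verbose)
  geo <- config$geometry
  mu <- study$spheres$spec$attenuation
  sc <- ms_scales_for(config$grid_n)
  ci <- study$central
  truth <- study$truth
  models <- list()

  plan_cyc <- config$plan
  plan_ang <- acquisition_plan("angular_subsampled", period = plan_cyc$period,
                               aperture = plan_cyc$aperture,
                               angular_step_keep = plan_cyc$period %/%
                                 plan_cyc$aperture)
  exposure_frac <- plan_cyc$aperture / plan_cyc$period
  plan_low <- acquisition_plan("low_exposure", period = plan_cyc$period,
                               aperture = plan_cyc$aperture,
                               exposure_fraction = exposure_frac)

  row_of <- function(label, recon, plan) {
    metric_report(label, recon, truth, dose_fraction(plan, geo$n_angles),
                  seg_threshold = mu / 2, ms_ssim_scales = sc)
  }

  # lazily computed shared intermediates
  env <- new.env()
  low_noisy <- function() {
    if (is.null(env$low)) {
      env$low <- lapply(seq_along(study$zs), function(i) {
        apply_counting_noise(study$noiseless[[i]],
          noise_model(config$incident_photons * exposure_frac,
                      seed = derive_seed(config$seed, "noise_low") + i))
      })
    }
    env$low
  }
  angular_kept <- function() {
    kept <- seq(1L, geo$n_angles, by = plan_ang$angular_step_keep)
    sub_geo <- ct_geometry(length(kept), geo$n_cols, geo$angular_range,
                           geo$pixel_size)
    s <- study$noisy[[ci]]
    structure(list(values = s$values[kept, , drop = FALSE], geometry = sub_geo,
                   slice_z = s$slice_z), class = "sinogram")
  }
  angular_interp <- function() {
    if (is.null(env$ang)) {
      pat <- build_mask(plan_ang, geo$n_angles, geo$n_cols)
      env$ang <- bicubic_interpolate(apply_pattern(study$noisy[[ci]], pat), pat)
    }
    env$ang
  }
  cyc_pipeline <- function() {
    if (is.null(env$cyc)) {
      # interpolate the pure cycloidal subsample; training rows are targets
      pat <- build_mask(no_train(plan_cyc), geo$n_angles, geo$n_cols)
      interp <- lapply(study$noisy, function(s) {
        bicubic_interpolate(apply_pattern(s, pat), pat)
      })
      env$cyc <- list(pattern = pat, interp = interp,
                      training_angles = select_training_angles(geo$n_angles,
                                                               plan_cyc$n_train))
    }
    env$cyc
  }
  tv_best <- function(s, label) {
    say("[tv] tuning %s over %d weights", label, length(tv_lambdas))
    tune_tv_parameter(s, truth, "psnr", tv_lambdas, config$grid_n,
                      tv_iterations)$recon
  }

  rows <- list()
  for (m in methods) {
    say("[method] %s", m)
    rows[[m]] <- switch(m,
      complete = row_of("complete", fbp(study$noisy[[ci]], config$grid_n),
                        acquisition_plan("dithered", period = plan_cyc$period,
                                         aperture = plan_cyc$aperture)),
      low_exposure = row_of("low_exposure",
                            fbp(low_noisy()[[ci]], config$grid_n), plan_low),
      low_exposure_tv = row_of("low_exposure_tv",
                               tv_best(low_noisy()[[ci]], m), plan_low),
      angular = row_of("angular", fbp(angular_kept(), config$grid_n), plan_ang),
      angular_bicubic = row_of("angular_bicubic",
                               fbp(angular_interp(), config$grid_n), plan_ang),
      angular_tv = row_of("angular_tv", tv_best(angular_kept(), m), plan_ang),
      cycloidal_bicubic = {
        cp <- cyc_pipeline()
        row_of("cycloidal_bicubic", fbp(cp$interp[[ci]], config$grid_n),
               no_train(plan_cyc))
      },
      cycloidal_msd = {
        cp <- cyc_pipeline()
        partials <- lapply(study$noisy, function(s) {
          extract_partial(s, cp$training_angles)
        })
        say("[train] cycloidal MS-D (%d epochs)", config$train$epochs)
        model <- msd_train(cp$interp, partials, config$msd, config$train,
                           verbose = verbose)
        models$cycloidal_msd <- model
        restored <- msd_apply(model, cp$interp[[ci]])
        row_of("cycloidal_msd", fbp(restored, config$grid_n), plan_cyc)
      },
      low_exposure_msd = {
        res <- denoise_projections(study, low_noisy(), config, plan_low)
        models$low_exposure_msd <- res$model
        row_of("low_exposure_msd", fbp(res$sino_central(ci), config$grid_n),
               plan_with_train(plan_low, plan_cyc$n_train))
      })
  }
  report <- do.call(rbind, rows[methods])
  rownames(report) <- NULL
  list(report = report, study = study, models = models)
}

plan_with_train <- function(plan, n_train) { plan$n_train <- as.integer(n_train); plan }

# Projection-denoising mode: train the same MS-D machinery on projection
# images assembled across slices (rows = slices, columns = detector), with
# low-exposure projections as input and full-exposure projections at the
# training angles as target.
denoise_projections <- function(study, low, config, plan_low) {
  n_angles <- config$geometry$n_angles
  n_slices <- length(study$zs)
  train_angles <- select_training_angles(n_angles, config$plan$n_train)
  proj_img <- function(stack, k) {
    t(vapply(stack, function(s) s$values[k, ], numeric(config$geometry$n_cols)))
  }
  inputs <- lapply(train_angles, function(k) proj_img(low, k))
  targets <- lapply(train_angles, function(k) {
    list(values = proj_img(study$noisy, k),
         defined = matrix(TRUE, n_slices, config$geometry$n_cols))
  })
  model <- msd_train(inputs, targets, config$msd, config$train)
  sino_central <- function(ci) {
    denoised <- vapply(seq_len(n_angles), function(k) {
      msd_apply(model, proj_img(low, k))[ci, ]
    }, numeric(config$geometry$n_cols))
    s <- low[[ci]]
    s$values <- t(denoised)
    s
  }
  list(model = model, sino_central = sino_central)
}

#' Generate the deterministic miniature fixture bundle
#'
#' Writes a small self-contained dataset used by the test suite: a 16-sphere
#' phantom (CSV + JSON), a 64 x 64 noiseless and noisy sinogram (TIFF +
#' JSON), cycloidal/angular masks (TIFF + JSON), and a depth-5 MS-D
#' checkpoint trained for a few epochs, with its validation loss recorded in
#' a JSON sidecar. Byte-identical across regenerations with the same seed.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return `dir`, invisibly.
#' @export
generate_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- phantom_spec(n_spheres = 16, cylinder_radius = 0.8,
                       radius_min = 0.05, radius_max = 0.2,
                       radius_exponent = 2, attenuation = 1,
                       seed = derive_seed(seed, "phantom"))
  spheres <- generate_phantom(spec)
  geo <- ct_geometry(64, 64)
  mu <- calibrate_attenuation(spheres, geo, 0.5)
  spheres$spec$attenuation <- mu
  write_sphere_set(spheres, file.path(dir, "phantom"))

  sino <- project_analytic(spheres, geo, z = 0)
  write_sinogram(sino, file.path(dir, "sino_noiseless"))
  noisy <- apply_counting_noise(sino, noise_model(1000,
                                                  seed = derive_seed(seed, "noise")))
  write_sinogram(noisy, file.path(dir, "sino_noisy"))

  plan <- acquisition_plan("cycloidal", period = 8, aperture = 1,
                           shift_per_angle = 3, n_train = 5)
  pat <- build_mask(plan, geo$n_angles, geo$n_cols)
  write_pattern(pat, file.path(dir, "mask_cycloidal"))
  write_pattern(build_mask(acquisition_plan("angular_subsampled",
                                            angular_step_keep = 8),
                           geo$n_angles, geo$n_cols),
                file.path(dir, "mask_angular"))

  zs <- c(-0.1, 0, 0.1, 0.2)
  noisy_all <- lapply(seq_along(zs), function(i) {
    apply_counting_noise(project_analytic(spheres, geo, zs[i]),
                         noise_model(1000, seed = derive_seed(seed, "noise") + i))
  })
  pat_cyc <- build_mask(no_train(plan), geo$n_angles, geo$n_cols)
  interp <- lapply(noisy_all, function(s) {
    bicubic_interpolate(apply_pattern(s, pat_cyc), pat_cyc)
  })
  partials <- lapply(noisy_all, function(s) extract_partial(s, pat$training_angles))
  model <- msd_train(interp, partials,
                     msd_config(depth = 5, dilations = 1:5,
                                seed = derive_seed(seed, "init")),
                     train_config(epochs = 3, seed = derive_seed(seed, "train")))
  model$log$wall_time <- 0  # timings stripped so bundles are byte-identical
  write_msd_model(model, file.path(dir, "checkpoint.rds"))
  jsonlite::write_json(list(best_val_loss = model$best_val_loss,
                            best_epoch = model$best_epoch),
                       file.path(dir, "checkpoint_val.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read an experiment configuration from YAML or JSON
#'
#' Top-level keys `phantom`, `geometry`, `plan`, `msd`, `train` hold the
#' arguments of the respective constructors; remaining keys are passed to
#' [experiment_config()] directly.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  need <- c("phantom", "geometry", "plan", "msd", "train")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("config is missing sections: ", paste(miss, collapse = ", "))
  }
  args <- list(phantom = do.call(phantom_spec, raw$phantom),
               geometry = do.call(ct_geometry, raw$geometry),
               plan = do.call(acquisition_plan, raw$plan),
               msd = do.call(msd_config, raw$msd),
               train = do.call(train_config, raw$train))
  rest <- raw[setdiff(names(raw), need)]
  do.call(experiment_config, c(args, rest))
}
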