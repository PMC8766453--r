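test_that("cycloidal masks sample the documented column residues", {
  plan <- acquisition_plan("cycloidal", period = 8, aperture = 1,
                           shift_per_angle = 3)
  pat <- build_mask(plan, 16, 32)
  expect_identical(which(pat$mask[1, ]), as.integer(c(0, 8, 16, 24) + 1))
  expect_identical(which(pat$mask[2, ]), as.integer(c(3, 11, 19, 27) + 1))
  expect_identical(which(pat$mask[3, ]), as.integer(c(6, 14, 22, 30) + 1))
  # mask fraction is exactly w/p without training rows
  expect_equal(mean(pat$mask), 1 / 8)
  # gcd(3, 8) = 1: any 8 consecutive rows cover all 8 residues exactly once
  for (k0 in 1:8) {
    res <- ((which(pat$mask[k0 + 0:7, 1:8, drop = FALSE],
                   arr.ind = TRUE)[, 2]) - 1) %% 8
    expect_setequal(res, 0:7)
  }
  # determinism / purity
  expect_identical(pat$mask, build_mask(plan, 16, 32)$mask)
})

test_that("rotation-only, dithered, angular and low-exposure masks behave", {
  rot <- build_mask(acquisition_plan("rotation_only", period = 8, aperture = 1),
                    12, 64)
  expect_true(all(apply(rot$mask, 1, identical, rot$mask[1, ])))
  expect_equal(mean(colSums(rot$mask) > 0), 1 / 8)

  expect_true(all(build_mask(acquisition_plan("dithered"), 6, 16)$mask))
  expect_true(all(build_mask(acquisition_plan("low_exposure",
                                              exposure_fraction = 0.125),
                             6, 16)$mask))

  ang <- build_mask(acquisition_plan("angular_subsampled",
                                     angular_step_keep = 8), 32, 16)
  expect_true(all(ang$mask[seq(1, 32, 8), ]))
  expect_false(any(ang$mask[-seq(1, 32, 8), ]))
})

test_that("aperture:period ratios outside the masked-beam regime warn", {
  expect_warning(acquisition_plan("cycloidal", period = 2, aperture = 1,
                                  shift_per_angle = 1),
                 "1:3 to 1:10")
  expect_silent(acquisition_plan("cycloidal", period = 8, aperture = 1))
})

test_that("training angles are evenly spread with the documented gaps", {
  idx <- select_training_angles(1024, 33)
  expect_length(idx, 33)
  expect_true(all(diff(idx) %in% c(31, 32)))
  expect_identical(select_training_angles(100, 0), integer(0))
  expect_identical(select_training_angles(7, 7), 1:7)
  # training rows are fully sampled in the mask
  pat <- build_mask(acquisition_plan("cycloidal", n_train = 5), 64, 32)
  expect_true(all(pat$mask[pat$training_angles, ]))
  expect_identical(pat$training_angles, select_training_angles(64, 5))
})

test_that("applying a pattern masks, preserves training rows, is idempotent", {
  sph <- small_foam(n = 5, seed = 1)
  s <- project_analytic(sph, ct_geometry(32, 32))
  pat <- build_mask(acquisition_plan("cycloidal", n_train = 4), 32, 32)
  inc <- apply_pattern(s, pat)
  expect_true(all(is.na(inc$values[!pat$mask])))
  expect_identical(inc$values[pat$mask], s$values[pat$mask])
  expect_identical(apply_pattern(inc, pat)$values, inc$values)
  expect_error(apply_pattern(s, build_mask(acquisition_plan("cycloidal"), 16, 32)),
               "shape")

  # constant sinogram: per-non-training-row defined count = ceiling(n_cols w/p)
  const <- as_sino(matrix(5, 32, 30))
  patc <- build_mask(acquisition_plan("cycloidal", period = 8, aperture = 1),
                     32, 30)
  incc <- apply_pattern(const, patc)
  expect_true(all(incc$values[patc$mask] == 5))
  counts <- rowSums(!is.na(incc$values))
  expect_true(all(counts %in% c(floor(30 / 8), ceiling(30 / 8))))
  expect_equal(sum(patc$mask), sum(counts))
  # the first row samples residue 0, hence exactly ceiling(n_cols w/p) entries
  expect_equal(counts[[1]], ceiling(30 / 8))
})

test_that("partial sinograms carry exactly the training rows", {
  sph <- small_foam(n = 5, seed = 1)
  s <- project_analytic(sph, ct_geometry(32, 48))
  tr <- select_training_angles(32, 6)
  part <- extract_partial(s, tr)
  expect_equal(sum(part$defined), 6 * 48)
  expect_identical(part$values[tr, ], s$values[tr, ])
  expect_true(all(is.na(part$values[-tr, ])))
  all_part <- extract_partial(s, 1:32)
  expect_identical(all_part$values, s$values)
  none <- extract_partial(s, integer(0))
  expect_false(any(none$defined))
})

test_that("dose fractions reproduce the benchmark arithmetic", {
  p8 <- function(mode, ...) acquisition_plan(mode, period = 8, aperture = 1, ...)
  expect_equal(dose_fraction(p8("dithered"), 1024), 100)
  expect_equal(dose_fraction(p8("cycloidal"), 1024), 12.5)
  expect_equal(dose_fraction(p8("cycloidal", n_train = 33), 1024),
               100 * (1024 + 33 * 8) / 8192)
  # additivity: total = base + training overhead
  expect_equal(dose_fraction(p8("cycloidal", n_train = 33), 1024) -
                 dose_fraction(p8("cycloidal"), 1024),
               100 * 33 * 8 / 8192)
  expect_equal(dose_fraction(p8("angular_subsampled", angular_step_keep = 8),
                             1024), 12.5)
  expect_equal(dose_fraction(p8("low_exposure", exposure_fraction = 1 / 8),
                             1024), 12.5)
  expect_equal(dose_fraction(p8("low_exposure", exposure_fraction = 1 / 8,
                                n_train = 33), 1024),
               12.5 + 100 * 33 * 8 / 8192)
})

test_that("sampling patterns round-trip through TIFF + JSON", {
  pat <- build_mask(acquisition_plan("cycloidal", n_train = 3), 32, 32)
  path <- file.path(withr::local_tempdir(), "mask")
  write_pattern(pat, path)
  back <- read_pattern(path)
  expect_identical(back$mask, pat$mask)
  expect_identical(back$training_angles, pat$training_angles)
  expect_equal(back$plan, pat$plan)
})
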