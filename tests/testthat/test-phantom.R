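test_that("phantom generation is deterministic and respects its invariants", {
  spec <- phantom_spec(n_spheres = 200, cylinder_radius = 0.8,
                       radius_min = 0.02, radius_max = 0.15,
                       radius_exponent = 2, seed = 42)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a, b)
  expect_length(a$radii, 200)
  # pairwise non-overlap, exhaustively
  d <- as.matrix(dist(a$centers))
  need <- outer(a$radii, a$radii, "+")
  diag(d) <- Inf
  expect_true(all(d >= need - 1e-12))
  # lateral containment in the cylinder
  lat <- sqrt(a$centers[, 1]^2 + a$centers[, 2]^2)
  expect_true(all(lat + a$radii <= spec$cylinder_radius + 1e-12))
})

test_that("degenerate sphere counts behave as specified", {
  empty <- generate_phantom(phantom_spec(n_spheres = 0, cylinder_radius = 0.7,
                                         attenuation = 3))
  expect_length(empty$radii, 0)
  sl <- rasterize_slice(empty, 0, grid_n = 32, supersample = 4)
  coord <- -1 + (seq_len(32) - 0.5) / 16
  rr <- sqrt(outer(coord^2, coord^2, "+"))
  expect_true(all(sl$values[rr < 0.6] == 3))
  expect_true(all(sl$values[rr > 0.8] == 0))

  two <- generate_phantom(phantom_spec(n_spheres = 2, cylinder_radius = 0.95,
                                       radius_min = 0.1, radius_max = 0.1,
                                       seed = 5))
  expect_gte(sqrt(sum((two$centers[1, ] - two$centers[2, ])^2)), 0.2)
  expect_true(all(sqrt(rowSums(two$centers[, 1:2]^2)) <= 0.85 + 1e-12))
})

test_that("overly dense packing fails with a diagnostic", {
  spec <- phantom_spec(n_spheres = 500, cylinder_radius = 0.5,
                       radius_min = 0.2, radius_max = 0.3, seed = 1)
  expect_error(generate_phantom(spec, max_attempts = 50), "packing too dense")
})

test_that("void volume fraction matches a Monte-Carlo oracle", {
  spec <- phantom_spec(n_spheres = 500, cylinder_radius = 0.8,
                       radius_min = 0.002, radius_max = 0.2,
                       radius_exponent = 3, z_half = 0.5, seed = 1)
  sph <- generate_phantom(spec)
  analytic <- sum(4 / 3 * pi * sph$radii^3)
  # sample uniformly in a box enclosing all spheres
  set.seed(99)
  zmax <- max(abs(sph$centers[, 3]) + sph$radii)
  n <- 1e6
  px <- runif(n, -0.8, 0.8); py <- runif(n, -0.8, 0.8)
  pz <- runif(n, -zmax, zmax)
  invoid <- rep(FALSE, n)
  for (i in seq_along(sph$radii)) {
    invoid <- invoid | ((px - sph$centers[i, 1])^2 +
                        (py - sph$centers[i, 2])^2 +
                        (pz - sph$centers[i, 3])^2 < sph$radii[i]^2)
  }
  mc <- mean(invoid) * (1.6 * 1.6 * 2 * zmax)
  expect_lt(abs(mc - analytic) / analytic, 0.01)
})

test_that("rasterization matches pointwise values and an edge-area oracle", {
  sph <- small_foam(n = 5, seed = 3)
  mu <- sph$spec$attenuation
  sl <- rasterize_slice(sph, 0, grid_n = 64, supersample = 4)
  # a pixel at the center of the largest void is exactly 0
  big <- which.max(sph$radii)
  cz <- sph$centers[big, ]
  jx <- round((cz[1] + 1) * 32 + 0.5); jy <- round((cz[2] + 1) * 32 + 0.5)
  if (abs(cz[3]) < sph$radii[big] - 0.1) {
    expect_equal(sl$values[jy, jx], 0)
  }
  # a bulk pixel far from all voids is exactly mu: center of mass of material
  coord <- -1 + (seq_len(64) - 0.5) / 32
  rr <- sqrt(outer(coord^2, coord^2, "+"))
  dmin <- matrix(Inf, 64, 64)
  for (i in seq_along(sph$radii)) {
    if (abs(sph$centers[i, 3]) >= sph$radii[i]) next
    rho <- sqrt(sph$radii[i]^2 - sph$centers[i, 3]^2)
    di <- sqrt(outer((coord - sph$centers[i, 2])^2,
                     (coord - sph$centers[i, 1])^2, "+")) - rho
    dmin <- pmin(dmin, di)
  }
  bulk <- rr < sph$spec$cylinder_radius - 0.1 & dmin > 0.1
  expect_true(all(sl$values[bulk] == mu))

  # pixel straddling the cylinder edge vs a quadrature chord-area oracle
  disk <- disk_phantom(R = 0.6, mu = 1)
  n <- 32; ps <- 2 / n; ss <- 8
  sl2 <- rasterize_slice(disk, 0, grid_n = n, supersample = ss)
  # pixel whose y-extent straddles the circle near x = 0
  jx <- n / 2 + 1                       # x in (0, ps)
  jy <- which(-1 + (seq_len(n) - 0.5) * ps < 0.6 &
              -1 + (seq_len(n) + 0.5) * ps > 0.6)[1]
  x0 <- -1 + (jx - 1) * ps; x1 <- x0 + ps
  y0 <- -1 + (jy - 1) * ps; y1 <- y0 + ps
  top <- function(x) pmin(pmax(sqrt(pmax(0.6^2 - x^2, 0)), y0), y1)
  area <- integrate(function(x) top(x) - y0, x0, x1, rel.tol = 1e-10)$value
  exact <- area / ps^2
  expect_lt(abs(sl2$values[jy, jx] - exact), 1 / ss)
})

test_that("rasterization converges with supersampling", {
  sph <- small_foam(n = 8, seed = 9)
  ref <- rasterize_slice(sph, 0, 32, supersample = 16)$values
  errs <- sapply(c(1, 2, 4, 8), function(ss) {
    max(abs(rasterize_slice(sph, 0, 32, supersample = ss)$values - ref))
  })
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("sphere sets round-trip through CSV/JSON", {
  sph <- small_foam(n = 10, seed = 2)
  path <- file.path(withr::local_tempdir(), "phantom")
  write_sphere_set(sph, path)
  back <- read_sphere_set(path)
  expect_equal(back$centers, sph$centers, ignore_attr = TRUE)
  expect_equal(back$radii, sph$radii)
  expect_equal(back$spec, sph$spec)
})
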