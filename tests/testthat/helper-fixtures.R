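# Shared in-code fixtures. Everything is generated deterministically at test
# time; nothing is read from disk.

# plain sinogram object around a value matrix (for synthetic test inputs)
as_sino <- function(values, angular_range = 180) {
  structure(list(values = values,
                 geometry = ct_geometry(nrow(values), ncol(values),
                                        angular_range),
                 slice_z = 0),
            class = "sinogram")
}

# small foam phantom used across modules
small_foam <- function(n = 20, seed = 7) {
  generate_phantom(phantom_spec(n_spheres = n, cylinder_radius = 0.8,
                                radius_min = 0.05, radius_max = 0.2,
                                radius_exponent = 2, attenuation = 1,
                                seed = seed))
}

# uniform disk phantom (no voids)
disk_phantom <- function(R = 0.6, mu = 2) {
  generate_phantom(phantom_spec(n_spheres = 0, cylinder_radius = R,
                                attenuation = mu, seed = 1))
}

# deterministic smooth image pair for the SSIM oracle comparison
ssim_pair <- function() {
  set.seed(11)
  base <- matrix(rnorm(64 * 64), 64, 64)
  sm <- function(m) {
    o <- m * 0
    for (du in -1:1) for (dv in -1:1) {
      rs <- pmin(pmax(1:64 + du, 1), 64)
      cs <- pmin(pmax(1:64 + dv, 1), 64)
      o <- o + m[rs, cs] / 9
    }
    o
  }
  x <- sm(sm(base))
  y <- x + 0.1 * matrix(rnorm(64 * 64), 64, 64)
  list(ref = x, img = y)
}

# conjugate gradient on the normal equations A^T A u = A^T b with the
# package's discrete projector: independent least-squares oracle for TV
cg_least_squares <- function(b, angles, grid_n, det_ps, n_iter = 80) {
  fwd <- function(u) cycloidct:::radon_forward_cpp(u, angles, ncol(b), det_ps)
  adj <- function(s) cycloidct:::radon_adjoint_cpp(s, angles, grid_n, det_ps)
  u <- matrix(0, grid_n, grid_n)
  r <- adj(b)
  p <- r
  rs <- sum(r^2)
  for (i in seq_len(n_iter)) {
    Ap <- adj(fwd(p))
    alpha <- rs / sum(p * Ap)
    u <- u + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r^2)
    if (rs_new < 1e-20) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  u
}
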