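# Shared fixtures, built once per test run. All synthetic, all seeded.

fix <- new.env()

# 62-entry acquisition scheme (61 weighted + 1 b0) emulating the protocol
fix$gt61 <- make_gradient_scheme(61, 1200, seed = 1)

# dense high-b scheme for resolution work
fix$gt300 <- make_gradient_scheme(300, 3000, seed = 5)

# noise-free straight-tube phantom with fitted FOD field
fix$straight <- local({
  truth <- make_bundle_phantom("straight", shape = c(14, 14, 24),
                               tube_radius = 2)
  model <- tissue_model(snr = Inf)
  dwi <- simulate_dwi(truth, fix$gt61, model)
  resp <- response_from_tensor(1200, model)
  fod <- fit_fod_field(dwi, resp, lambda = 1)
  list(truth = truth, model = model, dwi = dwi, resp = resp, fod = fod)
})

# hand-built FOD field: every voxel of a (possibly coarse) grid carries the
# same SH coefficient vector
uniform_fod_field <- function(coefs, dim, voxel_size = 1, lmax = 8) {
  nvox <- prod(dim)
  sel <- seq_len(nvox)
  vox <- cbind((sel - 1) %% dim[1],
               ((sel - 1) %/% dim[1]) %% dim[2],
               (sel - 1) %/% (dim[1] * dim[2]))
  mask <- array(TRUE, dim)
  structure(list(coefficients = matrix(coefs, nvox, length(coefs),
                                       byrow = TRUE),
                 voxels = vox, mask = mask, lmax = as.integer(lmax),
                 affine = diag(c(rep(voxel_size, 3), 1)), dim = dim),
            class = "fod_field")
}

# SH coefficients of a delta-like FOD along `axis` (truncated delta)
delta_fod <- function(axis = c(0, 0, 1), lmax = 8) {
  as.vector(sh_basis(matrix(axis / sqrt(sum(axis^2)), 1), lmax))
}

# independent brute-force oracle: smallest t with P(X > t) < alpha by direct
# pmf accumulation
poisson_threshold_oracle <- function(lambda, alpha) {
  t <- 0L
  cdf <- dpois(0, lambda)
  while (1 - cdf >= alpha) {
    t <- t + 1L
    cdf <- cdf + dpois(t, lambda)
  }
  t
}

# independent brute-force lattice count for spherical ROI sizes on a 1 mm grid
sphere_voxel_count_oracle <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  sum(g$x^2 + g$y^2 + g$z^2 <= radius^2)
}
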