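# CSD module: response estimation, constrained deconvolution, peak
# extraction, and the rotation/reconvolution self-consistency properties.

# predicted signal of a delta FOD along `axis` convolved with a zonal
# response: by the Funk-Hecke theorem this is the response profile itself,
# evaluated at the angle between gradient and axis
reconvolve_delta <- function(response, axis, dirs) {
  lmax <- response$lmax
  fl <- sqrt(4 * pi / (2 * seq(0, lmax, 2) + 1)) * response$zonal_coefficients
  fcol <- fl[picotract:::sh_degrees(lmax) / 2 + 1]
  A <- sweep(sh_basis(dirs, lmax), 2, fcol, "*")
  delta <- as.vector(sh_basis(matrix(axis, 1), lmax))
  as.vector(A %*% delta)
}

test_that("response estimation round-trips the masked mean signal", {
  st <- fix$straight
  mask <- array(FALSE, st$truth$shape)
  mask[st$truth$bundles$bundle$voxels + 1] <- TRUE

  dw <- fix$gt61$bvalues > 0
  gdw <- fix$gt61$directions[dw, ]
  sel <- which(mask)
  sig <- matrix(st$dwi$signal, prod(st$truth$shape))[sel, ]
  mean_dw <- colMeans(sig[, dw] / rowMeans(sig[, !dw, drop = FALSE]))

  # at a generous harmonic order the zonal model captures the tensor profile
  # essentially exactly
  r16 <- estimate_response(st$dwi, mask, c(0, 0, 1), lmax = 16)
  pred <- reconvolve_delta(r16, c(0, 0, 1), gdw)
  expect_lt(max(abs(pred - mean_dw)) / max(mean_dw), 1e-6)

  # at the working order lmax = 8 the truncation residual is still small
  r8 <- estimate_response(st$dwi, mask, c(0, 0, 1), lmax = 8)
  pred8 <- reconvolve_delta(r8, c(0, 0, 1), gdw)
  expect_lt(max(abs(pred8 - mean_dw)) / max(mean_dw), 1e-3)

  expect_error(estimate_response(st$dwi, array(FALSE, st$truth$shape),
                                 c(0, 0, 1)), "no single-fibre voxels")
})

test_that("an isotropic voxel set yields a zonal-flat response", {
  st <- fix$straight
  iso_mask <- st$truth$brain_mask
  iso_mask[st$truth$bundles$bundle$voxels + 1] <- FALSE
  r <- estimate_response(st$dwi, iso_mask, c(0, 0, 1))
  expect_lt(max(abs(r$zonal_coefficients[-1])),
            1e-6 * r$zonal_coefficients[1])
})

test_that("the l = 0 response coefficient is the sphere average times sqrt(4 pi)", {
  m <- tissue_model(snr = Inf)
  truth <- make_bundle_phantom("straight", shape = c(8, 8, 14),
                               tube_radius = 1.5)
  dwi <- simulate_dwi(truth, fix$gt300, m)
  mask <- array(FALSE, truth$shape)
  mask[truth$bundles$bundle$voxels[1, , drop = FALSE] + 1] <- TRUE
  r <- estimate_response(dwi, mask, c(0, 0, 1))
  # independent oracle: numerical quadrature of the closed-form profile
  b <- 3000
  f <- function(ct) exp(-b * (m$lambda_perp +
                                (m$lambda_parallel - m$lambda_perp) * ct^2))
  sphere_avg <- integrate(f, -1, 1)$value / 2
  expect_equal(r$zonal_coefficients[1], sphere_avg * sqrt(4 * pi),
               tolerance = 1e-3)
})

test_that("deconvolving the kernel itself recovers a single sharp peak", {
  resp <- response_from_tensor(3000, tissue_model(), lmax = 8)
  dw <- fix$gt300$bvalues > 0
  s <- reconvolve_delta(resp, c(0, 0, 1), fix$gt300$directions[dw, ])
  # prepend the unit b0 so the signal matches the full gradient table
  x <- fit_csd(c(1, s), fix$gt300, resp)
  pk <- find_fod_peaks(x)
  expect_equal(nrow(pk$directions), 1)
  expect_lt(picotract:::angle_deg(pk$directions[1, ], c(0, 0, 1)), 2)

  # reconvolution residual stays small after the constrained fit
  pred <- reconvolve_delta(resp, c(0, 0, 1), fix$gt300$directions[dw, ])
  A_resid <- max(abs(picotract:::csd_forward_matrix(
    fix$gt300$directions[dw, ], resp, 8) %*% x - s))
  expect_lt(A_resid, 1e-3)
})

test_that("crossing fibres are resolved at 90 and at 30 degrees", {
  m <- tissue_model(snr = Inf)
  # 90 degrees on the emulated 61-direction b = 1200 scheme
  resp61 <- response_from_tensor(1200, m, lmax = 8)
  u1 <- c(1, 0, 0); u2 <- c(0, 0, 1)
  s <- multi_tensor_signal(fix$gt61, rbind(u1, u2), c(0.5, 0.5), m) / m$S0
  pk <- find_fod_peaks(fit_csd(s, fix$gt61, resp61))
  expect_equal(nrow(pk$directions), 2)
  errs <- apply(pk$directions, 1, function(d)
    min(picotract:::angle_deg(d, u1), picotract:::angle_deg(d, u2)))
  expect_true(all(errs <= 5))

  # 30 degrees needs the dense high-b scheme at lmax = 8
  resp300 <- response_from_tensor(3000, m, lmax = 8)
  h <- 15 * pi / 180
  v1 <- c(sin(h), 0, cos(h)); v2 <- c(-sin(h), 0, cos(h))
  s30 <- multi_tensor_signal(fix$gt300, rbind(v1, v2), c(0.5, 0.5), m) / m$S0
  pk30 <- find_fod_peaks(fit_csd(s30, fix$gt300, resp300))
  expect_equal(nrow(pk30$directions), 2)
})

test_that("the FOD field recovers bundle tangents and flags background", {
  st <- fix$straight
  fod <- st$fod
  b <- st$truth$bundles$bundle
  lin_field <- fod$voxels[, 1] + st$truth$shape[1] *
    (fod$voxels[, 2] + st$truth$shape[2] * fod$voxels[, 3])
  lin_bundle <- b$voxels[, 1] + st$truth$shape[1] *
    (b$voxels[, 2] + st$truth$shape[2] * b$voxels[, 3])
  rows <- match(lin_bundle, lin_field)
  take <- seq(1, length(rows), by = 4)   # subsample for speed
  for (i in take) {
    pk <- find_fod_peaks(fod$coefficients[rows[i], ])
    expect_lt(picotract:::angle_deg(pk$directions[1, ], b$orientations[i, ]),
              5)
  }
  # background voxels: dominant amplitude below the tracking threshold
  bg <- setdiff(seq_len(nrow(fod$coefficients)), rows)
  amps <- vapply(bg, function(r) {
    pk <- find_fod_peaks(fod$coefficients[r, ], rel_threshold = 0.9)
    if (nrow(pk$directions)) pk$amplitudes[1] else 0
  }, 0)
  expect_gte(mean(amps < tracking_params()$fod_amplitude_threshold), 0.99)

  # deterministic: refitting gives identical coefficients
  fod2 <- fit_fod_field(st$dwi, st$resp, lambda = 1)
  expect_identical(fod$coefficients, fod2$coefficients)
})

test_that("fitting a rotated signal rotates the peaks (equivariance)", {
  m <- tissue_model(snr = Inf)
  resp <- response_from_tensor(1200, m, lmax = 8)
  R <- picotract:::rotation_between(c(0, 0, 1), c(1, 1, 1) / sqrt(3))
  u1 <- c(0, 0, 1); u2 <- c(1, 0, 0)
  s <- multi_tensor_signal(fix$gt61, rbind(u1, u2), c(0.5, 0.5), m) / m$S0
  pk <- find_fod_peaks(fit_csd(s, fix$gt61, resp))

  gt_rot <- gradient_table(fix$gt61$directions %*% t(R), fix$gt61$bvalues)
  s_rot <- multi_tensor_signal(gt_rot, rbind(as.vector(R %*% u1),
                                             as.vector(R %*% u2)),
                               c(0.5, 0.5), m) / m$S0
  # fitting in the rotated frame must give the rotated peaks
  pk_rot <- find_fod_peaks(fit_csd(s_rot, gt_rot, resp))
  expect_equal(nrow(pk$directions), nrow(pk_rot$directions))
  for (i in seq_len(nrow(pk$directions))) {
    rotated <- as.vector(R %*% pk$directions[i, ])
    best <- min(apply(pk_rot$directions, 1, picotract:::angle_deg,
                      b = rotated))
    expect_lt(best, 2)
  }
})

test_that("the soft penalty tames negative lobes monotonically in lambda", {
  m <- tissue_model(snr = Inf)
  resp <- response_from_tensor(1200, m, lmax = 8)
  s <- multi_tensor_signal(fix$gt61, c(0, 0, 1), 1, m) / m$S0
  Bc <- sh_basis(fibonacci_sphere(300), 8)
  minmax <- vapply(c(0.01, 1), function(lam) {
    x <- fit_csd(s, fix$gt61, resp, lambda = lam)
    a <- as.vector(Bc %*% x)
    min(a) / max(a)
  }, 0)
  expect_gt(minmax[2], minmax[1])      # stronger penalty, milder negativity
  expect_gt(minmax[2], -0.2)           # bounded violation at working weight
})

test_that("peak extraction respects symmetry and degenerate input", {
  expect_length(find_fod_peaks(rep(0, sh_ncoef(8)))$amplitudes, 0)

  d <- delta_fod(c(0, 0, 1))
  pk <- find_fod_peaks(d)
  expect_equal(nrow(pk$directions), 1)
  expect_lt(picotract:::angle_deg(pk$directions[1, ], c(0, 0, 1)), 1)

  # FOD symmetric under the x <-> y swap keeps a symmetric peak set
  two <- delta_fod(c(1, 0, 0)) + delta_fod(c(0, 1, 0))
  pk2 <- find_fod_peaks(two, rel_threshold = 0.5)
  expect_equal(nrow(pk2$directions), 2)
  swapped <- pk2$directions[, c(2, 1, 3)]
  for (i in 1:2)
    expect_lt(min(apply(pk2$directions, 1, picotract:::angle_deg,
                        b = swapped[i, ])), 1)

  # 90-degree crossing FOD at rel_threshold 0.5: exactly two peaks survive
  expect_equal(nrow(find_fod_peaks(two, rel_threshold = 0.5)$directions), 2)
})
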