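# Tracking module: FOD-amplitude direction sampling, bidirectional
# propagation with the printed stopping rules, and visitation counting.

test_that("direction sampling concentrates where the FOD mass is", {
  st <- fix$straight
  ctr <- c(6.5, 6.5, 12)   # mid-tube, world mm

  set.seed(21)
  draws <- sample_direction(st$fod, ctr, n = 10000)

  # brute-force oracle: normalised FOD mass within an angular cap over the
  # same sphere set and suprathreshold support used by the sampler. (An
  # lmax = 8 "delta" lobe is ~20 degrees wide, so a 10-degree cap holds
  # only ~22% of the mass; the oracle, not a guessed figure, is the
  # reference at every cap.)
  row <- which(st$fod$voxels[, 1] == 6 & st$fod$voxels[, 2] == 6 &
                 st$fod$voxels[, 3] == 12)
  dirs <- fibonacci_sphere(724)
  amp <- as.vector(sh_basis(dirs, 8) %*% st$fod$coefficients[row, ])
  thr <- tracking_params()$fod_amplitude_threshold
  amp[amp < thr] <- 0
  for (cap_deg in c(10, 20, 30)) {
    cap <- cos(cap_deg * pi / 180)
    mc <- mean(abs(draws[, 3]) > cap)
    oracle <- sum(amp[abs(dirs[, 3]) > cap]) / sum(amp)
    expect_lt(abs(mc - oracle), 0.02)
  }
  # the draw distribution is concentrated around +-z
  expect_gte(mean(abs(draws[, 3]) > cos(30 * pi / 180)), 0.95)
})

test_that("an isotropic FOD samples all octants uniformly", {
  iso <- rep(0, sh_ncoef(8))
  iso[1] <- 0.3 * sqrt(4 * pi)          # constant amplitude 0.3
  fld <- uniform_fod_field(iso, c(5, 5, 5))
  set.seed(8)
  draws <- sample_direction(fld, c(2, 2, 2), n = 10000)
  oct <- table(factor(paste(draws[, 1] > 0, draws[, 2] > 0, draws[, 3] > 0),
                      levels = apply(expand.grid(c(TRUE, FALSE),
                                                 c(TRUE, FALSE),
                                                 c(TRUE, FALSE)), 1, paste,
                                     collapse = " ")))
  p <- 1 / 8
  sigma <- sqrt(10000 * p * (1 - p))
  expect_true(all(abs(oct - 10000 * p) < 3 * sigma))
})

test_that("the hemisphere restriction follows the previous direction", {
  st <- fix$straight
  set.seed(3)
  draws <- sample_direction(st$fod, c(6.5, 6.5, 12),
                            previous_direction = c(0, 0, 1), n = 2000)
  expect_true(all(draws[, 3] > 0))
})

test_that("a coherent unbounded field is stopped only by the 500 mm cap", {
  # 2 mm voxels: 20 x 20 x 512 mm of uniform z-oriented FOD
  fld <- uniform_fod_field(delta_fod(c(0, 0, 1)), c(10, 10, 256),
                           voxel_size = 2)
  params <- tracking_params(fod_amplitude_threshold = 0.5, rng_seed = 5)
  lens <- numeric(20)
  reasons <- character(20)
  for (i in 1:20) {
    p <- tracking_params(fod_amplitude_threshold = 0.5, rng_seed = 100 + i)
    sl <- propagate_streamline(fld, c(9, 9, 255), p)
    lens[i] <- (nrow(sl$points) - 1) * sl$step_size
    reasons[i] <- sl$termination_reason
    expect_lte(nrow(sl$points), 1001)
  }
  expect_true(all(lens <= 500))
  expect_true(any(reasons == "max_length"))
  expect_true(all(lens[reasons == "max_length"] == 500))
})

test_that("streamlines respect step size, masks and determinism", {
  st <- fix$straight
  params <- tracking_params(rng_seed = 17)
  sl <- propagate_streamline(st$fod, c(6.5, 6.5, 12), params)
  steps <- sqrt(rowSums(diff(sl$points)^2))
  expect_equal(steps, rep(params$step_size, length(steps)),
               tolerance = 1e-9)

  # identical seeds give identical point lists
  sl2 <- propagate_streamline(st$fod, c(6.5, 6.5, 12), params)
  expect_identical(sl$points, sl2$points)

  # a seed voxel walled in by the mask boundary exits within a few steps
  lone <- uniform_fod_field(delta_fod(c(0, 0, 1)), c(3, 3, 3))
  lone$mask[] <- FALSE
  lone$mask[2, 2, 2] <- TRUE
  keep <- lone$voxels[, 1] == 1 & lone$voxels[, 2] == 1 & lone$voxels[, 3] == 1
  lone$coefficients <- lone$coefficients[keep, , drop = FALSE]
  lone$voxels <- lone$voxels[keep, , drop = FALSE]
  sl3 <- propagate_streamline(lone, c(1, 1, 1), tracking_params(rng_seed = 1))
  expect_equal(sl3$termination_reason, "exited_mask")
  expect_lt(nrow(sl3$points), 10)

  expect_error(propagate_streamline(st$fod, c(0.5, 0.5, 0.5),
                                    tracking_params()),
               "seed not in tracking domain")

  # nearest-neighbour interpolation is available and deterministic
  pn <- tracking_params(rng_seed = 17, interp = "nearest")
  sn1 <- propagate_streamline(st$fod, c(6.5, 6.5, 12), pn)
  sn2 <- propagate_streamline(st$fod, c(6.5, 6.5, 12), pn)
  expect_identical(sn1$points, sn2$points)
  expect_gt(nrow(sn1$points), 5)
})

test_that("visitation maps count each streamline once per voxel", {
  st <- fix$straight
  seedvox <- c(6, 6, 11)
  params <- tracking_params(n_streamlines_per_voxel = 500, rng_seed = 9)
  vm <- track_seed_voxel(st$fod, seedvox, params)
  expect_equal(max(vm$counts), 500)
  expect_equal(vm$counts[7, 7, 12], 500)          # the seed voxel itself
  expect_true(all(vm$counts >= 0 & vm$counts <= 500))

  # most streamlines reach the tube's far end in a coherent noise-free field
  far <- max(vm$counts[, , 20])
  expect_gt(far, 0.5 * 500)

  # untouched corner stays at zero
  expect_equal(vm$counts[1, 1, 1], 0L)

  # counts are monotone in the number of streamlines (shared seed prefix)
  vm_small <- track_seed_voxel(st$fod, seedvox,
    tracking_params(n_streamlines_per_voxel = 200, rng_seed = 9))
  expect_true(all(vm_small$counts <= vm$counts))

  # full determinism
  vm2 <- track_seed_voxel(st$fod, seedvox, params)
  expect_identical(vm$counts, vm2$counts)
})

test_that("spatially separated bundles stay separated in tracking", {
  truth <- make_bundle_phantom("two_arcs")
  targets <- make_label_volume(truth)
  dwi <- simulate_dwi(truth, fix$gt61, tissue_model(snr = Inf))
  fod <- fit_fod_field(dwi, response_from_tensor(1200, tissue_model()),
                       lambda = 1)
  # one seed voxel in the inner arc's start cap
  cap <- truth$bundles$inner$voxels[truth$bundles$inner$s <= 1, ,
                                    drop = FALSE]
  vm <- track_seed_voxel(fod, cap[1, ],
    tracking_params(n_streamlines_per_voxel = 1000, rng_seed = 13))
  outer_sel <- targets$labels %in%
    targets$names[c("outer_start", "outer_end")]
  expect_lt(max(vm$counts[outer_sel]), 0.001 * 1000 + 1e-9)
})
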