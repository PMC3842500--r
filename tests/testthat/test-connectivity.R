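# Connectivity module: spherical ROI geometry, max aggregation against
# target labels, and the matrix container's invariants.

grid_1mm <- list(dim = c(21, 21, 21), affine = diag(4))

test_that("spherical ROI voxel counts match the lattice enumeration", {
  ctr <- c(10, 10, 10)
  expect_equal(nrow(make_spherical_roi(ctr, 5, grid_1mm)$voxels), 515)
  expect_equal(nrow(make_spherical_roi(ctr, 0.4, grid_1mm)$voxels), 1)
  expect_equal(nrow(make_spherical_roi(ctr, 2, grid_1mm)$voxels), 33)
  for (r in 1:6)
    expect_equal(nrow(make_spherical_roi(ctr, r, grid_1mm)$voxels),
                 sphere_voxel_count_oracle(r))
})

test_that("ROI membership is inclusive and mask clipping is strict", {
  # boundary voxels at exactly radius distance are included
  roi <- make_spherical_roi(c(10, 10, 10), 3, grid_1mm)
  d <- sqrt(rowSums(sweep(roi$voxels, 2, c(10, 10, 10))^2))
  expect_true(any(abs(d - 3) < 1e-12))
  expect_true(all(d <= 3 + 1e-12))

  # clip mask: strictly positive probability retains a voxel
  pm <- array(0, grid_1mm$dim)
  pm[11, 11, 11] <- 0.2
  clipped <- make_spherical_roi(c(10, 10, 10), 3, grid_1mm, clip_mask = pm)
  expect_equal(nrow(clipped$voxels), 1)
  expect_error(make_spherical_roi(c(10, 10, 10), 3, grid_1mm,
                                  clip_mask = pm, threshold = 0.5),
               "ROI empty after clipping")
  expect_error(make_spherical_roi(c(100, 0, 0), 3, grid_1mm),
               "centre outside grid")
})

make_map <- function(counts, n_init, seed_voxel = c(0, 0, 0)) {
  structure(list(counts = counts, n_initiated = n_init,
                 seed_voxel = seed_voxel), class = "visitation_map")
}

test_that("region aggregation takes the max over maps and voxels", {
  dimz <- c(4, 4, 4)
  lab <- array(0L, dimz)
  lab[1, 1, 1] <- 1L; lab[2, 2, 2] <- 3L; lab[3, 3, 3] <- 2L
  targets <- structure(list(labels = lab,
                            names = c(regA = 1L, regB = 2L, regC = 3L)),
                       class = "label_volume")

  zero <- make_map(array(0L, dimz), 10000)
  expect_true(all(region_max_connectivity(list(zero), targets) == 0))

  m1 <- array(0L, dimz); m1[2, 2, 2] <- 7342L
  expect_equal(unname(region_max_connectivity(list(make_map(m1, 10000)),
                                              targets)["regC"]), 7342L)

  # two seed voxels hitting the same target voxel: max, not sum
  m2 <- array(0L, dimz); m2[2, 2, 2] <- 4000L
  m3 <- array(0L, dimz); m3[2, 2, 2] <- 9000L
  got <- region_max_connectivity(list(make_map(m2, 10000),
                                      make_map(m3, 10000)), targets)
  expect_equal(unname(got["regC"]), 9000L)
  # brute-force scan oracle over all maps and labelled voxels
  oracle <- max(vapply(list(m2, m3), function(m) max(m[lab == 3L]), 0L))
  expect_equal(unname(got["regC"]), oracle)

  expect_error(region_max_connectivity(list(zero), structure(
    list(labels = array(0L, dimz), names = integer(0)),
    class = "label_volume")), "no target regions")
})

test_that("deleting a target region zeroes exactly its column", {
  dimz <- c(4, 4, 4)
  lab <- array(0L, dimz)
  lab[1, 1, 1] <- 1L; lab[2, 2, 2] <- 2L
  tg <- structure(list(labels = lab, names = c(a = 1L, b = 2L)),
                  class = "label_volume")
  m <- array(0L, dimz); m[1, 1, 1] <- 5L; m[2, 2, 2] <- 9L
  maps <- list(make_map(m, 100))
  full <- region_max_connectivity(maps, tg)

  tg2 <- tg
  tg2$labels[tg2$labels == 2L] <- 0L
  dropped <- region_max_connectivity(maps, tg2)
  expect_equal(unname(dropped["b"]), 0L)
  expect_equal(dropped["a"], full["a"])
})

test_that("the matrix container enforces the 0..n_initiated range", {
  cm <- connectivity_matrix(matrix(c(0L, 10000L), 1), "s",
                            c("t1", "t2"), 10000)
  expect_equal(dim(cm$values), c(1, 2))
  expect_error(connectivity_matrix(matrix(10001L), "s", "t", 10000),
               "0, n_initiated")
  df <- as.data.frame(cm)
  expect_equal(df$value, c(0L, 10000L))
})
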