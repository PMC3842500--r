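# Phantom module: gradient schemes, bundle geometry, the multi-tensor
# forward model and cohort generation.

test_that("gradient schemes have the stated size, weighting and uniformity", {
  gt <- fix$gt61
  expect_length(gt$bvalues, 62)
  expect_equal(sum(gt$bvalues == 1200), 61)
  expect_equal(sum(gt$bvalues == 0), 1)

  small <- make_gradient_scheme(6, 1000, seed = 3)
  nrm <- sqrt(rowSums(small$directions^2))
  expect_equal(nrm[small$bvalues > 0], rep(1, 6), tolerance = 1e-9)

  # brute-force all-pairs angular separation (antipodally folded)
  X <- gt$directions[gt$bvalues > 0, ]
  G <- abs(X %*% t(X))
  diag(G) <- 0
  min_angle <- acos(min(max(G), 1)) * 180 / pi
  expect_gt(min_angle, 10)

  expect_error(make_gradient_scheme(5, 1000, seed = 1),
               "insufficient directions")
  # deterministic given seed
  expect_identical(make_gradient_scheme(20, 1000, seed = 9),
                   make_gradient_scheme(20, 1000, seed = 9))
})

test_that("bundle presets produce the designed geometry", {
  st <- fix$straight$truth
  b <- st$bundles$bundle
  expect_true(all(abs(b$orientations[, 1]) < 1e-9))
  expect_true(all(abs(b$orientations[, 3] - 1) < 1e-9))
  expect_equal(b$fraction, 1)

  cr <- make_bundle_phantom("crossing", shape = c(30, 30, 30),
                            crossing_angle = 90)
  tab <- picotract:::phantom_population_table(cr)
  overlap <- tab$lin[duplicated(tab$lin)]
  expect_gt(length(overlap), 0)
  for (l in unique(overlap)) {
    fr <- tab$fraction[tab$lin == l]
    expect_length(fr, 2)
    expect_equal(fr, c(0.5, 0.5))
  }

  ta <- make_bundle_phantom("two_arcs")
  expect_equal(nrow(ta$truth_connections), 2)
  # exhaustive voxel-set intersection: the tubes share no voxel
  lin <- function(v, d) v[, 1] + d[1] * (v[, 2] + d[2] * v[, 3])
  expect_length(intersect(lin(ta$bundles$inner$voxels, ta$shape),
                          lin(ta$bundles$outer$voxels, ta$shape)), 0)

  expect_error(make_bundle_phantom("two_arcs", shape = c(20, 20, 20)),
               "out of bounds")
})

test_that("the multi-tensor forward model matches its closed form", {
  m <- tissue_model(S0 = 100, snr = Inf)
  gt <- gradient_table(rbind(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0)),
                       c(0, 1200, 1200))
  s <- multi_tensor_signal(gt, c(0, 0, 1), 1, m)
  expect_equal(s[1], 100)                                  # b0
  expect_equal(s[2], 100 * exp(-1200 * 1.7e-3))            # along the fibre
  expect_equal(s[3], 100 * exp(-1200 * 3e-4))              # across: 69.768
  expect_equal(s[3], 69.768, tolerance = 1e-4)

  # mixed fractions include the isotropic compartment
  s2 <- multi_tensor_signal(gt, c(0, 0, 1), 0.6, m)
  expect_equal(s2[3], 100 * (0.6 * exp(-0.36) + 0.4 * exp(-1200 * 7e-4)))
})

test_that("signal is invariant under joint rotation of fibres and gradients", {
  m <- tissue_model(snr = Inf)
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3)  # 90 degrees about z
  set.seed(11)
  dirs <- matrix(rnorm(30), 10, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  gt1 <- gradient_table(rbind(0, dirs), c(0, rep(1200, 10)))
  gt2 <- gradient_table(rbind(0, dirs %*% t(R)), c(0, rep(1200, 10)))
  o <- c(0.6, 0.64, 0.48)
  s1 <- multi_tensor_signal(gt1, o, 0.8, m)
  s2 <- multi_tensor_signal(gt2, as.vector(R %*% o), 0.8, m)
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("Rician noise is biased upward and reproducible", {
  truth <- fix$straight$truth
  clean <- simulate_dwi(truth, fix$gt61, tissue_model(snr = Inf))
  noisy <- simulate_dwi(truth, fix$gt61, tissue_model(snr = 5, rng_seed = 2))
  sel <- which(truth$brain_mask)
  stopifnot(length(sel) * 62 > 10000)
  cs <- matrix(clean$signal, prod(truth$shape))[sel, ]
  ns <- matrix(noisy$signal, prod(truth$shape))[sel, ]
  expect_gt(mean(ns), mean(cs))
  # signal is non-negative everywhere and deterministic given the seed
  expect_true(all(noisy$signal >= 0))
  noisy2 <- simulate_dwi(truth, fix$gt61, tissue_model(snr = 5, rng_seed = 2))
  expect_identical(noisy$signal, noisy2$signal)
})

test_that("cohorts realise the designed connection presence", {
  truth <- make_bundle_phantom("two_arcs")
  m <- tissue_model(snr = 30)
  co <- make_cohort(truth, 13, "all", fix$gt61, m, seed = 4)
  expect_length(co$volumes, 13)
  expect_true(all(vapply(co$truths, function(t)
    nrow(t$truth_connections), 0L) == 2))

  pres <- matrix(TRUE, 13, 2, dimnames = list(NULL, c("inner", "outer")))
  pres[10:13, "inner"] <- FALSE   # inner present in exactly 9
  co9 <- make_cohort(truth, 13, pres, fix$gt61, m, seed = 4)
  n_with_inner <- sum(vapply(co9$truths, function(t)
    "inner" %in% names(t$bundles), TRUE))
  expect_equal(n_with_inner, 9)

  # all-absent participant: no anisotropic voxels remain
  none <- matrix(FALSE, 1, 2, dimnames = list(NULL, c("inner", "outer")))
  co0 <- make_cohort(truth, 1, none, fix$gt61, tissue_model(snr = Inf),
                     seed = 4)
  sig <- matrix(co0$volumes[[1]]$signal, prod(truth$shape))
  dwsel <- fix$gt61$bvalues > 0
  inmask <- which(truth$brain_mask)
  spread <- apply(sig[inmask, dwsel], 1, function(x) diff(range(x)))
  expect_lt(max(spread), 1e-9)    # isotropic signal in every masked voxel

  # bit-reproducible for a fixed master seed
  co_a <- make_cohort(truth, 3, "all", fix$gt61, m, seed = 7)
  co_b <- make_cohort(truth, 3, "all", fix$gt61, m, seed = 7)
  expect_identical(lapply(co_a$volumes, `[[`, "signal"),
                   lapply(co_b$volumes, `[[`, "signal"))
})

test_that("label volumes give each endpoint a unique disjoint label", {
  ta <- make_bundle_phantom("two_arcs")
  lv <- make_label_volume(ta)
  expect_length(lv$names, 4)
  expect_setequal(unique(as.vector(lv$labels)), c(0L, 1L, 2L, 3L, 4L))

  st <- make_bundle_phantom("straight", shape = c(14, 14, 24))
  lv2 <- make_label_volume(st)
  expect_length(lv2$names, 2)

  # disjointness: every labelled voxel carries exactly one label by
  # construction; the per-region voxel counts must sum to the labelled total
  per_region <- vapply(lv$names, function(l) sum(lv$labels == l), 0)
  expect_equal(sum(per_region), sum(lv$labels > 0))
})
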