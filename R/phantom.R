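## Digital fibre phantoms: ground-truth bundle geometries, the multi-tensor
## forward model with Rician noise, synthetic cohorts and endpoint label
## volumes. These stand in for acquired DWI so that every downstream stage is
## testable against known connections.

#' Tissue model parameters for the multi-tensor forward simulation
#'
#' @param S0 b = 0 signal level (arbitrary units).
#' @param lambda_parallel axial diffusivity of the fibre compartment
#'   (mm^2/s); default 1.7e-3, a typical white-matter value.
#' @param lambda_perp radial diffusivity of the fibre compartment (mm^2/s).
#' @param lambda_iso diffusivity of the isotropic (non-fibre) compartment.
#' @param snr signal-to-noise ratio at b = 0 (S0 / Gaussian sigma); `Inf`
#'   turns noise off.
#' @param rng_seed integer seed for the noise realisation.
#' @return object of class `tissue_model`.
#' @export
tissue_model <- function(S0 = 100, lambda_parallel = 1.7e-3,
                         lambda_perp = 3e-4, lambda_iso = 7e-4,
                         snr = 30, rng_seed = 1) {
  stopifnot(S0 > 0, snr > 0, lambda_perp > 0,
            lambda_parallel >= lambda_perp, lambda_iso > 0)
  structure(list(S0 = S0, lambda_parallel = lambda_parallel,
                 lambda_perp = lambda_perp, lambda_iso = lambda_iso,
                 snr = snr, rng_seed = as.integer(rng_seed)),
            class = "tissue_model")
}

# sample a space curve: returns points (m x 3, mm), unit tangents, arclength s
sample_centreline <- function(fun, total_len, ds = 0.25) {
  s <- seq(0, total_len, by = ds)
  if (s[length(s)] < total_len) s <- c(s, total_len)
  g <- fun(s)
  list(points = g$points, tangents = g$tangents, s = s, length = total_len)
}

arc_curve <- function(centre, radius, plane_normal = c(0, 1, 0)) {
  # semicircle in the plane y = centre[2], rising from z = centre[3]
  function(s) {
    th <- s / radius
    pts <- cbind(centre[1] - radius * cos(th), centre[2],
                 centre[3] + radius * sin(th))
    tg <- cbind(sin(th), 0, cos(th))
    list(points = pts, tangents = tg)
  }
}

line_curve <- function(start, direction) {
  direction <- direction / sqrt(sum(direction^2))
  function(s) {
    pts <- cbind(start[1] + s * direction[1], start[2] + s * direction[2],
                 start[3] + s * direction[3])
    list(points = pts, tangents = matrix(direction, length(s), 3, byrow = TRUE))
  }
}

#' Construct a ground-truth fibre phantom
#'
#' Builds one of four preset bundle geometries inside an isotropic voxel grid:
#' `straight` (one tube along z), `arc` (one semicircular tube), `two_arcs`
#' (two parallel, non-touching arc-shaped tubes mimicking an inner and an
#' outer crescent) and `crossing` (two straight tubes crossing at
#' `crossing_angle` through the volume centre). Every voxel inside a tube
#' carries that bundle's local tangent orientation; voxels inside several
#' tubes carry one population per bundle with equal fractions. The tube caps
#' (first and last `cap_length` mm of arclength) define endpoint regions, and
#' each bundle contributes one ground-truth connection between its two
#' endpoints. The brain mask is the tube union dilated by `mask_dilation`
#' voxels; inside the mask but outside any tube the tissue is purely
#' isotropic, outside the mask there is no signal.
#'
#' @param preset geometry preset name.
#' @param shape integer grid dimensions (voxels).
#' @param voxel_size isotropic voxel size (mm).
#' @param tube_radius bundle tube radius (mm).
#' @param crossing_angle crossing angle in degrees (crossing preset only).
#' @param arc_radii radii (mm) of the inner and outer arcs (two_arcs preset);
#'   the default 8/17 mm pair keeps the tube surfaces 5 mm apart so the
#'   bundles are genuinely disjoint.
#' @param mask_dilation brain-mask dilation beyond the tube surface (voxels).
#' @param cap_length arclength (mm) of the endpoint cap regions.
#' @return object of class `phantom_truth`.
#' @export
make_bundle_phantom <- function(preset = c("straight", "arc", "two_arcs",
                                           "crossing"),
                                shape = c(40, 40, 40), voxel_size = 1,
                                tube_radius = 2, crossing_angle = 90,
                                arc_radii = c(8, 17), mask_dilation = 2,
                                cap_length = 3) {
  preset <- match.arg(preset)
  shape <- as.integer(shape)
  vs <- voxel_size
  ext <- (shape - 1) * vs                # voxel-centre extent per axis
  ctr <- ext / 2
  margin <- tube_radius + 2 * vs

  curves <- switch(preset,
    straight = {
      L <- ext[3] - 2 * margin
      list(bundle = sample_centreline(
        line_curve(c(ctr[1], ctr[2], margin), c(0, 0, 1)), L))
    },
    arc = {
      r <- arc_radii[1]
      base <- c(ctr[1], ctr[2], margin)
      list(arc = sample_centreline(arc_curve(base, r), pi * r))
    },
    two_arcs = {
      base <- c(ctr[1], ctr[2], margin)
      list(inner = sample_centreline(arc_curve(base, arc_radii[1]),
                                     pi * arc_radii[1]),
           outer = sample_centreline(arc_curve(base, arc_radii[2]),
                                     pi * arc_radii[2]))
    },
    crossing = {
      a <- crossing_angle * pi / 180
      L <- 0.6 * min(ext)
      u1 <- c(sin(a / 2), 0, cos(a / 2))
      u2 <- c(-sin(a / 2), 0, cos(a / 2))
      list(cross1 = sample_centreline(line_curve(ctr - u1 * L / 2, u1), L),
           cross2 = sample_centreline(line_curve(ctr - u2 * L / 2, u2), L))
    })

  # bounds check: the tube surface must stay inside the volume
  lo <- -vs / 2
  hi <- ext + vs / 2
  for (nm in names(curves)) {
    P <- curves[[nm]]$points
    if (any(sweep(P, 2, lo, "-") < tube_radius - vs / 2) ||
        any(sweep(P, 2, hi, "-") > -(tube_radius - vs / 2)))
      stop("geometry out of bounds: bundle '", nm,
           "' tube exits the volume")
  }

  affine <- diag(c(vs, vs, vs, 1))
  nvox <- prod(shape)
  brain <- array(FALSE, dim = shape)
  mask_r <- tube_radius + mask_dilation * vs

  bundles <- list()
  for (nm in names(curves)) {
    cl <- curves[[nm]]
    P <- cl$points
    bb_lo <- pmax(floor((apply(P, 2, min) - mask_r) / vs), 0)
    bb_hi <- pmin(ceiling((apply(P, 2, max) + mask_r) / vs), shape - 1)
    gx <- bb_lo[1]:bb_hi[1]
    gy <- bb_lo[2]:bb_hi[2]
    gz <- bb_lo[3]:bb_hi[3]
    vox <- as.matrix(expand.grid(i = gx, j = gy, k = gz))
    centres <- vox * vs
    # nearest centreline sample per candidate voxel, chunked
    n <- nrow(vox)
    dmin <- numeric(n)
    amin <- integer(n)
    chunk <- 4096L
    for (off in seq(1, n, by = chunk)) {
      sel <- off:min(off + chunk - 1, n)
      D2 <- outer(rowSums(centres[sel, , drop = FALSE]^2), rowSums(P^2), "+") -
        2 * centres[sel, , drop = FALSE] %*% t(P)
      amin[sel] <- max.col(-D2, ties.method = "first")
      dmin[sel] <- sqrt(pmax(D2[cbind(seq_along(sel), amin[sel])], 0))
    }
    inmask <- dmin <= mask_r
    brain[vox[inmask, , drop = FALSE] + 1] <- TRUE
    intube <- dmin <= tube_radius
    bundles[[nm]] <- list(
      name = nm,
      voxels = vox[intube, , drop = FALSE],
      orientations = cl$tangents[amin[intube], , drop = FALSE],
      s = cl$s[amin[intube]],
      length = cl$length,
      fraction = 1)
  }

  conn <- data.frame(
    bundle = names(bundles),
    seed = paste0(names(bundles), "_start"),
    target = paste0(names(bundles), "_end"),
    stringsAsFactors = FALSE)

  structure(list(shape = shape, voxel_size = vs, affine = affine,
                 bundles = bundles, brain_mask = brain,
                 cap_length = cap_length, tube_radius = tube_radius,
                 truth_connections = conn),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> ", paste(x$shape, collapse = "x"), " voxels @ ",
      x$voxel_size, " mm; bundles: ",
      paste(names(x$bundles), collapse = ", "), "; ",
      nrow(x$truth_connections), " true connection(s)\n", sep = "")
  invisible(x)
}

# per-voxel population table with equal fraction split in overlap voxels:
# columns lin (1-based linear voxel id), bundle, ox/oy/oz, fraction
phantom_population_table <- function(truth) {
  if (length(truth$bundles) == 0)
    return(data.frame(lin = integer(0), bundle = character(0),
                      ox = numeric(0), oy = numeric(0), oz = numeric(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  tabs <- lapply(truth$bundles, function(b) {
    lin <- 1L + b$voxels[, 1] + truth$shape[1] *
      (b$voxels[, 2] + truth$shape[2] * b$voxels[, 3])
    data.frame(lin = lin, bundle = b$name, ox = b$orientations[, 1],
               oy = b$orientations[, 2], oz = b$orientations[, 3],
               fraction = b$fraction, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  mult <- table(tab$lin)
  tab$fraction <- tab$fraction / as.integer(mult[as.character(tab$lin)])
  rownames(tab) <- NULL
  tab
}

#' Closed-form multi-tensor DWI signal for one voxel
#'
#' Evaluates the noise-free forward model
#' `S(g) = S0 * (sum_j f_j exp(-b g' D_j g) + (1 - sum f_j) exp(-b lambda_iso))`
#' with axially symmetric diffusion tensors (axial diffusivity along each
#' population's orientation, radial diffusivity across).
#'
#' @param gradients a [gradient_table].
#' @param orientations k x 3 matrix of unit population orientations.
#' @param fractions k fibre volume fractions summing to <= 1.
#' @param model a [tissue_model].
#' @return numeric vector of signals, one per gradient-table entry.
#' @export
multi_tensor_signal <- function(gradients, orientations, fractions, model) {
  orientations <- matrix(orientations, ncol = 3)
  stopifnot(length(fractions) == nrow(orientations),
            sum(fractions) <= 1 + 1e-9)
  b <- gradients$bvalues
  if (max(b) * model$lambda_parallel > 700)
    warning("diffusion exponent underflow; signal clipped to 0")
  g <- gradients$directions
  S <- rep((1 - sum(fractions)) * exp(-b * model$lambda_iso), 1)
  if (nrow(orientations) > 0) {
    M2 <- (orientations %*% t(g))^2            # k x ngrad
    ad <- model$lambda_perp +
      (model$lambda_parallel - model$lambda_perp) * M2
    E <- exp(-sweep(ad, 2, b, "*"))
    S <- S + as.vector(fractions %*% E)
  }
  model$S0 * S
}

#' Simulate a diffusion-weighted volume from a phantom
#'
#' Applies the multi-tensor forward model per voxel (isotropic compartment for
#' the non-fibre fraction, zero signal outside the brain mask) and then Rician
#' noise: `S_noisy = sqrt((S + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma^2)`
#' and `sigma = S0 / snr`. Deterministic given `rng_seed`.
#'
#' @param truth a [make_bundle_phantom] ground truth.
#' @param gradients a [gradient_table].
#' @param model a [tissue_model].
#' @param rng_seed noise seed; defaults to the model's.
#' @return object of class `dwi_volume` with fields `signal` (4D array),
#'   `gradients`, `affine` and `brain_mask`.
#' @export
simulate_dwi <- function(truth, gradients, model,
                         rng_seed = model$rng_seed) {
  shape <- truth$shape
  ngrad <- length(gradients$bvalues)
  nvox <- prod(shape)
  b <- gradients$bvalues
  g <- gradients$directions
  sig <- matrix(0, nvox, ngrad)

  mask_lin <- which(truth$brain_mask)
  totfrac <- numeric(nvox)
  tab <- phantom_population_table(truth)
  if (nrow(tab) > 0) {
    O <- as.matrix(tab[, c("ox", "oy", "oz")])
    M2 <- (O %*% t(g))^2
    ad <- model$lambda_perp +
      (model$lambda_parallel - model$lambda_perp) * M2
    E <- exp(-sweep(ad, 2, b, "*")) * tab$fraction
    # accumulate (several populations may share a voxel)
    for (grp in split(seq_len(nrow(tab)), tab$lin)) {
      lin <- tab$lin[grp[1]]
      sig[lin, ] <- sig[lin, ] + colSums(E[grp, , drop = FALSE])
    }
    tf <- vapply(split(tab$fraction, tab$lin), sum, 0)
    totfrac[as.integer(names(tf))] <- tf
  }
  iso <- exp(-b * model$lambda_iso)
  sig[mask_lin, ] <- sig[mask_lin, ] +
    outer(1 - totfrac[mask_lin], iso)
  sig <- model$S0 * sig

  if (is.finite(model$snr)) {
    sigma <- model$S0 / model$snr
    sig <- with_rng_seed(rng_seed, {
      n1 <- matrix(rnorm(length(sig), 0, sigma), nrow(sig))
      n2 <- matrix(rnorm(length(sig), 0, sigma), nrow(sig))
      sqrt((sig + n1)^2 + n2^2)
    })
  }

  structure(list(signal = array(sig, c(shape, ngrad)), gradients = gradients,
                 affine = truth$affine, brain_mask = truth$brain_mask),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat("<dwi_volume> ", paste(d[1:3], collapse = "x"), " voxels, ",
      d[4], " gradient volumes, ", sum(x$brain_mask),
      " voxels in brain mask\n", sep = "")
  invisible(x)
}

#' Simulate a cohort with designed connection presence/absence
#'
#' Each participant gets an independent noise realisation (seed
#' `seed + participant index`). Bundles whose connection is marked absent for
#' a participant are removed from that participant's ground truth before the
#' signal simulation; the brain mask (the shared "anatomy" envelope) stays
#' identical across participants.
#'
#' @param truth full phantom ground truth.
#' @param n_participants cohort size.
#' @param presence logical matrix `n_participants` x bundles (colnames are
#'   bundle names), or `"all"` for a fully present cohort.
#' @param gradients a [gradient_table].
#' @param model a [tissue_model].
#' @param seed master seed from which per-participant seeds are derived.
#' @return object of class `phantom_cohort`: lists `volumes` and `truths`
#'   plus the resolved presence matrix.
#' @export
make_cohort <- function(truth, n_participants, presence, gradients, model,
                        seed) {
  if (n_participants < 1) stop("n_participants must be >= 1")
  bn <- names(truth$bundles)
  if (identical(presence, "all"))
    presence <- matrix(TRUE, n_participants, length(bn),
                       dimnames = list(NULL, bn))
  presence <- as.matrix(presence)
  if (!all(bn %in% colnames(presence)))
    stop("presence must be defined for every bundle/connection: ",
         paste(setdiff(bn, colnames(presence)), collapse = ", "))
  if (nrow(presence) != n_participants)
    stop("presence has ", nrow(presence), " rows for ", n_participants,
         " participants")

  truths <- vector("list", n_participants)
  volumes <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    tp <- truth
    keep <- bn[presence[p, bn]]
    tp$bundles <- truth$bundles[keep]
    tp$truth_connections <-
      truth$truth_connections[truth$truth_connections$bundle %in% keep, ,
                              drop = FALSE]
    truths[[p]] <- tp
    volumes[[p]] <- simulate_dwi(tp, gradients, model,
                                 rng_seed = seed + p)
  }
  structure(list(volumes = volumes, truths = truths,
                 presence = presence[, bn, drop = FALSE],
                 master_seed = seed),
            class = "phantom_cohort")
}

#' Integer label volume of bundle endpoint regions
#'
#' Gives each bundle endpoint cap (the first and last `cap_length` mm of tube
#' arclength) a unique positive integer label, 0 elsewhere; regions are
#' checked to be disjoint. These synthetic labels play the role that an
#' anatomical target-region atlas plays for acquired data.
#'
#' @param truth a [make_bundle_phantom] ground truth (always the full
#'   phantom, so all participants share one target scheme).
#' @return object of class `label_volume`: integer array `labels` plus a
#'   named vector `names` mapping region name to label.
#' @export
make_label_volume <- function(truth) {
  lab <- array(0L, dim = truth$shape)
  nm <- integer(0)
  nxt <- 1L
  for (b in truth$bundles) {
    for (side in c("start", "end")) {
      selv <- if (side == "start") b$s <= truth$cap_length
              else b$s >= b$length - truth$cap_length
      vox <- b$voxels[selv, , drop = FALSE] + 1
      if (any(lab[vox] != 0))
        stop("endpoint regions overlap; labels must be disjoint")
      lab[vox] <- nxt
      nm[paste0(b$name, "_", side)] <- nxt
      nxt <- nxt + 1L
    }
  }
  structure(list(labels = lab, names = nm), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", length(x$names), " regions: ",
      paste(names(x$names), collapse = ", "), "\n", sep = "")
  invisible(x)
}
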