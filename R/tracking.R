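## PICo-style Monte-Carlo streamline propagation: importance sampling of FOD
## amplitudes on a fixed sphere set, bidirectional propagation with the
## printed stopping rules, and per-seed-voxel visitation maps.

#' Tracking parameters
#'
#' Defaults follow the emulated acquisition protocol: 10,000 streamlines per
#' seed voxel, 0.50 mm steps, a 500 mm physical path limit and termination
#' when pathway curvature over a voxel exceeds 180 degrees.
#'
#' @param n_streamlines_per_voxel streamlines initiated per seed voxel.
#' @param step_size step length (mm); must not exceed the voxel size.
#' @param max_path_length physical path limit (mm).
#' @param curvature_limit maximum cumulative turning angle within one voxel
#'   (degrees).
#' @param fod_amplitude_threshold tracking stops where no permitted FOD
#'   amplitude reaches this value.
#' @param rng_seed base RNG seed for the Monte-Carlo draws.
#' @param n_sphere size of the precomputed direction set used for FOD
#'   sampling.
#' @param interp interpolation of the SH coefficients at the tracking
#'   position: `"trilinear"` (default) or `"nearest"` (nearest voxel).
#' @return object of class `tracking_params`.
#' @export
tracking_params <- function(n_streamlines_per_voxel = 10000, step_size = 0.5,
                            max_path_length = 500, curvature_limit = 180,
                            fod_amplitude_threshold = 0.1, rng_seed = 1,
                            n_sphere = 724,
                            interp = c("trilinear", "nearest")) {
  interp <- match.arg(interp)
  stopifnot(n_streamlines_per_voxel > 0, step_size > 0, max_path_length > 0,
            curvature_limit > 0, fod_amplitude_threshold >= 0)
  structure(list(n_streamlines_per_voxel = as.integer(n_streamlines_per_voxel),
                 step_size = step_size, max_path_length = max_path_length,
                 curvature_limit = curvature_limit,
                 fod_amplitude_threshold = fod_amplitude_threshold,
                 rng_seed = as.integer(rng_seed),
                 n_sphere = as.integer(n_sphere), interp = interp),
            class = "tracking_params")
}

termination_reasons <- c("none", "curvature", "max_length", "exited_mask",
                         "low_fod")

# Precompute what the compiled tracker needs: per-voxel FOD amplitudes on the
# sampling sphere (amplitude is linear in the SH coefficients, so
# interpolating amplitudes equals interpolating coefficients), a voxel ->
# field-column lookup grid, and both affine directions.
prepare_tracking_field <- function(fod_field, n_sphere = 724) {
  dirs <- fibonacci_sphere(n_sphere)
  B <- sh_basis(dirs, fod_field$lmax)
  ampT <- B %*% t(fod_field$coefficients)      # n_sphere x nmask
  idx <- array(-1L, dim = fod_field$dim)
  idx[fod_field$voxels + 1] <- seq_len(ncol(ampT)) - 1L
  minv <- solve(fod_field$affine)
  list(ampT = ampT, idx = as.integer(idx), dim = as.integer(fod_field$dim),
       dirs = dirs, minv = minv[1:3, , drop = FALSE],
       affine = fod_field$affine[1:3, , drop = FALSE])
}

check_step_size <- function(fod_field, params) {
  vs <- min(sqrt(colSums(fod_field$affine[1:3, 1:3]^2)))
  if (params$step_size > vs + 1e-9)
    stop("step_size (", params$step_size, " mm) exceeds voxel size (",
         vs, " mm)")
}

#' Draw propagation directions from the FOD at a position
#'
#' Trilinearly interpolates the FOD at a world-mm position and draws
#' directions with probability proportional to `max(amplitude, 0)` over a
#' precomputed sphere set, restricted to the hemisphere within 90 degrees of
#' `previous_direction` (full sphere when `NULL`). Draws come from the
#' current R RNG stream.
#'
#' @param fod_field a `fod_field`.
#' @param position world coordinate (mm, length 3).
#' @param previous_direction unit 3-vector or `NULL`.
#' @param n number of draws.
#' @param params a [tracking_params] (supplies the amplitude threshold and
#'   sphere size).
#' @return an `n` x 3 matrix of unit vectors (a plain length-3 vector when
#'   `n = 1`).
#' @export
sample_direction <- function(fod_field, position, previous_direction = NULL,
                             n = 1, params = tracking_params()) {
  fld <- prepare_tracking_field(fod_field, params$n_sphere)
  v <- fld$minv %*% c(position, 1)
  vox <- round(v)
  inside <- all(vox >= 0) && all(vox < fld$dim)
  if (!inside || fld$idx[1 + vox[1] + fld$dim[1] *
                           (vox[2] + fld$dim[2] * vox[3])] < 0)
    stop("position outside the field mask")
  res <- cpp_sample_directions(fld$ampT, fld$idx, fld$dim, fld$dirs,
                               fld$minv, fld$affine, as.numeric(position),
                               previous_direction, as.integer(n),
                               params$fod_amplitude_threshold,
                               identical(params$interp, "nearest"))
  if (!res$ok)
    stop("low_fod: all permitted FOD amplitudes below threshold")
  if (n == 1) as.vector(res$directions[1, ]) else res$directions
}

#' Propagate one probabilistic streamline
#'
#' Propagates bidirectionally from a world-mm seed point: a first half-track
#' starts with an unrestricted draw, the second half-track starts in the
#' opposite hemisphere, and the two are concatenated through the seed point.
#' Each step advances `step_size` along a freshly sampled direction. Tracking
#' stops when the cumulative turning angle within a voxel exceeds the
#' curvature limit, the physical path limit is reached (the two half-tracks
#' share one step budget), the streamline leaves the field mask, or no
#' permitted FOD amplitude reaches the threshold.
#'
#' @param fod_field a `fod_field`.
#' @param seed_point world coordinate (mm).
#' @param params a [tracking_params]; its `rng_seed` makes the draw
#'   deterministic.
#' @return object of class `streamline`: `points` (ordered coordinates),
#'   `termination_reason` and `step_size`.
#' @export
propagate_streamline <- function(fod_field, seed_point,
                                 params = tracking_params()) {
  check_step_size(fod_field, params)
  fld <- prepare_tracking_field(fod_field, params$n_sphere)
  v <- round(fld$minv %*% c(seed_point, 1))
  if (any(v < 0) || any(v >= fld$dim) ||
      fld$idx[1 + v[1] + fld$dim[1] * (v[2] + fld$dim[2] * v[3])] < 0)
    stop("seed not in tracking domain")
  res <- with_rng_seed(params$rng_seed,
    cpp_propagate(fld$ampT, fld$idx, fld$dim, fld$dirs, fld$minv,
                  fld$affine, as.numeric(seed_point), params$step_size,
                  params$max_path_length, params$curvature_limit,
                  params$fod_amplitude_threshold,
                  identical(params$interp, "nearest")))
  structure(list(points = res$points,
                 termination_reason = termination_reasons[res$reason + 1],
                 step_size = params$step_size),
            class = "streamline")
}

#' @export
print.streamline <- function(x, ...) {
  cat("<streamline> ", nrow(x$points), " points, arc length ",
      (nrow(x$points) - 1) * x$step_size, " mm, terminated: ",
      x$termination_reason, "\n", sep = "")
  invisible(x)
}

#' Visitation map from one seed voxel
#'
#' Initiates `n_streamlines_per_voxel` streamlines from start points jittered
#' uniformly within the seed voxel and records, per voxel, the number of
#' distinct streamlines that encountered it (binary visitation per
#' streamline). The seed voxel is encountered by every streamline, so its
#' count equals the number initiated. The RNG stream is seeded with
#' `params$rng_seed` plus the seed voxel's linear index, so maps for
#' different voxels are independent and the whole map is reproducible.
#'
#' @param fod_field a `fod_field`.
#' @param voxel 0-based voxel index (length 3) inside the field mask.
#' @param params a [tracking_params].
#' @return object of class `visitation_map`: integer `counts` array,
#'   `n_initiated` and `seed_voxel`.
#' @export
track_seed_voxel <- function(fod_field, voxel, params = tracking_params()) {
  maps <- track_voxels(fod_field, matrix(voxel, 1), params)
  maps[[1]]
}

# shared bulk driver: one visitation map per seed voxel
track_voxels <- function(fod_field, voxels, params = tracking_params()) {
  check_step_size(fod_field, params)
  voxels <- matrix(as.integer(voxels), ncol = 3)
  fld <- prepare_tracking_field(fod_field, params$n_sphere)
  lin <- voxels[, 1] + fld$dim[1] * (voxels[, 2] + fld$dim[2] * voxels[, 3])
  if (any(fld$idx[lin + 1] < 0))
    stop("seed not in tracking domain")
  lapply(seq_len(nrow(voxels)), function(i) {
    counts <- with_rng_seed(params$rng_seed + lin[i],
      cpp_track_voxels(fld$ampT, fld$idx, fld$dim, fld$dirs, fld$minv,
                       fld$affine, voxels[i, , drop = FALSE],
                       params$n_streamlines_per_voxel, params$step_size,
                       params$max_path_length, params$curvature_limit,
                       params$fod_amplitude_threshold,
                       identical(params$interp, "nearest")))[[1]]
    structure(list(counts = array(counts, fld$dim),
                   n_initiated = params$n_streamlines_per_voxel,
                   seed_voxel = voxels[i, ]),
              class = "visitation_map")
  })
}

#' @export
print.visitation_map <- function(x, ...) {
  cat("<visitation_map> seed voxel (", paste(x$seed_voxel, collapse = ", "),
      "), ", x$n_initiated, " streamlines, ", sum(x$counts > 0),
      " voxels visited\n", sep = "")
  invisible(x)
}
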