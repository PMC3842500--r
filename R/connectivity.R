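## Seed ROIs, target label aggregation and the seed x target
## maximum-connectivity matrix.

# accept several grid-bearing objects
grid_of <- function(x) {
  if (inherits(x, "dwi_volume")) list(dim = dim(x$signal)[1:3],
                                      affine = x$affine)
  else if (inherits(x, "fod_field")) list(dim = x$dim, affine = x$affine)
  else if (inherits(x, "phantom_truth")) list(dim = x$shape,
                                              affine = x$affine)
  else if (is.list(x) && !is.null(x$dim) && !is.null(x$affine)) x
  else stop("cannot extract a grid (dim + affine) from this object")
}

#' Spherical seed region of interest
#'
#' Collects every voxel whose centre lies within `radius` mm (inclusive) of
#' the given world-mm centre. When a clip mask is supplied (e.g. a
#' probabilistic anatomical map), voxels whose mask value is not strictly
#' above `threshold` are removed, so by default any non-zero probability
#' retains the voxel.
#'
#' @param centre world coordinate (mm).
#' @param radius sphere radius (mm).
#' @param grid an object carrying the voxel grid (a `dwi_volume`,
#'   `fod_field`, `phantom_truth`, or a list with `dim` and `affine`).
#' @param clip_mask optional numeric/logical 3D array.
#' @param threshold clip threshold (default 0: keep strictly positive mask
#'   values).
#' @param label ROI name.
#' @return object of class `seed_roi` with the 0-based member `voxels`.
#' @export
make_spherical_roi <- function(centre, radius, grid, clip_mask = NULL,
                               threshold = 0, label = "roi") {
  g <- grid_of(grid)
  stopifnot(radius > 0)
  minv <- solve(g$affine)
  vc <- (minv %*% c(centre, 1))[1:3]
  if (any(vc < -0.5) || any(vc > g$dim - 0.5))
    stop("centre outside grid")
  # bounding box in voxel space, then exact distance on voxel centres
  vs <- sqrt(colSums(g$affine[1:3, 1:3]^2))
  lo <- pmax(floor(vc - radius / vs - 1), 0)
  hi <- pmin(ceiling(vc + radius / vs + 1), g$dim - 1)
  vox <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                               k = lo[3]:hi[3]))
  w <- t(g$affine[1:3, , drop = FALSE] %*% rbind(t(vox), 1))
  d <- sqrt(rowSums(sweep(w, 2, centre)^2))
  vox <- vox[d <= radius, , drop = FALSE]
  if (!is.null(clip_mask)) {
    keep <- clip_mask[vox + 1] > threshold
    vox <- vox[keep, , drop = FALSE]
  }
  if (nrow(vox) == 0) stop("ROI empty after clipping")
  structure(list(label = label, centre = centre, radius = radius,
                 voxels = unname(vox)),
            class = "seed_roi")
}

#' @export
print.seed_roi <- function(x, ...) {
  cat("<seed_roi> '", x$label, "': ", nrow(x$voxels), " voxels, radius ",
      x$radius, " mm at (", paste(signif(x$centre, 4), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Maximum connectivity of one seed ROI to each target region
#'
#' For each target region the connectivity value is the maximum, over the
#' ROI's per-seed-voxel visitation maps and over the region's voxels, of the
#' visitation count. Max (not sum) aggregation keeps values within
#' `[0, n_initiated]` regardless of ROI size.
#'
#' @param maps list of `visitation_map`s, one per seed voxel.
#' @param targets a `label_volume`.
#' @return named integer vector, one value per target region.
#' @export
region_max_connectivity <- function(maps, targets) {
  if (all(targets$labels == 0)) stop("no target regions")
  out <- integer(length(targets$names))
  names(out) <- names(targets$names)
  for (r in seq_along(targets$names)) {
    sel <- targets$labels == targets$names[r]
    if (!any(sel)) next   # region without voxels: no connectivity
    out[r] <- max(vapply(maps, function(m) max(m$counts[sel]), integer(1)))
  }
  out
}

#' Build a seed x target connectivity matrix
#'
#' Tracks every voxel of every seed ROI and aggregates visitation maps per
#' target region with [region_max_connectivity].
#'
#' @param fod_field a `fod_field`.
#' @param rois list of `seed_roi`s.
#' @param targets a `label_volume`.
#' @param params a [tracking_params].
#' @return object of class `connectivity_matrix`: integer `values`
#'   (seeds x targets), labels and `n_initiated`.
#' @export
seed_connectivity <- function(fod_field, rois, targets,
                              params = tracking_params()) {
  rows <- lapply(rois, function(roi) {
    maps <- track_voxels(fod_field, roi$voxels, params)
    region_max_connectivity(maps, targets)
  })
  connectivity_matrix(do.call(rbind, rows),
                      vapply(rois, `[[`, "", "label"),
                      names(targets$names),
                      params$n_streamlines_per_voxel)
}

#' Connectivity matrix container
#'
#' @param values integer matrix seeds x targets.
#' @param seed_labels,target_labels dimension names.
#' @param n_initiated streamlines initiated per seed voxel (upper bound for
#'   every entry).
#' @return object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(values, seed_labels, target_labels,
                                n_initiated) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(seed_labels),
            ncol(values) == length(target_labels))
  if (any(values < 0) || any(values > n_initiated))
    stop("connectivity values must lie in [0, n_initiated]")
  dimnames(values) <- list(seed_labels, target_labels)
  structure(list(values = values, seed_labels = seed_labels,
                 target_labels = target_labels,
                 n_initiated = n_initiated),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("<connectivity_matrix> ", length(x$seed_labels), " seed ROI(s) x ",
      length(x$target_labels), " target region(s), counts in [0, ",
      x$n_initiated, "]\n", sep = "")
  print(x$values)
  invisible(x)
}

#' @export
as.data.frame.connectivity_matrix <- function(x, ...) {
  data.frame(seed = rep(x$seed_labels, times = length(x$target_labels)),
             target = rep(x$target_labels, each = length(x$seed_labels)),
             value = as.vector(x$values), stringsAsFactors = FALSE)
}
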