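## End-to-end pipeline: phantom cohort -> response + CSD -> tracking ->
## connectivity matrices -> two-level group inference, with a serialisable
## configuration.

#' Pipeline configuration
#'
#' Collects every stage parameter with defaults that reproduce the emulated
#' protocol: a 61-direction b = 1200 s/mm^2 + 1 b0 scheme, 10,000 streamlines
#' per seed voxel, 0.50 mm steps, a 500 mm path limit, a 180 degree per-voxel
#' curvature limit, the Poisson threshold at p = .05 and the 75%/50%
#' consistency criteria.
#'
#' @param preset phantom geometry preset.
#' @param shape,voxel_size,tube_radius,arc_radii,crossing_angle phantom
#'   geometry (see [make_bundle_phantom]).
#' @param n_participants cohort size.
#' @param presence `"all"`, or a named list mapping bundle name to either the
#'   number of participants (the first k) or a logical vector marking the
#'   participants in which that bundle's connection is present.
#' @param n_directions,b_value gradient scheme.
#' @param S0,snr tissue model signal level and signal-to-noise ratio.
#' @param response `"truth_mask"` (estimate from ground-truth single-fibre
#'   voxels) or `"analytic"` (tensor-convolution response).
#' @param lmax,tau,n_constraint_dirs,csd_max_iter,csd_lambda CSD parameters
#'   (see [fit_csd]).
#' @param n_streamlines,step_size,max_path_length,curvature_limit,fod_amplitude_threshold
#'   tracking parameters (see [tracking_params]).
#' @param roi_radius seed-ROI sphere radius in mm; ROIs are clipped to their
#'   endpoint region mask, mirroring how anatomical seed spheres are clipped
#'   to probabilistic region boundaries.
#' @param alpha,strict_frac,relaxed_frac group-inference parameters.
#' @param seed master seed; every stage derives its stream from it.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = "two_arcs", shape = c(40, 40, 40),
                            voxel_size = 1, tube_radius = 2,
                            arc_radii = c(8, 17), crossing_angle = 90,
                            n_participants = 13, presence = "all",
                            n_directions = 61, b_value = 1200,
                            S0 = 100, snr = 30,
                            response = "truth_mask",
                            lmax = 8, tau = 0.1, n_constraint_dirs = 300,
                            csd_max_iter = 50, csd_lambda = 1,
                            n_streamlines = 10000, step_size = 0.5,
                            max_path_length = 500, curvature_limit = 180,
                            fod_amplitude_threshold = 0.1,
                            roi_radius = 1.5,
                            alpha = 0.05, strict_frac = 0.75,
                            relaxed_frac = 0.50, seed = 42) {
  cfg <- as.list(environment())
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Write / read a pipeline configuration (YAML)
#' @param config a [pipeline_config].
#' @param path YAML file.
#' @return `write_config` returns `path` invisibly; `read_config` the
#'   configuration.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw)
  cfg
}

# expand the presence spec into a logical participants x bundles matrix
resolve_presence <- function(presence, n_participants, bundle_names) {
  if (identical(presence, "all"))
    return(matrix(TRUE, n_participants, length(bundle_names),
                  dimnames = list(NULL, bundle_names)))
  m <- matrix(TRUE, n_participants, length(bundle_names),
              dimnames = list(NULL, bundle_names))
  for (nm in names(presence)) {
    if (!nm %in% bundle_names)
      stop("presence names unknown bundle '", nm, "'")
    v <- presence[[nm]]
    m[, nm] <- if (is.logical(v)) v
               else seq_len(n_participants) <= v
  }
  m
}

# seed ROIs: one sphere per true connection, centred on the centroid of the
# connection's seed endpoint region, clipped to that region
auto_seed_rois <- function(truth, targets, roi_radius) {
  grid <- grid_of(truth)
  lapply(seq_len(nrow(truth$truth_connections)), function(i) {
    nm <- truth$truth_connections$seed[i]
    lab <- targets$names[[nm]]
    vox <- which(targets$labels == lab, arr.ind = TRUE) - 1
    ctr <- colMeans(vox %*% t(truth$affine[1:3, 1:3])) +
      truth$affine[1:3, 4]
    make_spherical_roi(ctr, roi_radius, grid,
                       clip_mask = targets$labels == lab,
                       label = nm)
  })
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates the phantom, target labels and cohort, then per participant:
#' estimates the single-fibre response, fits the FOD field by CSD, tracks
#' every seed-ROI voxel, and aggregates the seed x target connectivity
#' matrix; finally applies the per-participant Poisson threshold and the
#' group-consistency criteria. Deterministic given the configuration's
#' master seed. When `out_dir` is given, writes `profile.tsv`,
#' `connectivity_p<i>.tsv`, the resolved `config.yaml` and a `log.txt`.
#'
#' @param config a [pipeline_config].
#' @param out_dir optional output directory (created if missing).
#' @return invisibly, a list with the group `profile` (annotated with a
#'   `kind` column: truth / self / spurious), per-participant `matrices` and
#'   `models`, the `truth`, `targets` and resolved `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  truth <- make_bundle_phantom(
    preset = config$preset, shape = config$shape,
    voxel_size = config$voxel_size, tube_radius = config$tube_radius,
    crossing_angle = config$crossing_angle, arc_radii = config$arc_radii)
  targets <- make_label_volume(truth)
  say("phantom: ", paste(names(truth$bundles), collapse = ", "),
      " (", sum(truth$brain_mask), " masked voxels)")

  gradients <- make_gradient_scheme(config$n_directions, config$b_value,
                                    seed = config$seed)
  model <- tissue_model(S0 = config$S0, snr = config$snr,
                        rng_seed = config$seed)
  presence <- resolve_presence(config$presence, config$n_participants,
                               names(truth$bundles))
  cohort <- make_cohort(truth, config$n_participants, presence, gradients,
                        model, seed = config$seed)
  rois <- auto_seed_rois(truth, targets, config$roi_radius)
  say("cohort: ", config$n_participants, " participants; seeds: ",
      paste(vapply(rois, `[[`, "", "label"), collapse = ", "))

  matrices <- vector("list", config$n_participants)
  models <- vector("list", config$n_participants)
  bins <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    dwi <- cohort$volumes[[p]]
    tp <- cohort$truths[[p]]
    resp <- participant_response(dwi, tp, config)
    fod <- fit_fod_field(dwi, resp, lmax = config$lmax, tau = config$tau,
                         n_constraint_dirs = config$n_constraint_dirs,
                         max_iter = config$csd_max_iter,
                         lambda = config$csd_lambda)
    tparams <- tracking_params(
      n_streamlines_per_voxel = config$n_streamlines,
      step_size = config$step_size,
      max_path_length = config$max_path_length,
      curvature_limit = config$curvature_limit,
      fod_amplitude_threshold = config$fod_amplitude_threshold,
      rng_seed = config$seed + 7919 * p)
    matrices[[p]] <- seed_connectivity(fod, rois, targets, tparams)
    # pool every seed x target value except each seed's own host region
    # (the analysed target scheme excludes the seed regions themselves)
    vals <- matrices[[p]]$values
    nonself <- outer(rownames(vals), colnames(vals), `!=`)
    models[[p]] <- poisson_model(vals[nonself], alpha = config$alpha)
    bins[[p]] <- apply_individual_threshold(matrices[[p]], models[[p]])
    say("participant ", p, ": lambda = ",
        signif(models[[p]]$lambda, 5), ", threshold = ",
        models[[p]]$threshold)
  }

  profile <- group_consistency(bins, config$strict_frac,
                               config$relaxed_frac)
  att <- attributes(profile)[c("n_participants", "strict_frac",
                               "relaxed_frac")]
  profile$kind <- connection_kind(profile, truth)
  attributes(profile)[names(att)] <- att
  say("profile: ", sum(profile$strict_pass), " strict, ",
      sum(profile$relaxed_pass), " relaxed of ", nrow(profile), " pairs")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_profile(profile, file.path(out_dir, "profile.tsv"))
    for (p in seq_along(matrices))
      write_connectivity(matrices[[p]],
                         file.path(out_dir,
                                   sprintf("connectivity_p%02d.tsv", p)))
    write_config(config, file.path(out_dir, "config.yaml"))
    writeLines(log_lines, file.path(out_dir, "log.txt"))
  }

  invisible(list(profile = profile, matrices = matrices, models = models,
                 truth = truth, targets = targets, config = config,
                 presence = presence))
}

# label each seed-target pair: the designed connection (truth), the seed's
# own host region (self), or a pair absent by design (spurious)
connection_kind <- function(profile, truth) {
  tc <- truth$truth_connections
  truth_key <- paste(tc$seed, tc$target)
  key <- paste(profile$seed, profile$target)
  kind <- rep("spurious", nrow(profile))
  kind[key %in% truth_key] <- "truth"
  kind[profile$seed == profile$target] <- "self"
  kind
}

# participant-level response function: ground-truth single-fibre voxels, or
# the analytic tensor response (also the fallback when no bundle is present)
participant_response <- function(dwi, truth_p, config) {
  if (identical(config$response, "analytic") ||
      length(truth_p$bundles) == 0)
    return(response_from_tensor(config$b_value, tissue_model(
      S0 = config$S0, snr = config$snr), lmax = config$lmax))
  tab <- phantom_population_table(truth_p)
  single <- tab[abs(tab$fraction - 1) < 1e-9, , drop = FALSE]
  if (nrow(single) == 0)
    return(response_from_tensor(config$b_value, tissue_model(
      S0 = config$S0, snr = config$snr), lmax = config$lmax))
  # subsample for speed; evenly spaced, deterministic
  take <- single[seq(1, nrow(single),
                     by = max(1, floor(nrow(single) / 200))), ,
                 drop = FALSE]
  mask <- array(FALSE, truth_p$shape)
  mask[take$lin] <- TRUE
  # estimate_response walks which(mask) in linear order; order axes the same
  ord <- order(take$lin)
  estimate_response(dwi, mask,
                    as.matrix(take[ord, c("ox", "oy", "oz")]),
                    lmax = config$lmax)
}
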