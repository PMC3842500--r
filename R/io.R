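## Readers and writers for the pipeline's standard formats: NIfTI volumes,
## FSL-dialect bval/bvec text, TCK streamline files and TSV tables.

# write a 3D/4D array as NIfTI with the given voxel-to-world affine
write_nifti_array <- function(arr, affine, path) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a DWI volume as NIfTI plus FSL-style bval/bvec files
#'
#' The bvec file holds three rows of whitespace-separated direction
#' components; the bval file one row of b-values. The brain mask is written
#' alongside as `<prefix>_mask.nii.gz`.
#'
#' @param dwi a `dwi_volume`.
#' @param prefix output path prefix (directories must exist).
#' @return invisibly, the paths written.
#' @export
write_dwi <- function(dwi, prefix) {
  nii <- paste0(prefix, ".nii.gz")
  write_nifti_array(dwi$signal, dwi$affine, nii)
  bval <- paste0(prefix, ".bval")
  bvec <- paste0(prefix, ".bvec")
  writeLines(paste(format(dwi$gradients$bvalues, trim = TRUE),
                   collapse = " "), bval)
  writeLines(apply(t(dwi$gradients$directions), 1, paste,
                   collapse = " "), bvec)
  msk <- paste0(prefix, "_mask.nii.gz")
  write_nifti_array(array(as.integer(dwi$brain_mask),
                          dim = dim(dwi$brain_mask)), dwi$affine, msk)
  invisible(c(nifti = nii, bval = bval, bvec = bvec, mask = msk))
}

#' Read a DWI volume from NIfTI + bval/bvec files
#'
#' Validates that the gradient table length matches the image's 4th
#' dimension; weighted directions with a norm off unity by more than 1e-6
#' are renormalised with a warning.
#'
#' @param nifti_path 4D NIfTI file.
#' @param bval_path,bvec_path FSL-style gradient text files.
#' @param mask_path optional mask NIfTI; defaults to voxels with positive
#'   mean b0 signal.
#' @return a `dwi_volume`.
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path, mask_path = NULL) {
  img <- RNifti::readNifti(nifti_path)
  sig <- as.array(img)
  if (length(dim(sig)) != 4) stop("expected a 4D NIfTI volume")
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4, 4))
  bvals <- scan(bval_path, quiet = TRUE)
  bvecs <- as.matrix(read.table(bvec_path))
  if (nrow(bvecs) != 3) stop("bvec file must have 3 rows")
  dirs <- t(bvecs)
  if (length(bvals) != dim(sig)[4] || nrow(dirs) != dim(sig)[4])
    stop("gradient table length (", length(bvals),
         ") does not match image volumes (", dim(sig)[4], ")")
  nrm <- sqrt(rowSums(dirs^2))
  fix <- bvals > 0 & abs(nrm - 1) > 1e-6
  if (any(fix & nrm == 0))
    stop("zero-length gradient direction at b > 0")
  if (any(fix)) {
    warning(sum(fix), " gradient direction(s) renormalised to unit length")
    dirs[fix, ] <- dirs[fix, ] / nrm[fix]
  }
  gt <- gradient_table(dirs, bvals)
  mask <- if (!is.null(mask_path)) {
    as.array(RNifti::readNifti(mask_path)) > 0
  } else {
    b0 <- array(rowMeans(matrix(sig, prod(dim(sig)[1:3]))[,
                 bvals == 0, drop = FALSE]), dim(sig)[1:3])
    b0 > 0
  }
  structure(list(signal = sig, gradients = gt, affine = affine,
                 brain_mask = mask),
            class = "dwi_volume")
}

#' Write a label volume as integer NIfTI plus a name table
#'
#' @param labels a `label_volume`.
#' @param prefix output path prefix.
#' @param affine voxel-to-world transform (default: identity, i.e. 1 mm
#'   isotropic voxels).
#' @return invisibly, the paths written.
#' @export
write_labels <- function(labels, prefix, affine = diag(4)) {
  nii <- paste0(prefix, ".nii.gz")
  write_nifti_array(labels$labels, affine, nii)
  tsv <- paste0(prefix, "_names.tsv")
  write.table(data.frame(label = unname(labels$names),
                         name = names(labels$names)),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(nifti = nii, names = tsv))
}

#' Read a label volume written by [write_labels]
#' @param prefix path prefix used at write time.
#' @return a `label_volume`.
#' @export
read_labels <- function(prefix) {
  lab <- as.array(RNifti::readNifti(paste0(prefix, ".nii.gz")))
  storage.mode(lab) <- "integer"
  tab <- read.table(paste0(prefix, "_names.tsv"), header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  nm <- tab$label
  names(nm) <- tab$name
  structure(list(labels = lab, names = nm), class = "label_volume")
}

#' Write phantom ground truth as NIfTI volumes
#'
#' Writes the per-voxel fibre orientations as a 4D (x, y, z, 3) NIfTI (the
#' first population where several overlap), the brain mask, and the endpoint
#' label volume with its name table.
#'
#' @param truth a `phantom_truth`.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_truth <- function(truth, prefix) {
  ori <- array(0, c(truth$shape, 3))
  nvox <- prod(truth$shape)
  tab <- phantom_population_table(truth)
  first <- tab[!duplicated(tab$lin), , drop = FALSE]
  for (j in 1:3)
    ori[first$lin + (j - 1) * nvox] <- first[[c("ox", "oy", "oz")[j]]]
  onii <- paste0(prefix, "_orientations.nii.gz")
  write_nifti_array(ori, truth$affine, onii)
  mnii <- paste0(prefix, "_mask.nii.gz")
  write_nifti_array(array(as.integer(truth$brain_mask),
                          dim = truth$shape), truth$affine, mnii)
  lab <- write_labels(make_label_volume(truth), paste0(prefix, "_labels"),
                      affine = truth$affine)
  invisible(c(orientations = onii, mask = mnii, lab))
}

#' Write an FOD field as NIfTI (4D coefficient volume + mask)
#'
#' @param fod a `fod_field`.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_fod <- function(fod, prefix) {
  arr <- array(0, c(fod$dim, ncol(fod$coefficients)))
  lin <- 1 + fod$voxels[, 1] + fod$dim[1] *
    (fod$voxels[, 2] + fod$dim[2] * fod$voxels[, 3])
  nvox <- prod(fod$dim)
  for (j in seq_len(ncol(fod$coefficients)))
    arr[lin + (j - 1) * nvox] <- fod$coefficients[, j]
  nii <- paste0(prefix, "_fod.nii.gz")
  msk <- paste0(prefix, "_fodmask.nii.gz")
  write_nifti_array(arr, fod$affine, nii)
  write_nifti_array(array(as.integer(fod$mask), dim = fod$dim),
                    fod$affine, msk)
  invisible(c(fod = nii, mask = msk))
}

#' Read an FOD field written by [write_fod]
#' @param prefix path prefix used at write time.
#' @return a `fod_field`.
#' @export
read_fod <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, "_fod.nii.gz"))
  arr <- as.array(img)
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4, 4))
  mask <- as.array(RNifti::readNifti(paste0(prefix, "_fodmask.nii.gz"))) > 0
  ncoef <- dim(arr)[4]
  lmax <- as.integer((sqrt(8 * ncoef + 1) - 3) / 2)
  shape <- dim(arr)[1:3]
  sel <- which(mask)
  nvox <- prod(shape)
  coefs <- matrix(arr, nvox)[sel, , drop = FALSE]
  vox <- cbind((sel - 1) %% shape[1],
               ((sel - 1) %/% shape[1]) %% shape[2],
               (sel - 1) %/% (shape[1] * shape[2]))
  structure(list(coefficients = coefs, voxels = vox, mask = mask,
                 lmax = lmax, affine = affine, dim = shape),
            class = "fod_field")
}

## ---- TCK streamlines -------------------------------------------------------

#' Write streamlines to a TCK (MRtrix track) file
#'
#' Coordinates are stored as little-endian float32 triplets in world mm, with
#' NaN triplets separating tracks and an Inf triplet terminating the file.
#' An empty list writes a valid zero-track file.
#'
#' @param streamlines list of `streamline` objects or point matrices.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_streamlines <- function(streamlines, path) {
  pts <- lapply(streamlines, function(s)
    if (inherits(s, "streamline")) s$points else as.matrix(s))
  n <- length(pts)
  hdr_fmt <- paste0("mrtrix tracks\ncount: ", n,
                    "\ndatatype: Float32LE\nfile: . %d\nEND\n")
  # the offset field's width feeds back into the offset; iterate to fixpoint
  off <- nchar(sprintf(hdr_fmt, 0))
  off <- nchar(sprintf(hdr_fmt, off))
  off <- nchar(sprintf(hdr_fmt, off))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf(hdr_fmt, off), con, eos = NULL)
  for (p in pts) {
    writeBin(as.numeric(t(p)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a TCK streamline file
#'
#' @param path TCK file.
#' @return list of point matrices (world mm, float32 precision).
#' @export
read_streamlines <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!identical(magic, "mrtrix tracks")) stop("not a TCK file")
  off <- NA
  repeat {
    ln <- readLines(con, n = 1)
    if (identical(ln, "END")) break
    kv <- strsplit(ln, ": *")[[1]]
    if (kv[1] == "file") off <- as.integer(strsplit(kv[2], " ")[[1]][2])
    if (kv[1] == "datatype" && kv[2] != "Float32LE")
      stop("unsupported TCK datatype: ", kv[2])
  }
  seek(con, off)
  raw <- readBin(con, "numeric", n = file.size(path), size = 4,
                 endian = "little")
  m <- matrix(raw, ncol = 3, byrow = TRUE)
  ends <- which(!is.finite(m[, 1]))
  out <- list()
  start <- 1
  for (e in ends) {
    if (is.infinite(m[e, 1])) break
    if (e > start) out[[length(out) + 1]] <- m[start:(e - 1), , drop = FALSE]
    else out[[length(out) + 1]] <- m[0, , drop = FALSE]
    start <- e + 1
  }
  out
}

## ---- profiles and matrices -------------------------------------------------

#' Write a group connectivity profile as TSV
#'
#' Columns: seed, target, participant_count, strict_pass, relaxed_pass (plus
#' any extra columns the profile carries) — the machine-readable analogue of
#' a published consistency table.
#'
#' @param profile a `group_profile`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a group profile TSV written by [write_profile]
#' @param path TSV file.
#' @return data.frame.
#' @export
read_profile <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a connectivity matrix as TSV (seeds in rows)
#' @param cm a `connectivity_matrix`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_connectivity <- function(cm, path) {
  df <- data.frame(seed = cm$seed_labels, cm$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a connectivity matrix written by [write_connectivity]
#' @param path TSV file.
#' @param n_initiated streamlines initiated per seed voxel.
#' @return a `connectivity_matrix`.
#' @export
read_connectivity <- function(path, n_initiated) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  connectivity_matrix(vals, df$seed, colnames(vals), n_initiated)
}
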