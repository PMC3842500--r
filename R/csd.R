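## Constrained spherical deconvolution: single-fibre response estimation,
## per-voxel FOD fitting with an iterative soft non-negativity penalty, and
## FOD peak extraction.

#' Single-fibre response function
#'
#' The axially symmetric diffusion-weighted signal profile assumed common to
#' all coherent single-fibre populations, stored as its zonal (m = 0)
#' spherical-harmonic coefficients for even orders 0..lmax, with the symmetry
#' axis along z.
#'
#' @param zonal_coefficients numeric vector of length `lmax/2 + 1`.
#' @param lmax even maximum order.
#' @return object of class `response_function`.
#' @export
response_function <- function(zonal_coefficients, lmax) {
  stopifnot(lmax %% 2 == 0,
            length(zonal_coefficients) == lmax / 2 + 1)
  if (zonal_coefficients[1] <= 0)
    stop("response l = 0 coefficient must be positive")
  structure(list(zonal_coefficients = as.numeric(zonal_coefficients),
                 lmax = as.integer(lmax)),
            class = "response_function")
}

#' @export
print.response_function <- function(x, ...) {
  cat("<response_function> lmax =", x$lmax, "; zonal coefficients:",
      signif(x$zonal_coefficients, 4), "\n")
  invisible(x)
}

#' Estimate the single-fibre response from known coherent voxels
#'
#' Normalises each selected voxel's diffusion-weighted signal by its mean
#' b = 0 signal, rotates the gradient frame so the voxel's fibre axis aligns
#' with z, averages across voxels, and projects the averaged profile onto the
#' zonal even-order harmonics by least squares.
#'
#' @param dwi a `dwi_volume`.
#' @param single_fibre_mask logical 3D array selecting voxels that contain a
#'   single coherent fibre population.
#' @param axis unit 3-vector giving the fibre axis, or a matrix with one row
#'   per selected voxel when the axis varies (e.g. along a curved bundle).
#' @param lmax even maximum order (default 8).
#' @return a [response_function] in b0-normalised signal units.
#' @export
estimate_response <- function(dwi, single_fibre_mask, axis, lmax = 8) {
  sel <- which(single_fibre_mask)
  if (length(sel) == 0) stop("no single-fibre voxels")
  axis <- matrix(axis, ncol = 3)
  if (nrow(axis) == 1) axis <- axis[rep(1, length(sel)), , drop = FALSE]
  stopifnot(nrow(axis) == length(sel))

  b <- dwi$gradients$bvalues
  dw <- b > 0
  nvox <- prod(dim(dwi$signal)[1:3])
  sig <- matrix(dwi$signal, nvox)[sel, , drop = FALSE]
  b0 <- rowMeans(sig[, !dw, drop = FALSE])
  if (any(b0 <= 0)) stop("non-positive b0 signal in single-fibre mask")
  sdw <- sig[, dw, drop = FALSE] / b0
  gdw <- dwi$gradients$directions[dw, , drop = FALSE]

  # rotate each voxel's gradient frame so its fibre axis maps onto z, then
  # accumulate the zonal normal equations
  zc <- sh_zonal_indices(lmax)
  XtX <- matrix(0, length(zc), length(zc))
  Xty <- numeric(length(zc))
  for (v in seq_along(sel)) {
    R <- rotation_between(axis[v, ], c(0, 0, 1))
    gz <- gdw %*% t(R)
    Bz <- sh_basis(gz, lmax)[, zc, drop = FALSE]
    XtX <- XtX + crossprod(Bz)
    Xty <- Xty + crossprod(Bz, sdw[v, ])
  }
  response_function(solve(XtX, Xty), lmax)
}

#' Analytic response of an axially symmetric diffusion tensor
#'
#' Projects `S(theta) = exp(-b (lambda_perp + (lambda_par - lambda_perp)
#' cos^2 theta))` onto the zonal even harmonics by Gauss-Legendre quadrature.
#' Units are b0-normalised signal (S0 = 1), matching [estimate_response].
#'
#' @param b_value diffusion weighting (s/mm^2).
#' @param model a [tissue_model] supplying the diffusivities.
#' @param lmax even maximum order.
#' @return a [response_function].
#' @export
response_from_tensor <- function(b_value, model, lmax = 8) {
  gq <- pracma::gaussLegendre(64, -1, 1)
  S <- exp(-b_value * (model$lambda_perp +
                         (model$lambda_parallel - model$lambda_perp) *
                           gq$x^2))
  zc <- vapply(seq(0, lmax, 2), function(l) {
    N <- sqrt((2 * l + 1) / (4 * pi))
    Pl <- vapply(gq$x, function(x) pracma::legendre(l, x)[1], 0)
    2 * pi * sum(gq$w * S * N * Pl)
  }, 0)
  response_function(zc, lmax)
}

# forward convolution matrix: signal at dirs = A %*% fod_coefficients.
# By the Funk-Hecke theorem a zonal kernel multiplies each order l by
# sqrt(4*pi/(2l+1)) * r_l.
csd_forward_matrix <- function(dirs, response, lmax) {
  rl <- response$zonal_coefficients[seq_len(lmax / 2 + 1)]
  fl <- sqrt(4 * pi / (2 * seq(0, lmax, 2) + 1)) * rl
  fcol <- fl[sh_degrees(lmax) / 2 + 1]
  sweep(sh_basis(dirs, lmax), 2, fcol, "*")
}

#' Fit the fibre orientation distribution by constrained spherical deconvolution
#'
#' Solves the spherical deconvolution `signal = FOD (*) response` in the SH
#' domain (per even order l the forward coefficient is `fod_l * r_l` up to
#' the Funk-Hecke normalisation), iteratively re-fitting with a soft penalty
#' that pushes FOD amplitudes below `tau * mean(initial FOD amplitude)` over
#' `n_constraint_dirs` sphere directions towards zero, until the active
#' constraint set stabilises or `max_iter` is reached.
#'
#' @param signal numeric vector (one voxel) or matrix (voxels x measurements)
#'   of signals matching the gradient table; when the table contains b = 0
#'   entries the weighted measurements are normalised by the per-voxel mean
#'   b0 signal.
#' @param gradients the [gradient_table] the signal was measured on.
#' @param response the single-fibre [response_function].
#' @param lmax even maximum FOD order (default 8).
#' @param tau amplitude threshold factor for the penalty set (default 0.1).
#' @param n_constraint_dirs sphere directions used to evaluate the constraint
#'   (default 300).
#' @param max_iter maximum constraint re-fits (default 50).
#' @param lambda penalty weight, scaled internally by the Frobenius-norm
#'   ratio of the data and constraint operators (default 0.01; see the
#'   methods vignette for how this trades non-negativity against angular
#'   resolution).
#' @return for a vector signal, a numeric vector of `sh_ncoef(lmax)` FOD
#'   coefficients (attributes `iterations`, `converged`); for a matrix, a
#'   matrix of coefficients with the same attributes vectorised.
#' @export
fit_csd <- function(signal, gradients, response, lmax = 8, tau = 0.1,
                    n_constraint_dirs = 300, max_iter = 50, lambda = 0.01) {
  single <- is.null(dim(signal))
  S <- if (single) matrix(signal, 1) else as.matrix(signal)
  b <- gradients$bvalues
  dw <- b > 0
  if (ncol(S) != length(b))
    stop("signal has ", ncol(S), " measurements for ", length(b),
         " gradient entries")
  if (any(!dw)) {
    b0 <- rowMeans(S[, !dw, drop = FALSE])
    S <- S[, dw, drop = FALSE] / b0
  }
  if (sum(dw) < sh_ncoef(lmax))
    stop("gradient count (", sum(dw), ") below coefficient count (",
         sh_ncoef(lmax), ") for lmax = ", lmax)
  rl <- response$zonal_coefficients
  need <- seq_len(lmax / 2 + 1)
  if (response$lmax < lmax || any(abs(rl[need]) < 1e-12)) {
    l_bad <- 2 * (which(abs(rl[need]) < 1e-12)[1] - 1)
    stop("response has no power at order ", l_bad, "; reduce lmax")
  }
  A <- csd_forward_matrix(gradients$directions[dw, , drop = FALSE],
                          response, lmax)
  Bc <- sh_basis(fibonacci_sphere(n_constraint_dirs), lmax)
  lam2 <- (lambda * norm(A, "F") / norm(Bc, "F"))^2
  fit <- csd_fit_batch(S, A, Bc, tau, max_iter, lam2)
  out <- fit$coefficients
  if (single) {
    out <- as.vector(out)
    attr(out, "iterations") <- fit$iterations[1]
    attr(out, "converged") <- fit$converged[1]
  } else {
    attr(out, "iterations") <- fit$iterations
    attr(out, "converged") <- fit$converged
  }
  out
}

#' Fit the FOD field over a masked volume
#'
#' Applies [fit_csd] to every masked voxel of a DWI volume. Voxels whose fit
#' fails (non-finite coefficients or non-positive b0) are dropped from the
#' field mask and reported via a message.
#'
#' @param dwi a `dwi_volume`.
#' @param response the single-fibre [response_function].
#' @param mask logical 3D array of voxels to fit (default: the brain mask).
#' @param ... parameters passed to [fit_csd].
#' @param lmax even maximum FOD order.
#' @return object of class `fod_field`: per-voxel SH `coefficients`
#'   (voxels x coefficients), the 0-based `voxels` index matrix, the logical
#'   `mask`, `lmax`, `affine` and grid `dim`.
#' @export
fit_fod_field <- function(dwi, response, lmax = 8, mask = dwi$brain_mask,
                          ...) {
  if (!any(mask)) stop("mask is empty")
  shape <- dim(dwi$signal)[1:3]
  nvox <- prod(shape)
  sel <- which(mask)
  sig <- matrix(dwi$signal, nvox)[sel, , drop = FALSE]
  b0ok <- rowMeans(sig[, dwi$gradients$bvalues == 0, drop = FALSE]) > 0
  coefs <- matrix(NA_real_, length(sel), sh_ncoef(lmax))
  if (any(b0ok))
    coefs[b0ok, ] <- fit_csd(sig[b0ok, , drop = FALSE], dwi$gradients,
                             response, lmax = lmax, ...)
  ok <- b0ok & apply(is.finite(coefs), 1, all)
  if (any(!ok))
    message(sum(!ok), " voxel(s) failed to fit and were masked out")
  sel <- sel[ok]
  mask2 <- array(FALSE, shape)
  mask2[sel] <- TRUE
  vox <- cbind((sel - 1) %% shape[1],
               ((sel - 1) %/% shape[1]) %% shape[2],
               (sel - 1) %/% (shape[1] * shape[2]))
  structure(list(coefficients = coefs[ok, , drop = FALSE],
                 voxels = vox, mask = mask2, lmax = as.integer(lmax),
                 affine = dwi$affine, dim = shape),
            class = "fod_field")
}

#' @export
print.fod_field <- function(x, ...) {
  cat("<fod_field> lmax =", x$lmax, ";", nrow(x$coefficients),
      "fitted voxels on a", paste(x$dim, collapse = "x"), "grid\n")
  invisible(x)
}

# cached sphere grid + neighbour structure for peak finding
.peak_cache <- new.env(parent = emptyenv())
peak_grid <- function(lmax, n = 724) {
  key <- paste0(lmax, "_", n)
  if (!is.null(.peak_cache[[key]])) return(.peak_cache[[key]])
  dirs <- fibonacci_sphere(n)
  B <- sh_basis(dirs, lmax)
  G <- dirs %*% t(dirs)
  nb <- G > cos(12 * pi / 180)
  diag(nb) <- FALSE
  out <- list(dirs = dirs, B = B, nb = nb)
  .peak_cache[[key]] <- out
  out
}

# canonical sign for an antipodally symmetric peak direction
canonical_dir <- function(d) {
  if (d[3] < 0 || (abs(d[3]) < 1e-9 && (d[2] < 0 ||
      (abs(d[2]) < 1e-9 && d[1] < 0)))) -d else d
}

#' Smallest resolvable crossing angle of the CSD implementation
#'
#' Sweeps two-fibre crossings over a grid of angles (descending): for each
#' angle, synthesises the noise-free equal-weight two-tensor signal, fits the
#' FOD by [fit_csd] with the matched analytic response, extracts peaks and
#' checks that exactly two peaks are found, each within `tol_deg` of a true
#' orientation. Returns the smallest angle that still resolves.
#'
#' @param gradients a [gradient_table] (a dense scheme for resolution tests).
#' @param model a [tissue_model] supplying the tensor diffusivities.
#' @param angles crossing angles (degrees) to test.
#' @param lmax even maximum FOD order.
#' @param tol_deg peak-to-truth tolerance in degrees.
#' @param ... further arguments to [fit_csd].
#' @return list: `resolved` (logical per angle), `min_angle` (smallest
#'   resolved angle, `NA` if none), `angles`.
#' @export
angular_resolution_sweep <- function(gradients, model = tissue_model(),
                                     angles = seq(90, 20, by = -5),
                                     lmax = 8, tol_deg = 10, ...) {
  b <- max(gradients$bvalues)
  resp <- response_from_tensor(b, model, lmax = lmax)
  resolved <- vapply(angles, function(a) {
    h <- a / 2 * pi / 180
    u1 <- c(sin(h), 0, cos(h))
    u2 <- c(-sin(h), 0, cos(h))
    s <- multi_tensor_signal(gradients, rbind(u1, u2), c(0.5, 0.5),
                             model) / model$S0
    x <- fit_csd(s, gradients, resp, lmax = lmax, ...)
    pk <- find_fod_peaks(x)
    nrow(pk$directions) == 2 &&
      all(vapply(seq_len(2), function(i)
        min(angle_deg(pk$directions[i, ], u1),
            angle_deg(pk$directions[i, ], u2)) <= tol_deg, TRUE))
  }, TRUE)
  min_angle <- if (any(resolved)) {
    # smallest angle below which resolution is never regained
    min(angles[resolved])
  } else NA_real_
  list(angles = angles, resolved = resolved, min_angle = min_angle)
}

#' Extract FOD peaks
#'
#' Locates local maxima of the FOD amplitude over a 724-point sphere grid,
#' refines each candidate by derivative-free ascent in the local tangent
#' plane, merges antipodal duplicates, discards peaks below
#' `rel_threshold * max amplitude` or within `min_separation_deg` of a
#' stronger peak, and returns the survivors sorted by amplitude (descending).
#'
#' @param coefficients even-order SH coefficient vector.
#' @param min_separation_deg minimum angular separation between peaks.
#' @param rel_threshold relative amplitude cut-off.
#' @return list with `directions` (n x 3, canonical hemisphere) and
#'   `amplitudes`; both empty when the FOD is identically zero.
#' @export
find_fod_peaks <- function(coefficients, min_separation_deg = 15,
                           rel_threshold = 0.25) {
  ncoef <- length(coefficients)
  lmax <- (sqrt(8 * ncoef + 1) - 3) / 2
  if (abs(lmax - round(lmax)) > 1e-9)
    stop("coefficient length does not match an even-order basis")
  lmax <- as.integer(round(lmax))
  empty <- list(directions = matrix(0, 0, 3), amplitudes = numeric(0))
  if (all(coefficients == 0)) return(empty)
  pg <- peak_grid(lmax)
  amp <- as.vector(pg$B %*% coefficients)
  cand <- which(vapply(seq_along(amp), function(i)
    amp[i] > 0 && all(amp[i] >= amp[pg$nb[i, ]]), TRUE))
  if (length(cand) == 0) return(empty)

  refine <- function(d0) {
    e1 <- if (abs(d0[3]) < 0.9) c(-d0[2], d0[1], 0) else c(1, 0, 0)
    e1 <- e1 - sum(e1 * d0) * d0
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(d0[2] * e1[3] - d0[3] * e1[2],
            d0[3] * e1[1] - d0[1] * e1[3],
            d0[1] * e1[2] - d0[2] * e1[1])
    f <- function(t) {
      d <- d0 + t[1] * e1 + t[2] * e2
      d <- d / sqrt(sum(d^2))
      -sum(sh_basis(matrix(d, 1), lmax) * coefficients)
    }
    o <- optim(c(0, 0), f, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 200))
    d <- d0 + o$par[1] * e1 + o$par[2] * e2
    list(d = canonical_dir(d / sqrt(sum(d^2))), a = -o$value)
  }
  pk <- lapply(cand, function(i) refine(pg$dirs[i, ]))
  ds <- do.call(rbind, lapply(pk, `[[`, "d"))
  as_ <- vapply(pk, `[[`, 0, "a")
  o <- order(-as_)
  ds <- ds[o, , drop = FALSE]
  as_ <- as_[o]
  cmin <- cos(min_separation_deg * pi / 180)
  keep <- integer(0)
  for (i in seq_along(as_)) {
    if (!length(keep) ||
        all(abs(ds[keep, , drop = FALSE] %*% ds[i, ]) < cmin))
      keep <- c(keep, i)
  }
  ds <- ds[keep, , drop = FALSE]
  as_ <- as_[keep]
  ok <- as_ >= rel_threshold * as_[1] & as_ > 0
  list(directions = ds[ok, , drop = FALSE], amplitudes = as_[ok])
}
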