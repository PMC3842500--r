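## Sphere point sets, gradient schemes and the real even-order spherical
## harmonic basis shared by the CSD and tracking stages.

#' Deterministic near-uniform sphere point set (spherical Fibonacci lattice)
#'
#' @param n number of points.
#' @param hemisphere if `TRUE`, fold all points into the z >= 0 hemisphere.
#' @return an `n` x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n, hemisphere = FALSE) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  th <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(1 - z^2, 0))
  pts <- cbind(r * cos(th), r * sin(th), z)
  if (hemisphere) pts <- pts * ifelse(pts[, 3] < 0, -1, 1)
  pts
}

#' Gradient table for a diffusion-weighted acquisition
#'
#' Bundles unit gradient directions with their b-values and validates the
#' acquisition-geometry invariants: weighted directions are unit vectors, at
#' least one b = 0 entry is present, and the two fields have equal length.
#'
#' @param directions n x 3 matrix; rows for b = 0 entries may be zero vectors.
#' @param bvalues numeric vector of b-values (s/mm^2).
#' @return an object of class `gradient_table`.
#' @export
gradient_table <- function(directions, bvalues) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3)
    stop("directions must be an n x 3 matrix")
  if (nrow(directions) != length(bvalues))
    stop("directions and bvalues have unequal length (",
         nrow(directions), " vs ", length(bvalues), ")")
  if (!any(bvalues == 0))
    stop("gradient table must contain at least one b = 0 entry")
  nrm <- sqrt(rowSums(directions^2))
  bad <- bvalues > 0 & abs(nrm - 1) > 1e-6
  if (any(bad))
    stop("non-unit gradient direction at b > 0 (row ",
         which(bad)[1], ", norm ", signif(nrm[which(bad)[1]], 6), ")")
  structure(list(directions = directions, bvalues = as.numeric(bvalues)),
            class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat("<gradient_table> ", length(x$bvalues), " entries: ",
      sum(x$bvalues > 0), " weighted (b = ",
      paste(unique(x$bvalues[x$bvalues > 0]), collapse = ", "),
      "), ", sum(x$bvalues == 0), " b0\n", sep = "")
  invisible(x)
}

#' Generate a near-uniform gradient sampling scheme
#'
#' Places `n_directions` unit vectors approximately uniformly over the sphere
#' (antipodally symmetric coverage) by electrostatic repulsion from a random
#' seeded start, then prepends a single b = 0 entry. The repulsion minimises
#' the Coulomb energy of each point and its antipode over a fixed iteration
#' budget, so the result is deterministic given `seed`.
#'
#' @param n_directions number of weighted directions (>= 6, the minimum for an
#'   even-order spherical-harmonic fit).
#' @param b_value diffusion weighting (s/mm^2) shared by all directions.
#' @param seed integer RNG seed for the initial configuration.
#' @param n_iter repulsion iterations (default 500).
#' @return a [gradient_table] with `n_directions + 1` entries.
#' @export
make_gradient_scheme <- function(n_directions, b_value, seed, n_iter = 500) {
  if (n_directions < 6)
    stop("insufficient directions for even-order SH fitting")
  X <- with_rng_seed(seed, {
    X0 <- matrix(rnorm(3 * n_directions), n_directions, 3)
    X0 / sqrt(rowSums(X0^2))
  })
  eta <- 0.1 / n_directions
  for (it in seq_len(n_iter)) {
    G <- X %*% t(X)
    G[G > 1] <- 1
    G[G < -1] <- -1
    wm <- 2 - 2 * G
    wp <- 2 + 2 * G
    diag(wm) <- Inf
    diag(wp) <- Inf
    wm <- wm^(-1.5)
    wp <- wp^(-1.5)
    Fr <- X * (rowSums(wm) + rowSums(wp)) - wm %*% X + wp %*% X
    Fr <- Fr - X * rowSums(Fr * X)  # tangential component
    X <- X + eta * Fr
    X <- X / sqrt(rowSums(X^2))
  }
  gradient_table(rbind(c(0, 0, 0), X), c(0, rep(b_value, n_directions)))
}

## ---- real even-order spherical harmonics ----------------------------------

#' Number of even-order SH coefficients up to lmax
#' @param lmax even maximum harmonic order.
#' @return integer coefficient count.
#' @export
sh_ncoef <- function(lmax) (lmax + 1) * (lmax + 2) / 2

# per-coefficient degree l for the even-order basis
sh_degrees <- function(lmax) {
  unlist(lapply(seq(0, lmax, 2), function(l) rep(l, 2 * l + 1)))
}

# column indices of the zonal (m = 0) coefficients
sh_zonal_indices <- function(lmax) {
  j <- 0
  out <- integer(0)
  for (l in seq(0, lmax, 2)) {
    out <- c(out, j + l + 1)
    j <- j + 2 * l + 1
  }
  out
}

#' Real even-order spherical harmonic basis matrix
#'
#' Evaluates the real, orthonormal, antipodally symmetric SH basis (even
#' orders only; within each order l the columns run m = -l..l, with sine
#' harmonics for m < 0, the zonal harmonic at m = 0 and cosine harmonics for
#' m > 0) at the given unit directions. Normalisation is orthonormal over the
#' sphere, so the basis Gram matrix under uniform quadrature is the identity.
#'
#' @param dirs n x 3 matrix of unit vectors.
#' @param lmax even maximum order.
#' @return an n x `sh_ncoef(lmax)` matrix.
#' @export
sh_basis <- function(dirs, lmax) {
  dirs <- matrix(dirs, ncol = 3)
  ct <- pmin(pmax(dirs[, 3], -1), 1)
  phi <- atan2(dirs[, 2], dirs[, 1])
  B <- matrix(0, nrow(dirs), sh_ncoef(lmax))
  j <- 0
  for (l in seq(0, lmax, 2)) {
    P <- pracma::legendre(l, ct)
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    for (m in -l:l) {
      j <- j + 1
      am <- abs(m)
      N <- sqrt((2 * l + 1) / (4 * pi) *
                  factorial(l - am) / factorial(l + am))
      B[, j] <- if (m < 0) {
        sqrt(2) * N * P[am + 1, ] * sin(am * phi)
      } else if (m == 0) {
        N * P[1, ]
      } else {
        sqrt(2) * N * P[am + 1, ] * cos(am * phi)
      }
    }
  }
  B
}

# rotation matrix mapping unit vector `from` onto unit vector `to` (Rodrigues)
rotation_between <- function(from, to) {
  from <- from / sqrt(sum(from^2))
  to <- to / sqrt(sum(to^2))
  v <- c(from[2] * to[3] - from[3] * to[2],
         from[3] * to[1] - from[1] * to[3],
         from[1] * to[2] - from[2] * to[1])
  c2 <- sum(from * to)
  if (c2 < -1 + 1e-12) {
    # antiparallel: rotate 180 degrees about any orthogonal axis
    ax <- if (abs(from[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- ax - sum(ax * from) * from
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c2)
}

# angle in degrees between unit vectors, optionally ignoring sign
angle_deg <- function(a, b, antipodal = TRUE) {
  d <- sum(a * b)
  if (antipodal) d <- abs(d)
  acos(pmin(pmax(d, -1), 1)) * 180 / pi
}
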