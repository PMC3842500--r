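## Two-level group inference: per-participant Poisson thresholding of the
## pooled connectivity values at p = .05, then group consistency under
## strict (>75% of participants) and relaxed (>50%) criteria.

#' Maximum-likelihood Poisson rate of pooled connectivity values
#'
#' The MLE of a Poisson rate is the sample mean. Zeros are pooled by default
#' (every seed-target pair contributes); `include_zeros = FALSE` is offered
#' for sensitivity analysis of the resulting zero-inflation.
#'
#' @param values non-negative integer connectivity values.
#' @param include_zeros pool zero values (default TRUE).
#' @return the fitted rate (scalar).
#' @export
fit_poisson_lambda <- function(values, include_zeros = TRUE) {
  if (length(values) == 0) stop("no values to fit")
  if (any(values < 0)) stop("connectivity values must be non-negative")
  if (!include_zeros) values <- values[values > 0]
  if (length(values) == 0) return(0)
  mean(values)
}

#' Poisson threshold at significance level alpha
#'
#' Returns the smallest integer `t` such that `P(X > t) < alpha` for
#' `X ~ Poisson(lambda)`. Connections with values strictly greater than `t`
#' are deemed present downstream.
#'
#' @param lambda Poisson rate (>= 0).
#' @param alpha tail probability (default 0.05).
#' @return non-negative integer threshold.
#' @export
poisson_threshold <- function(lambda, alpha = 0.05) {
  stopifnot(lambda >= 0, alpha > 0, alpha < 1)
  if (lambda == 0) return(0L)
  t <- qpois(1 - alpha, lambda)
  # need strict P(X > t) < alpha, i.e. ppois(t) > 1 - alpha
  while (ppois(t, lambda) <= 1 - alpha) t <- t + 1L
  as.integer(t)
}

#' Per-participant Poisson model of the connectivity-value distribution
#'
#' Fits the rate on the participant's own pooled seed x target values and
#' derives the individual threshold at level `alpha`.
#'
#' @param values pooled connectivity values (or a `connectivity_matrix`).
#' @param alpha significance level (default 0.05).
#' @param include_zeros see [fit_poisson_lambda].
#' @return object of class `poisson_model` with `lambda`, `alpha`,
#'   `threshold`.
#' @export
poisson_model <- function(values, alpha = 0.05, include_zeros = TRUE) {
  if (inherits(values, "connectivity_matrix")) values <- values$values
  lambda <- fit_poisson_lambda(as.vector(values), include_zeros)
  structure(list(lambda = lambda, alpha = alpha,
                 threshold = poisson_threshold(lambda, alpha)),
            class = "poisson_model")
}

#' @export
print.poisson_model <- function(x, ...) {
  cat("<poisson_model> lambda =", signif(x$lambda, 5), ", alpha =", x$alpha,
      "-> threshold", x$threshold, "\n")
  invisible(x)
}

#' Apply the individual threshold to a connectivity matrix
#'
#' An entry passes iff its value is strictly greater than the model's
#' threshold ("above which a connection is deemed to exist").
#'
#' @param matrix a `connectivity_matrix` (or plain numeric matrix).
#' @param model a [poisson_model].
#' @return logical matrix of the same shape.
#' @export
apply_individual_threshold <- function(matrix, model) {
  v <- if (inherits(matrix, "connectivity_matrix")) matrix$values else matrix
  v > model$threshold
}

# smallest integer count strictly exceeding frac * n
consistency_cutoff <- function(frac, n) floor(frac * n) + 1L

#' Group consistency of individually thresholded connections
#'
#' Counts, per seed-target pair, the participants whose individual threshold
#' the connection passed, and flags pairs meeting the strict (count strictly
#' over `strict_frac` of participants) and relaxed (over `relaxed_frac`)
#' criteria. With 13 participants the defaults give the printed cut-offs of
#' at least 10/13 (strict) and 7/13 (relaxed).
#'
#' @param binary_matrices list of logical matrices, one per participant, all
#'   the same shape.
#' @param strict_frac strict consistency fraction (default 0.75).
#' @param relaxed_frac relaxed consistency fraction (default 0.50).
#' @return object of class `group_profile`: a data.frame with one row per
#'   seed-target pair (`seed`, `target`, `participant_count`, `strict_pass`,
#'   `relaxed_pass`) and attributes `n_participants`, `strict_frac`,
#'   `relaxed_frac`.
#' @export
group_consistency <- function(binary_matrices, strict_frac = 0.75,
                              relaxed_frac = 0.50) {
  n <- length(binary_matrices)
  if (n < 1) stop("need at least one participant")
  dims <- lapply(binary_matrices, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("participant matrices have mismatching shapes")
  counts <- Reduce(`+`, lapply(binary_matrices, function(m) m * 1L))
  sc <- consistency_cutoff(strict_frac, n)
  rc <- consistency_cutoff(relaxed_frac, n)
  dn <- dimnames(binary_matrices[[1]])
  if (is.null(dn))
    dn <- list(paste0("seed", seq_len(nrow(counts))),
               paste0("target", seq_len(ncol(counts))))
  out <- data.frame(
    seed = rep(dn[[1]], times = ncol(counts)),
    target = rep(dn[[2]], each = nrow(counts)),
    participant_count = as.vector(counts),
    stringsAsFactors = FALSE)
  out$strict_pass <- out$participant_count >= sc
  out$relaxed_pass <- out$participant_count >= rc
  structure(out, n_participants = n, strict_frac = strict_frac,
            relaxed_frac = relaxed_frac,
            class = c("group_profile", "data.frame"))
}

#' @export
print.group_profile <- function(x, ...) {
  cat("<group_profile> ", attr(x, "n_participants"), " participants; ",
      sum(x$strict_pass), " strict-pass and ", sum(x$relaxed_pass),
      " relaxed-pass connection(s) of ", nrow(x), "\n", sep = "")
  NextMethod()
}
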