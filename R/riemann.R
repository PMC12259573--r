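#' Ledoit-Wolf shrinkage covariance of one window
#'
#' Sample covariance shrunk toward the scaled identity
#' `(tr(S)/p) I` with the analytic Ledoit-Wolf intensity, guaranteeing a
#' symmetric positive-definite estimate even when there are fewer samples
#' than channels.
#'
#' @param window channels x samples numeric matrix.
#' @return list-free SPD matrix with attribute `shrinkage` (the intensity
#'   alpha in `[0, 1]`).
#' @export
lw_covariance <- function(window) {
  stopifnot(ncol(window) >= 2)
  p <- nrow(window)
  n <- ncol(window)
  x <- window - rowMeans(window)
  if (all(abs(x) < 1e-300)) stop("constant (zero-variance) window")
  S <- tcrossprod(x) / n
  mu <- sum(diag(S)) / p
  delta2 <- sum((S - diag(mu, p))^2) / p
  # E || x x' - S ||_F^2 / (n p), computed via column norms
  cn2 <- colSums(x^2)
  beta2 <- (sum(cn2^2) / n - sum(S^2)) / (n * p)
  alpha <- if (delta2 <= 0) 1 else min(1, max(0, beta2 / delta2))
  out <- (1 - alpha) * S + alpha * diag(mu, p)
  attr(out, "shrinkage") <- alpha
  out
}

# Stack of LW covariances for a window set (channels x channels x windows)
lw_covariance_stack <- function(x) {
  n <- dim(x)[3]
  out <- array(0, dim = c(dim(x)[1], dim(x)[1], n))
  for (i in seq_len(n)) out[, , i] <- lw_covariance(x[, , i])
  out
}

check_spd <- function(A, tol = 1e-10) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) stop("not a square matrix")
  if (max(abs(A - t(A))) > tol * max(1, max(abs(A)))) stop("matrix not symmetric")
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("matrix not positive definite")
  invisible(TRUE)
}

#' Affine-invariant Riemannian (AIRM) distance between SPD matrices
#'
#' `sqrt(sum(log(lambda_i)^2))` over the generalized eigenvalues
#' `lambda_i` of `(A, B)`; symmetric, zero iff `A == B`, and invariant
#' under congruence `X -> W X W'`.
#'
#' @param A,B SPD matrices of equal size.
#' @return non-negative distance.
#' @export
airm_distance <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop("size mismatch")
  check_spd(A)
  check_spd(B)
  cpp_airm_distance(A, B)
}

#' Karcher (geometric) mean of SPD matrices under the AIRM
#'
#' Fixed-point/gradient-descent iteration from the arithmetic mean with
#' unit step: at the solution the mean of the matrix logarithms of the
#' mean-whitened inputs vanishes.
#'
#' @param mats list of SPD matrices (or a channels x channels x n array).
#' @param tol convergence tolerance on the Frobenius norm of the gradient.
#' @param max_iter maximum iterations (warns if reached).
#' @param le_init warm-start from the log-Euclidean mean instead of the
#'   arithmetic mean (same fixed point, typically fewer iterations when
#'   the inputs are widely spread).
#' @return the SPD geometric mean, with attributes `iterations` and
#'   `grad_norm`.
#' @export
geometric_mean <- function(mats, tol = 1e-8, max_iter = 50, le_init = FALSE) {
  cube <- as_spd_cube(mats)
  if (dim(cube)[3] == 0) stop("empty list of matrices")
  res <- cpp_karcher_mean(cube, tol, max_iter, le_init)
  if (res$grad_norm >= tol && dim(cube)[3] > 1) {
    warning(sprintf("Karcher mean not converged (grad %.2e after %d iters)",
                    res$grad_norm, res$iterations))
  }
  out <- res$mean
  attr(out, "iterations") <- res$iterations
  attr(out, "grad_norm") <- res$grad_norm
  out
}

as_spd_cube <- function(mats) {
  if (is.array(mats) && length(dim(mats)) == 3) return(mats)
  stopifnot(is.list(mats), length(mats) >= 1)
  d <- nrow(mats[[1]])
  cube <- array(0, dim = c(d, d, length(mats)))
  for (i in seq_along(mats)) cube[, , i] <- mats[[i]]
  cube
}

#' Minimum-distance-to-mean (MDM) classifier on SPD matrices
#'
#' Fits one geometric mean per class; prediction assigns each covariance
#' matrix to the class with the nearest mean under the AIRM. Distance ties
#' break toward the class whose label sorts first.
#'
#' @param covs channels x channels x n array (or list) of SPD matrices.
#' @param labels class labels, length n.
#' @param tol,max_iter forwarded to [geometric_mean()] for the class means.
#' @return an `ncv_mdm` model.
#' @export
mdm_fit <- function(covs, labels, tol = 1e-8, max_iter = 50) {
  cube <- as_spd_cube(covs)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (any(table(factor(labels, classes)) == 0)) stop("a class is absent from training")
  means <- lapply(classes, function(cl) {
    geometric_mean(cube[, , labels == cl, drop = FALSE], tol = tol,
                   max_iter = max_iter)
  })
  structure(list(classes = classes, means = means), class = "ncv_mdm")
}

#' @rdname mdm_fit
#' @param model an `ncv_mdm` model.
#' @export
mdm_predict <- function(model, covs) {
  cube <- as_spd_cube(covs)
  means <- array(0, dim = c(dim(cube)[1], dim(cube)[1], length(model$means)))
  for (j in seq_along(model$means)) means[, , j] <- model$means[[j]]
  D <- cpp_dist_to_means(cube, means)
  # max.col on negated distances with ties.method = "first": ties go to the
  # earlier (alphabetically first) class
  model$classes[max.col(-D, ties.method = "first")]
}

#' Backward electrode elimination on class covariance means
#'
#' Starting from the full channel set, repeatedly removes the channel
#' whose deletion (of its row/column in both class geometric means)
#' maximizes the AIRM distance between the two pruned class means, until
#' `k` channels remain. The class means are estimated once on the full
#' channel set; candidate removals are scored on submatrices.
#'
#' @param covs SPD array/list of per-window covariances (training data).
#' @param labels two-class labels.
#' @param k number of electrodes to keep (< number of channels).
#' @param tol,max_iter forwarded to [geometric_mean()]; the default
#'   tolerance is loose because the discrete channel choice is insensitive
#'   to sub-permille perturbations of the class means.
#' @return integer vector of `k` retained channel indices (ascending).
#' @export
select_electrodes <- function(covs, labels, k = 8, tol = 1e-3,
                              max_iter = 50) {
  cube <- as_spd_cube(covs)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) stop("electrode selection requires exactly two classes")
  if (k >= dim(cube)[1]) stop("k must be smaller than the number of channels")
  A <- geometric_mean(cube[, , labels == classes[1], drop = FALSE], tol = tol,
                      max_iter = max_iter)
  B <- geometric_mean(cube[, , labels == classes[2], drop = FALSE], tol = tol,
                      max_iter = max_iter)
  sort(as.integer(cpp_select_channels(A, B, as.integer(k))))
}

#' Block-diagonal assembly of per-band SPD matrices
#'
#' Represents a set of per-frequency-band covariance blocks; under the
#' AIRM the distance of the assembled block-diagonal matrices decomposes
#' as the square root of the sum of squared per-block distances, which
#' [block_airm_distance()] exploits.
#'
#' @param per_band_covs named list of SPD matrices.
#' @return an `ncv_block_spd` object.
#' @export
assemble_block_spd <- function(per_band_covs) {
  stopifnot(length(per_band_covs) >= 1)
  for (b in per_band_covs) check_spd(b)
  structure(list(blocks = per_band_covs,
                 bands = names(per_band_covs) %||%
                   as.character(seq_along(per_band_covs))),
            class = "ncv_block_spd")
}

#' @rdname assemble_block_spd
#' @param x an `ncv_block_spd`.
#' @export
materialize_block_spd <- function(x) {
  sizes <- vapply(x$blocks, nrow, 1L)
  n <- sum(sizes)
  out <- matrix(0, n, n)
  at <- 0L
  for (b in x$blocks) {
    idx <- at + seq_len(nrow(b))
    out[idx, idx] <- b
    at <- at + nrow(b)
  }
  out
}

#' @rdname assemble_block_spd
#' @param A,B `ncv_block_spd` objects with matching block structure.
#' @export
block_airm_distance <- function(A, B) {
  stopifnot(length(A$blocks) == length(B$blocks))
  sqrt(sum(vapply(seq_along(A$blocks), function(i) {
    cpp_airm_distance(A$blocks[[i]], B$blocks[[i]])^2
  }, numeric(1))))
}
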