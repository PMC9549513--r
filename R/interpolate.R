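# The interpolation core: closed-form solution of the semi-supervised
# problem
#   f* = argmin_f ||M_l (f - f_s)||^2 + alpha ||M_u f||^2 + beta f' L f
# i.e. the SPD linear system (M_l + alpha M_u + beta L) f* = f_s,
# plus the equivalent spectral graph-filter formulation and a Gaussian
# process regression baseline.

#' Solve the regularised interpolation system
#'
#' Computes the per-vertex interpolant `f*` satisfying
#' `(M_l + alpha*M_u + beta*L) f* = f_s`, where `M_l`/`M_u` are diagonal
#' 0/1 masks of labelled/unlabelled vertices, `f_s` is the observed signal
#' (zero off the labelled set) and `L` the graph Laplacian. The system is
#' symmetric positive definite for any `alpha > 0` and is solved by sparse
#' Cholesky factorisation rather than explicit inversion.
#'
#' @param graph a weighted [surface_graph()].
#' @param values observed LAT values (ms) at the labelled vertices.
#' @param labeled integer vector of labelled vertex indices (1-based), or a
#'   logical mask of length `graph$n`.
#' @param alpha Tikhonov coefficient, > 0 (default 1e-5). Keeps the system
#'   invertible and shrinks unconstrained components towards 0.
#' @param beta Dirichlet (smoothness) coefficient, >= 0 (default 1e-2).
#' @return Numeric vector of length `graph$n`: the interpolated LAT map.
#' @examples
#' g <- surface_graph(2, rbind(c(1, 2)), weights = 1)
#' magic_lat_solve(g, 10, labeled = 1)   # approx c(10.000, 9.990)
#' @export
magic_lat_solve <- function(graph, values, labeled, alpha = 1e-5,
                            beta = 1e-2) {
  if (is.null(graph$laplacian)) stop("graph weights are unset")
  if (!(alpha > 0)) stop("alpha must be > 0")
  if (beta < 0) stop("beta must be >= 0")
  n <- graph$n
  if (is.logical(labeled)) {
    if (length(labeled) != n) stop("logical mask must have length graph$n")
    labeled <- which(labeled)
  }
  labeled <- as.integer(labeled)
  if (!length(labeled)) stop("at least one labelled vertex is required")
  if (length(values) != length(labeled)) {
    stop("values must have one entry per labelled vertex")
  }
  fs <- numeric(n)
  fs[labeled] <- values
  mask <- rep(alpha, n)
  mask[labeled] <- 1
  A <- Matrix::Diagonal(n, x = mask) + beta * graph$laplacian
  A <- Matrix::forceSymmetric(A)
  f <- as.numeric(Matrix::solve(A, fs))
  resid <- max(abs(as.numeric(A %*% f) - fs))
  scale <- max(abs(fs))
  if (scale > 0 && resid > 1e-8 * scale) {
    stop(sprintf("solver failure: residual %.3g exceeds tolerance (malformed Laplacian?)",
                 resid))
  }
  f
}

#' Eigendecomposition of the graph Laplacian
#'
#' Dense symmetric eigendecomposition, eigenvalues ascending. Intended for
#' diagnostics and the spectral-filter path on graphs up to a couple of
#' thousand vertices; the production interpolation path is the sparse solve.
#'
#' @param graph a weighted [surface_graph()].
#' @return List with `values` (ascending) and `vectors` (orthonormal columns,
#'   matching order).
#' @export
laplacian_eigen <- function(graph) {
  if (is.null(graph$laplacian)) stop("graph weights are unset")
  e <- eigen(as.matrix(graph$laplacian), symmetric = TRUE)
  idx <- rev(seq_along(e$values))
  list(values = e$values[idx], vectors = e$vectors[, idx, drop = FALSE])
}

#' Interpolate by spectral graph filtering
#'
#' Applies a graph filter in the Laplacian eigenbasis:
#' `U diag(h(lambda)) U' f_s`. With `h(lambda) = 1/(1 + lambda)` and the
#' masks collapsed to the identity (`alpha = beta = 1`) this reproduces
#' [magic_lat_solve()] exactly, exposing the method as a low-pass graph
#' filter of the observed signal.
#'
#' @param decomp a [laplacian_eigen()] decomposition of the problem's
#'   Laplacian.
#' @param fs per-vertex input signal (zero at unlabelled vertices).
#' @param filter scalar function mapping an eigenvalue to a gain; must be
#'   finite on the spectrum.
#' @return Numeric vector: the filtered (interpolated) signal.
#' @export
spectral_interpolate <- function(decomp, fs, filter) {
  U <- decomp$vectors
  if (length(fs) != nrow(U)) stop("fs length does not match decomposition")
  gains <- vapply(decomp$values, filter, numeric(1))
  if (!all(is.finite(gains))) {
    stop("filter gain is not finite on the Laplacian spectrum")
  }
  as.numeric(U %*% (gains * crossprod(U, fs)))
}

#' Gaussian process regression baseline
#'
#' Out-of-the-box scattered-data interpolator used as a comparison method:
#' posterior mean of a zero-mean GP whose covariance is a sum of three
#' squared-exponential (RBF) kernels with length scales 0.01, 0.1 and 1.
#' Because those length scales are dimensionless, coordinates are by default
#' rescaled so the bounding-box diagonal of all points is 1; set
#' `rescale = FALSE` to use raw coordinates.
#'
#' @param train_coords m x 3 matrix of training locations (mm).
#' @param train_values m LAT values (ms).
#' @param query_coords q x 3 matrix of prediction locations (mm).
#' @param length_scales RBF length scales (default `c(0.01, 0.1, 1)`).
#' @param jitter diagonal regularisation added to the kernel matrix
#'   (default 1e-8).
#' @param rescale rescale coordinates to unit bounding-box diagonal
#'   (default TRUE).
#' @return Numeric vector of q posterior-mean LAT values.
#' @export
gpr_baseline <- function(train_coords, train_values, query_coords,
                         length_scales = c(0.01, 0.1, 1), jitter = 1e-8,
                         rescale = TRUE) {
  train_coords <- as.matrix(train_coords)
  query_coords <- as.matrix(query_coords)
  if (nrow(train_coords) < 1L) stop("at least one training point is required")
  if (length(train_values) != nrow(train_coords)) {
    stop("train_values must have one entry per training point")
  }
  if (anyDuplicated(train_coords)) {
    stop("duplicate training coordinates make the kernel singular; merge them first")
  }
  if (rescale) {
    all_pts <- rbind(train_coords, query_coords)
    diag_len <- sqrt(sum((apply(all_pts, 2L, max) -
                            apply(all_pts, 2L, min))^2))
    if (diag_len > 0) {
      train_coords <- train_coords / diag_len
      query_coords <- query_coords / diag_len
    }
  }
  K <- rbf_sum_kernel(train_coords, train_coords, length_scales)
  Ks <- rbf_sum_kernel(query_coords, train_coords, length_scales)
  ch <- chol(K + diag(jitter, nrow(K)))
  as.numeric(Ks %*% backsolve(ch, forwardsolve(t(ch), train_values)))
}

rbf_sum_kernel <- function(a, b, length_scales) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  K <- 0
  for (l in length_scales) K <- K + exp(-d2 / (2 * l^2))
  K
}
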