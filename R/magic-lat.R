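#' Fit a graph-based LAT interpolation model
#'
#' The main entry point: takes a triangulated cardiac-surface mesh and sparse
#' LAT observations and produces a full per-vertex activation map. The
#' pipeline is (1) snap observations to nearest vertices and optionally
#' reject locally anomalous ones, (2) build the positive-weight cotangent
#' Laplacian of the mesh, (3) quantize the LAT field by nearest neighbours
#' and delete edges across activation jumps of at least `delta_lat` ms,
#' (4) solve the regularised semi-supervised system
#' `(M_l + alpha*M_u + beta*L) f* = f_s` in closed form.
#'
#' @param mesh a [tri_mesh()].
#' @param samples a [lat_samples()] (raw catheter observations) or a
#'   [labeled_set()] (already snapped to vertices).
#' @param alpha Tikhonov coefficient, > 0 (default 1e-5).
#' @param beta Dirichlet smoothness coefficient, >= 0 (default 1e-2).
#' @param delta_lat edge-removal jump threshold in ms (default 50);
#'   `Inf` keeps every mesh edge.
#' @param filter_anomalies reject observations deviating from their local
#'   neighbourhood before fitting (default TRUE; see [remove_anomalous()]).
#' @param k,radius,threshold parameters of [remove_anomalous()].
#' @param weight_floor positive replacement for non-positive cotangent
#'   weights (default 1e-6).
#' @return An object of class `magic_lat`: a list with the per-vertex
#'   interpolant (`fitted`), the labelled set used (`labeled`), the
#'   (sparsified) `graph`, the nearest-neighbour `quantization`, and the
#'   configuration. Supports `print`, `summary`, `fitted`, `coef`,
#'   `residuals`, `predict` and `plot`.
#' @examples
#' mesh <- make_mesh("icosphere", subdivisions = 2)
#' truth <- simulate_focal_lat(mesh, focus = 1, conduction_velocity = 0.8)
#' obs <- sample_observations(mesh, truth, m = 60, seed = 1)
#' fit <- magic_lat(mesh, obs)
#' fit
#' @export
magic_lat <- function(mesh, samples, alpha = 1e-5, beta = 1e-2,
                      delta_lat = 50, filter_anomalies = TRUE, k = 5,
                      radius = 5, threshold = 30, weight_floor = 1e-6) {
  if (!inherits(mesh, "tri_mesh")) stop("mesh must be a tri_mesh")
  if (inherits(samples, "lat_samples")) {
    labeled <- snap_to_vertices(mesh, samples)
  } else if (inherits(samples, "labeled_set")) {
    labeled <- samples
  } else {
    stop("samples must be lat_samples or a labeled_set")
  }
  if (filter_anomalies) {
    labeled <- remove_anomalous(labeled, mesh, k = k, radius = radius,
                                threshold = threshold)
    if (!length(labeled$values)) {
      stop("anomaly filtering removed every observation")
    }
  }
  graph <- cotan_laplacian(mesh, floor = weight_floor)
  q <- nn_quantize(mesh, labeled)
  graph <- sparsify_edges(graph, q, delta_lat = delta_lat)
  f <- magic_lat_solve(graph, labeled$values, labeled$vertex_indices,
                       alpha = alpha, beta = beta)
  structure(list(fitted = f, labeled = labeled, graph = graph,
                 quantization = q, mesh = mesh,
                 config = list(alpha = alpha, beta = beta,
                               delta_lat = delta_lat,
                               filter_anomalies = filter_anomalies,
                               k = k, radius = radius, threshold = threshold,
                               weight_floor = weight_floor),
                 call = match.call()),
            class = "magic_lat")
}

#' @method print magic_lat
#' @export
print.magic_lat <- function(x, ...) {
  cat("Graph-based LAT interpolation fit\n")
  cat(sprintf("  mesh: %d vertices, %d faces\n", nrow(x$mesh$vertices),
              nrow(x$mesh$faces)))
  cat(sprintf("  labelled vertices: %d; edges removed: %d\n",
              length(x$labeled$values), nrow(x$graph$removed_edges)))
  cat(sprintf("  alpha = %g, beta = %g, delta_lat = %g ms\n",
              x$config$alpha, x$config$beta, x$config$delta_lat))
  cat(sprintf("  interpolated LAT range: [%.1f, %.1f] ms\n",
              min(x$fitted), max(x$fitted)))
  invisible(x)
}

#' @method summary magic_lat
#' @export
summary.magic_lat <- function(object, ...) {
  r <- residuals(object)
  structure(list(n = nrow(object$mesh$vertices),
                 t = nrow(object$mesh$faces),
                 m = length(object$labeled$values),
                 removed_edges = nrow(object$graph$removed_edges),
                 total_edges = nrow(object$graph$edges) +
                   nrow(object$graph$removed_edges),
                 config = object$config,
                 fitted_range = range(object$fitted),
                 resid_summary = summary(r),
                 resid_rms = sqrt(mean(r^2))),
            class = "summary.magic_lat")
}

#' @method print summary.magic_lat
#' @export
print.summary.magic_lat <- function(x, ...) {
  cat("Graph-based LAT interpolation fit\n")
  cat(sprintf("  mesh: %d vertices, %d faces; %d labelled vertices\n",
              x$n, x$t, x$m))
  cat(sprintf("  graph: %d edges, %d removed by the %g ms jump rule\n",
              x$total_edges - x$removed_edges, x$removed_edges,
              x$config$delta_lat))
  cat(sprintf("  alpha = %g, beta = %g\n", x$config$alpha, x$config$beta))
  cat(sprintf("  interpolated LAT range: [%.1f, %.1f] ms\n",
              x$fitted_range[1], x$fitted_range[2]))
  cat(sprintf("  residuals at labelled vertices (observed - fitted), RMS %.3f ms:\n",
              x$resid_rms))
  print(x$resid_summary)
  invisible(x)
}

#' @export
fitted.magic_lat <- function(object, ...) object$fitted

#' @export
coef.magic_lat <- function(object, ...) object$fitted

#' @export
residuals.magic_lat <- function(object, ...) {
  object$labeled$values - object$fitted[object$labeled$vertex_indices]
}

#' Predict LAT at arbitrary locations
#'
#' Returns the interpolated map at mesh vertices, or — when `newdata` gives
#' 3-D coordinates — at the Euclidean-nearest mesh vertex of each query point
#' (consistent with how observations are snapped during fitting).
#'
#' @param object a [magic_lat()] fit.
#' @param newdata optional q x 3 coordinate matrix (mm).
#' @param ... unused.
#' @return Numeric vector of LAT predictions (ms).
#' @export
predict.magic_lat <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != 3L) stop("newdata must be a q x 3 coordinate matrix")
  object$fitted[nearest_point_index(newdata, object$mesh$vertices)]
}

#' Diagnostic plot of a LAT interpolation fit
#'
#' Observed vs fitted LAT at the labelled vertices (left) and a histogram of
#' the interpolated map (right).
#'
#' @param x a [magic_lat()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.magic_lat <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  obs <- x$labeled$values
  fit <- x$fitted[x$labeled$vertex_indices]
  graphics::plot(obs, fit, xlab = "observed LAT [ms]",
                 ylab = "fitted LAT [ms]",
                 main = "Observed vs fitted", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::hist(x$fitted, breaks = 30, main = "Interpolated map",
                 xlab = "LAT [ms]")
  invisible(x)
}
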