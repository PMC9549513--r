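# Pre-processing: snap catheter observations to mesh vertices and reject
# locally anomalous observations, mimicking the manual culling a mapping
# technician performs during the procedure.

#' Labelled vertex set
#'
#' LAT values attached to mesh vertices after snapping: unique 1-based vertex
#' indices plus one value (ms) per index.
#'
#' @param vertex_indices integer vector of unique 1-based vertex indices.
#' @param values numeric vector of LAT values (ms), same length.
#' @param n optional vertex count for range checking.
#' @return An object of class `labeled_set`.
#' @export
labeled_set <- function(vertex_indices, values, n = NULL) {
  vertex_indices <- as.integer(vertex_indices)
  values <- as.numeric(values)
  if (length(vertex_indices) != length(values)) {
    stop("vertex_indices and values must have the same length")
  }
  if (anyDuplicated(vertex_indices)) {
    stop("vertex_indices must be unique; merge duplicates first")
  }
  if (!is.null(n) && length(vertex_indices) &&
      (min(vertex_indices) < 1L || max(vertex_indices) > n)) {
    stop(sprintf("vertex index out of range [1, %d]", n))
  }
  structure(list(vertex_indices = vertex_indices, values = values),
            class = "labeled_set")
}

#' @method print labeled_set
#' @export
print.labeled_set <- function(x, ...) {
  cat(sprintf("%d labelled vertices, LAT in [%.1f, %.1f] ms\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.labeled_set <- function(x) length(x$values)

# index of the Euclidean-nearest row of `points` for each row of `query`;
# ties go to the lowest index (which.min semantics), chunked to bound memory.
# The fast |q - p|^2 = |q|^2 - 2 q.p + |p|^2 expansion carries rounding noise
# that can flip exact ties, so near-ties are re-decided with the direct
# formula.
nearest_point_index <- function(query, points, chunk = 512L) {
  query <- as.matrix(query)
  points <- as.matrix(points)
  p2 <- rowSums(points^2)
  out <- integer(nrow(query))
  for (start in seq(1L, nrow(query), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(query))
    q <- query[idx, , drop = FALSE]
    d2 <- outer(rowSums(q^2), p2, "+") - 2 * (q %*% t(points))
    best <- max.col(-d2, ties.method = "first")
    dmin <- d2[cbind(seq_along(best), best)]
    tol <- 1e-9 * pmax(1, abs(dmin))
    for (r in seq_along(best)) {
      cand <- which(d2[r, ] <= dmin[r] + tol[r])
      if (length(cand) > 1L) {
        exact <- colSums((t(points[cand, , drop = FALSE]) - q[r, ])^2)
        best[r] <- cand[which.min(exact)]
      }
    }
    out[idx] <- best
  }
  out
}

#' Snap LAT samples to their nearest mesh vertices
#'
#' Assigns every observation to the Euclidean-nearest mesh vertex (ties broken
#' by lowest vertex index). Observations landing on the same vertex are merged
#' by the arithmetic mean of their LAT values.
#'
#' @param mesh a [tri_mesh()].
#' @param samples a [lat_samples()].
#' @return A [labeled_set()] sorted by vertex index.
#' @export
snap_to_vertices <- function(mesh, samples) {
  idx <- nearest_point_index(samples$coords, mesh$vertices)
  merged <- tapply(samples$values, idx, mean)
  vi <- as.integer(names(merged))
  o <- order(vi)
  labeled_set(vi[o], as.numeric(merged)[o], n = nrow(mesh$vertices))
}

#' Remove locally anomalous observations
#'
#' Drops every observation whose LAT differs from the mean of its up-to-`k`
#' Euclidean-nearest co-observations within `radius` by strictly more than
#' `threshold`. The decision is made against the original set in a single
#' pass (no cascading removals); observations with no neighbour inside the
#' radius are kept.
#'
#' @param set a [labeled_set()].
#' @param mesh the [tri_mesh()] the set indexes into.
#' @param k neighbour count cap (default 5).
#' @param radius neighbourhood radius in mm (default 5).
#' @param threshold rejection threshold in ms (default 30, strict inequality).
#' @return The filtered [labeled_set()].
#' @export
remove_anomalous <- function(set, mesh, k = 5, radius = 5, threshold = 30) {
  m <- length(set$values)
  if (m == 0L) stop("cannot filter an empty labelled set")
  if (m == 1L) return(set)
  xyz <- mesh$vertices[set$vertex_indices, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  keep <- logical(m)
  for (i in seq_len(m)) {
    di <- d[i, -i]
    vals <- set$values[-i]
    inside <- which(di <= radius)
    if (!length(inside)) {
      keep[i] <- TRUE
      next
    }
    nb <- inside[order(di[inside])][seq_len(min(k, length(inside)))]
    keep[i] <- abs(set$values[i] - mean(vals[nb])) <= threshold
  }
  labeled_set(set$vertex_indices[keep], set$values[keep],
              n = nrow(mesh$vertices))
}
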