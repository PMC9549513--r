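# Surface graph construction: face-derived edge set, positive-weight
# cotangent Laplacian, nearest-neighbour quantization of the LAT field, and
# removal of edges crossing implausibly large activation jumps.

#' Surface graph with weights and Laplacian
#'
#' Undirected graph over the mesh vertices. `edges` is an e x 2 matrix of
#' 1-based vertex pairs with `edges[,1] < edges[,2]`; `weights` holds one
#' symmetric non-negative weight per edge; `laplacian` is the sparse
#' symmetric matrix L = D - W with D the diagonal of weighted degrees.
#' `removed_edges` records edges deleted by [sparsify_edges()].
#'
#' @param n vertex count.
#' @param edges e x 2 integer matrix of vertex pairs.
#' @param weights numeric vector of e edge weights, or NULL if unset.
#' @param removed_edges r x 2 integer matrix of deleted edges.
#' @return An object of class `surface_graph`.
#' @export
surface_graph <- function(n, edges, weights = NULL,
                          removed_edges = matrix(integer(), 0L, 2L)) {
  edges <- as.matrix(edges)
  storage.mode(edges) <- "integer"
  if (nrow(edges) && ncol(edges) != 2L) stop("edges must be an e x 2 matrix")
  edges <- t(apply(edges, 1L, sort))
  if (nrow(edges) == 1L) edges <- matrix(edges, 1L, 2L)
  if (anyDuplicated(edges)) stop("duplicate edges")
  if (nrow(edges) && (min(edges) < 1L || max(edges) > n)) {
    stop(sprintf("edge index out of range [1, %d]", n))
  }
  g <- structure(list(n = as.integer(n), edges = edges, weights = NULL,
                      laplacian = NULL, removed_edges = removed_edges),
                 class = "surface_graph")
  if (!is.null(weights)) {
    if (length(weights) != nrow(edges)) {
      stop("weights must have one entry per edge")
    }
    if (any(weights <= 0)) stop("all retained edge weights must be positive")
    g$weights <- as.numeric(weights)
    g$laplacian <- build_laplacian(n, edges, g$weights)
  }
  g
}

#' @method print surface_graph
#' @export
print.surface_graph <- function(x, ...) {
  cat(sprintf("Surface graph: %d vertices, %d edges (%d removed)%s\n",
              x$n, nrow(x$edges), nrow(x$removed_edges),
              if (is.null(x$weights)) ", weights unset" else ""))
  invisible(x)
}

build_laplacian <- function(n, edges, weights) {
  i <- edges[, 1]; j <- edges[, 2]
  W <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(weights, weights),
                            dims = c(n, n))
  L <- Matrix::Diagonal(n, x = Matrix::rowSums(W)) - W
  Matrix::forceSymmetric(L)
}

#' Derive the edge set of a mesh
#'
#' An edge (i, j) exists iff vertices i and j form two corners of some face;
#' the three edges of every face are collected and de-duplicated. Weights are
#' left unset (see [cotan_laplacian()]).
#'
#' @param mesh a [tri_mesh()].
#' @return A [surface_graph()] with `weights = NULL`.
#' @export
mesh_graph <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  surface_graph(nrow(mesh$vertices), e[order(e[, 1], e[, 2]), , drop = FALSE])
}

#' Cotangent Laplacian with guaranteed positive edge weights
#'
#' Builds the classic cotangent-weight graph Laplacian of a triangle mesh:
#' `w_ij = 1/2 * sum(cot(angle opposite edge ij))` over the one or two faces
#' containing the edge (boundary edges get the single half-cotangent). A
#' non-positive cotangent weight (obtuse configurations) is replaced by a
#' small positive `floor`, preserving the positivity, symmetry, zero row sum
#' and positive-semidefiniteness required of the smoothing operator.
#'
#' @param mesh a [tri_mesh()].
#' @param floor replacement weight for non-positive cotangent sums
#'   (default 1e-6).
#' @return A [surface_graph()] with weights and `laplacian` set.
#' @export
cotan_laplacian <- function(mesh, floor = 1e-6) {
  v <- mesh$vertices
  f <- mesh$faces
  n <- nrow(v)
  g <- mesh_graph(mesh)
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- rowcross3(b - a, c_ - a)
  area2 <- sqrt(rowSums(cr^2))          # twice the face area
  degen <- which(area2 < 2e-12)
  if (length(degen)) {
    stop(sprintf("degenerate face %d (area < 1e-12 mm^2)", degen[1]))
  }
  # cot of the angle at each corner = dot of adjacent edges / |cross|
  cot1 <- rowSums((b - a) * (c_ - a)) / area2  # at corner 1, opposite edge 2-3
  cot2 <- rowSums((a - b) * (c_ - b)) / area2  # at corner 2, opposite edge 1-3
  cot3 <- rowSums((a - c_) * (b - c_)) / area2 # at corner 3, opposite edge 1-2
  ei <- c(f[, 2], f[, 1], f[, 1])
  ej <- c(f[, 3], f[, 3], f[, 2])
  ii <- pmin(ei, ej); jj <- pmax(ei, ej)
  # sparseMatrix sums duplicate (i, j) entries: one or two half-cotangents
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = 0.5 * c(cot1, cot2, cot3),
                            dims = c(n, n))
  w <- S[cbind(g$edges[, 1], g$edges[, 2])]
  w[w <= 0] <- floor
  surface_graph(g$n, g$edges, weights = w)
}

rowcross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Nearest-neighbour quantization of the LAT field
#'
#' Assigns to every mesh vertex the LAT value of its Euclidean-nearest
#' labelled vertex (labelled vertices keep their own value). This coarse
#' per-vertex field is what the edge-removal rule of [sparsify_edges()] is
#' evaluated on.
#'
#' @param mesh a [tri_mesh()].
#' @param labels a non-empty [labeled_set()].
#' @return Numeric vector of length n; every entry equals some observed value.
#' @export
nn_quantize <- function(mesh, labels) {
  if (length(labels$values) == 0L) stop("labels must be non-empty")
  nearest <- nearest_point_index(mesh$vertices,
                                 mesh$vertices[labels$vertex_indices, ,
                                               drop = FALSE])
  q <- labels$values[nearest]
  q[labels$vertex_indices] <- labels$values
  q
}

#' Remove edges across implausible activation jumps
#'
#' Deletes every edge whose endpoints' quantized LAT values differ by at
#' least `delta_lat` ms (the inequality is `>=`): such a jump cannot arise
#' from continuous conduction and indicates scar block, a re-entry boundary
#' or a mis-windowed cycle, so the vertices should not be smoothed across.
#' Surviving edges keep their cotangent weights; the Laplacian diagonal is
#' recomputed so row sums stay zero.
#'
#' @param graph a weighted [surface_graph()].
#' @param q per-vertex quantized LAT values, length `graph$n`
#'   (see [nn_quantize()]).
#' @param delta_lat jump threshold in ms (default 50); `Inf` disables removal.
#' @return The sparsified [surface_graph()]; deleted pairs are appended to
#'   `removed_edges`.
#' @export
sparsify_edges <- function(graph, q, delta_lat = 50) {
  if (is.null(graph$weights)) stop("graph weights are unset; build them first")
  if (length(q) != graph$n) stop("quantization length must equal graph$n")
  jump <- abs(q[graph$edges[, 1]] - q[graph$edges[, 2]])
  drop <- jump >= delta_lat & jump > 0
  if (!any(drop)) return(graph)
  surface_graph(graph$n, graph$edges[!drop, , drop = FALSE],
                weights = graph$weights[!drop],
                removed_edges = rbind(graph$removed_edges,
                                      graph$edges[drop, , drop = FALSE]))
}

# Euclidean lengths of graph edges, used as Dijkstra weights
edge_lengths <- function(mesh, graph = mesh_graph(mesh)) {
  d <- mesh$vertices[graph$edges[, 1], , drop = FALSE] -
    mesh$vertices[graph$edges[, 2], , drop = FALSE]
  sqrt(rowSums(d^2))
}
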