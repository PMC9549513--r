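#' Triangular surface mesh
#'
#' Container for an indexed triangle mesh approximating a cardiac chamber
#' surface: vertex coordinates in millimetres and triangular faces given as
#' integer triples. Faces are 1-based internally (R convention); mesh files
#' and CSV output use 0-based indices as is usual on disk.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param faces integer matrix, t x 3, 1-based vertex indices per triangle.
#' @return An object of class `tri_mesh` with elements `vertices` and `faces`.
#' @examples
#' m <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), rbind(1:3))
#' m
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be a t x 3 matrix")
  n <- nrow(vertices)
  if (n < 3L) stop("a mesh needs at least 3 vertices")
  if (nrow(faces) < 1L) stop("a mesh needs at least 1 face")
  if (anyNA(vertices)) stop("vertex coordinates contain NA")
  bad <- which(faces < 1L | faces > n)
  if (length(bad)) {
    stop(sprintf("face index out of range [1, %d] at face %d", n,
                 ((bad[1] - 1L) %% nrow(faces)) + 1L))
  }
  degen <- which(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
                   faces[, 2] == faces[, 3])
  if (length(degen)) {
    stop(sprintf("face %d has repeated vertex indices", degen[1]))
  }
  key <- apply(faces, 1L, function(f) paste(sort(f), collapse = "-"))
  if (anyDuplicated(key)) {
    stop(sprintf("duplicated face (as unordered triple) at face %d",
                 which(duplicated(key))[1]))
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @method print tri_mesh
#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("Triangular surface mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  bb <- apply(x$vertices, 2L, range)
  cat(sprintf("  bounding box [mm]: x [%.2f, %.2f]  y [%.2f, %.2f]  z [%.2f, %.2f]\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Scattered LAT observations
#'
#' A set of local activation time (LAT) measurements: 3-D catheter positions
#' in millimetres and LAT values in milliseconds relative to the reference
#' electrogram. Sample locations generally do not coincide with mesh
#' vertices; see [snap_to_vertices()].
#'
#' @param coords numeric matrix, m x 3, sample coordinates in mm.
#' @param values numeric vector of m LAT values in ms.
#' @return An object of class `lat_samples`.
#' @export
lat_samples <- function(coords, values) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  values <- as.numeric(values)
  if (ncol(coords) != 3L) stop("coords must be an m x 3 matrix")
  if (nrow(coords) != length(values)) {
    stop("coords and values must have the same length")
  }
  if (length(values) < 1L) stop("at least one sample is required")
  if (!all(is.finite(values))) stop("all LAT values must be finite")
  if (anyNA(coords)) stop("sample coordinates contain NA")
  structure(list(coords = coords, values = values), class = "lat_samples")
}

#' @method print lat_samples
#' @export
print.lat_samples <- function(x, ...) {
  cat(sprintf("%d LAT samples, values in [%.1f, %.1f] ms\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.lat_samples <- function(x) length(x$values)
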