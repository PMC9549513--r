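# Readers/writers for open mesh formats (ASCII OFF/PLY/OBJ) and the CSV
# sample/result tables. Only indexed triangle meshes are supported; polygons
# with more than 3 sides are rejected, not triangulated.

#' Read a triangular surface mesh
#'
#' Reads an indexed triangle mesh from an ASCII OFF, PLY or OBJ file.
#' Non-triangular faces are an error: interpolation assumes a triangulation
#' and silent fan-triangulation could hide bad input.
#'
#' @param path path to the mesh file.
#' @param fmt one of `"auto"` (from extension), `"off"`, `"ply"`, `"obj"`.
#' @return A [tri_mesh()].
#' @seealso [write_mesh()]
#' @export
read_mesh <- function(path, fmt = c("auto", "off", "ply", "obj")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) stop(sprintf("mesh file not found: %s", path))
  if (fmt == "auto") {
    fmt <- switch(tolower(tools::file_ext(path)),
                  off = "off", ply = "ply", obj = "obj",
                  stop(sprintf("cannot infer mesh format from '%s'; pass fmt=",
                               basename(path))))
  }
  switch(fmt,
         off = read_off(path),
         ply = read_ply(path),
         obj = read_obj(path))
}

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines) || toupper(lines[1]) != "OFF") {
    stop(sprintf("%s: not an ASCII OFF file (missing OFF header)", path))
  }
  counts <- scan(text = lines[2], quiet = TRUE)
  if (length(counts) < 2L) stop(sprintf("%s: malformed OFF count line", path))
  n <- as.integer(counts[1]); t <- as.integer(counts[2])
  vtx <- lines[3:(2 + n)]
  verts <- matrix(scan(text = vtx, quiet = TRUE), ncol = 3L, byrow = TRUE)
  fl <- lines[(3 + n):(2 + n + t)]
  faces <- matrix(0L, t, 3L)
  for (i in seq_len(t)) {
    f <- scan(text = fl[i], quiet = TRUE)
    if (f[1] != 3) {
      stop(sprintf("%s: non-triangular face with %d vertices at face %d",
                   path, f[1], i))
    }
    faces[i, ] <- as.integer(f[2:4]) + 1L
  }
  tri_mesh(verts, faces)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply") {
    stop(sprintf("%s: missing 'ply' magic line", path))
  }
  hdr_end <- which(trimws(lines) == "end_header")[1]
  if (is.na(hdr_end)) stop(sprintf("%s: no end_header in PLY file", path))
  hdr <- trimws(lines[seq_len(hdr_end)])
  if (any(grepl("^format\\s+binary", hdr))) {
    stop(sprintf("%s: binary PLY is not supported; export ASCII", path))
  }
  elem <- grep("^element\\s", hdr, value = TRUE)
  counts <- list()
  for (e in elem) {
    p <- strsplit(e, "\\s+")[[1]]
    counts[[p[2]]] <- as.integer(p[3])
  }
  if (is.null(counts$vertex) || is.null(counts$face)) {
    stop(sprintf("%s: PLY file must declare vertex and face elements", path))
  }
  body <- trimws(lines[(hdr_end + 1L):length(lines)])
  body <- body[nzchar(body)]
  n <- counts$vertex; t <- counts$face
  verts <- t(vapply(body[seq_len(n)],
                    function(l) scan(text = l, quiet = TRUE)[1:3],
                    numeric(3)))
  faces <- matrix(0L, t, 3L)
  for (i in seq_len(t)) {
    f <- scan(text = body[n + i], quiet = TRUE)
    if (f[1] != 3) {
      stop(sprintf("%s: non-triangular face with %d vertices at face %d",
                   path, f[1], i))
    }
    faces[i, ] <- as.integer(f[2:4]) + 1L
  }
  rownames(verts) <- NULL
  tri_mesh(verts, faces)
}

read_obj <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (!length(vl) || !length(fl)) {
    stop(sprintf("%s: OBJ file has no vertices or no faces", path))
  }
  verts <- t(vapply(vl, function(l) {
    scan(text = sub("^v\\s+", "", l), quiet = TRUE)[1:3]
  }, numeric(3)))
  rownames(verts) <- NULL
  faces <- matrix(0L, length(fl), 3L)
  for (i in seq_along(fl)) {
    toks <- strsplit(sub("^f\\s+", "", fl[i]), "\\s+")[[1]]
    if (length(toks) != 3L) {
      stop(sprintf("%s: non-triangular face with %d vertices at face %d",
                   path, length(toks), i))
    }
    # tokens may be "i", "i/j", "i//k", "i/j/k"; the vertex index leads
    faces[i, ] <- as.integer(vapply(strsplit(toks, "/"), `[[`, "", 1L))
  }
  tri_mesh(verts, faces)
}

#' Write a triangular surface mesh
#'
#' @param mesh a [tri_mesh()].
#' @param path output path; format from extension unless `fmt` given.
#' @param fmt one of `"auto"`, `"off"`, `"ply"`, `"obj"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, fmt = c("auto", "off", "ply", "obj")) {
  fmt <- match.arg(fmt)
  if (fmt == "auto") {
    fmt <- switch(tolower(tools::file_ext(path)),
                  off = "off", ply = "ply", obj = "obj",
                  stop("cannot infer mesh format from extension; pass fmt="))
  }
  v <- mesh$vertices
  f0 <- mesh$faces - 1L   # 0-based on disk
  n <- nrow(v); t <- nrow(f0)
  vl <- sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3])
  con <- file(path, "w")
  on.exit(close(con))
  if (fmt == "off") {
    writeLines(c("OFF", sprintf("%d %d 0", n, t), vl,
                 sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3])), con)
  } else if (fmt == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", n),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", t),
                 "property list uchar int vertex_indices", "end_header", vl,
                 sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3])), con)
  } else {
    writeLines(c(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]),
                 sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                         mesh$faces[, 3])), con)
  }
  invisible(path)
}

#' Read LAT samples from CSV
#'
#' Expects a header with columns `x,y,z,lat` (coordinates in mm, LAT in ms);
#' extra columns are ignored, row order is preserved.
#'
#' @param path path to the CSV file.
#' @return A [lat_samples()].
#' @export
read_lat_samples <- function(path) {
  if (!file.exists(path)) stop(sprintf("sample file not found: %s", path))
  df <- utils::read.csv(path)
  if (nrow(df) == 0L) stop(sprintf("%s: no sample rows", path))
  need <- c("x", "y", "z", "lat")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  for (col in need) {
    if (!is.numeric(df[[col]])) {
      stop(sprintf("%s: column '%s' is not numeric", path, col))
    }
  }
  lat_samples(as.matrix(df[, c("x", "y", "z")]), df$lat)
}

#' Write LAT samples to CSV
#'
#' @param samples a [lat_samples()].
#' @param path output CSV path (columns `x,y,z,lat`).
#' @return `path`, invisibly.
#' @export
write_lat_samples <- function(samples, path) {
  df <- data.frame(x = samples$coords[, 1], y = samples$coords[, 2],
                   z = samples$coords[, 3], lat = samples$values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a per-vertex signal to CSV
#'
#' Writes one row per mesh vertex with columns
#' `vertex_index,x,y,z,lat` (`vertex_index` is 0-based, matching the indices
#' inside mesh files).
#'
#' @param path output CSV path.
#' @param mesh a [tri_mesh()].
#' @param values numeric vector of length `nrow(mesh$vertices)`, ms.
#' @return `path`, invisibly.
#' @export
write_vertex_signal <- function(path, mesh, values) {
  n <- nrow(mesh$vertices)
  if (length(values) != n) {
    stop(sprintf("values has length %d but the mesh has %d vertices",
                 length(values), n))
  }
  df <- data.frame(vertex_index = seq_len(n) - 1L,
                   x = mesh$vertices[, 1], y = mesh$vertices[, 2],
                   z = mesh$vertices[, 3], lat = values)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a per-vertex signal written by [write_vertex_signal()]
#'
#' @param path CSV path with columns `vertex_index,x,y,z,lat`.
#' @return numeric vector of LAT values ordered by vertex index.
#' @export
read_vertex_signal <- function(path) {
  df <- utils::read.csv(path)
  need <- c("vertex_index", "lat")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  }
  df$lat[order(df$vertex_index)]
}
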