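# Synthetic meshes and ground-truth activation fields. Two clinical regimes
# are emulated at desk scale: a focal arrhythmia (PVC-like), where activation
# spreads centrifugally from one origin so LAT grows with geodesic distance
# from the focus; and an "early-meets-late" map, where adjacent regions carry
# extreme low and high LAT values across a sharp boundary.

#' Generate a synthetic surface mesh
#'
#' `icosphere`: subdivided icosahedron projected to a sphere
#' (`10 * 4^k + 2` vertices at subdivision `k`); `ellipsoid`: the same mesh
#' scaled anisotropically; `cylinder`: an open tube. Default dimensions are
#' in the range of a human ventricular chamber.
#'
#' @param shape `"icosphere"`, `"ellipsoid"` or `"cylinder"`.
#' @param subdivisions icosphere subdivision level k >= 0 (default 4,
#'   n = 2562, matching the low-thousands vertex counts of clinical meshes).
#' @param radius sphere/cylinder radius in mm (default 25).
#' @param semi_axes ellipsoid semi-axes in mm (default `c(20, 25, 35)`).
#' @param height,segments,rings cylinder dimensions (mm) and resolution.
#' @return A [tri_mesh()].
#' @export
make_mesh <- function(shape = c("icosphere", "ellipsoid", "cylinder"),
                      subdivisions = 4, radius = 25,
                      semi_axes = c(20, 25, 35), height = 60,
                      segments = 32, rings = 24) {
  shape <- match.arg(shape)
  if (shape == "cylinder") return(cylinder_mesh(radius, height, segments, rings))
  m <- icosphere_mesh(subdivisions)
  v <- if (shape == "icosphere") m$vertices * radius
       else sweep(m$vertices, 2L, semi_axes, "*")
  tri_mesh(v, m$faces)
}

icosphere_mesh <- function(k) {
  if (k < 0) stop("subdivisions must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (iter in seq_len(k)) {
    edge_key <- function(i, j) pmin(i, j) * (nrow(v) + 1) + pmax(i, j)
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
    keys <- edge_key(e[, 1], e[, 2])
    uk <- unique(keys)
    mid_of <- match(keys, uk) + nrow(v)
    ue <- e[!duplicated(keys), , drop = FALSE]
    mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE]) / 2
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    t <- nrow(f)
    m12 <- mid_of[seq_len(t)]
    m23 <- mid_of[t + seq_len(t)]
    m13 <- mid_of[2 * t + seq_len(t)]
    f <- rbind(cbind(f[, 1], m12, m13), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m13, m23), cbind(m12, m23, m13))
  }
  list(vertices = v, faces = f)
}

cylinder_mesh <- function(radius, height, segments, rings) {
  theta <- 2 * pi * (seq_len(segments) - 1) / segments
  z <- seq(0, height, length.out = rings)
  v <- do.call(rbind, lapply(z, function(zz) {
    cbind(radius * cos(theta), radius * sin(theta), zz)
  }))
  f <- NULL
  idx <- function(r, s) (r - 1L) * segments + ((s - 1L) %% segments) + 1L
  for (r in seq_len(rings - 1L)) {
    for (s in seq_len(segments)) {
      a <- idx(r, s); b <- idx(r, s + 1L)
      c_ <- idx(r + 1L, s); d <- idx(r + 1L, s + 1L)
      f <- rbind(f, c(a, b, d), c(a, d, c_))
    }
  }
  tri_mesh(v, f)
}

# geodesic (graph shortest-path) distances in mm from one vertex
geodesic_from <- function(mesh, from) {
  g <- mesh_graph(mesh)
  ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
  d <- as.numeric(igraph::distances(ig, v = from,
                                    weights = edge_lengths(mesh, g)))
  if (any(!is.finite(d))) {
    stop("mesh has a component unreachable from the focus vertex")
  }
  d
}

#' Simulate a focal activation field
#'
#' LAT grows with geodesic distance from a focus vertex divided by the
#' conduction velocity, plus optional Gaussian measurement noise; the field
#' is shifted so the focus sits at 0 ms. With `noise_sd = 0` the focus is
#' exactly the map minimum.
#'
#' @param mesh a [tri_mesh()].
#' @param focus focus vertex index, or `"random"`.
#' @param conduction_velocity wavefront speed in mm/ms (default 0.8).
#' @param noise_sd measurement noise SD in ms (default 0).
#' @param seed integer seed for noise (and the random focus).
#' @return Numeric per-vertex LAT vector (ms) with attribute `"focus"`.
#' @export
simulate_focal_lat <- function(mesh, focus = 1, conduction_velocity = 0.8,
                               noise_sd = 0, seed = 1) {
  if (conduction_velocity <= 0) stop("conduction_velocity must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n <- nrow(mesh$vertices)
  if (identical(focus, "random")) {
    focus <- with_seed(seed + 10007L, sample.int(n, 1L))
  }
  if (focus < 1L || focus > n) stop("focus vertex out of range")
  lat <- geodesic_from(mesh, focus) / conduction_velocity
  if (noise_sd > 0) {
    lat <- lat + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  }
  lat <- lat - lat[focus]
  attr(lat, "focus") <- as.integer(focus)
  lat
}

#' Simulate an early-meets-late activation field
#'
#' A focal field on one side of a boundary plane; the same field plus
#' `jump_ms` on the other side, creating adjacent vertices whose LAT differs
#' by far more than continuous conduction allows (the regime where edge
#' sparsification matters).
#'
#' @inheritParams simulate_focal_lat
#' @param jump_ms LAT offset across the boundary, >= 50 ms (default 250,
#'   the scale of a map where roughly -200 ms sits next to +50 ms).
#' @param plane_point point on the boundary plane (default mesh centroid).
#' @param plane_normal boundary plane normal (default `c(0, 0, 1)`).
#' @return List with `values` (per-vertex ms), `side` (logical, on the
#'   offset side), `n_crossing` (mesh edges straddling the plane) and
#'   `focus`.
#' @export
simulate_early_meets_late <- function(mesh, focus = 1,
                                      conduction_velocity = 0.8,
                                      noise_sd = 0, seed = 1, jump_ms = 250,
                                      plane_point = NULL,
                                      plane_normal = c(0, 0, 1)) {
  if (jump_ms < 50) {
    stop("jump_ms must be >= 50 ms: smaller offsets are not an early-meets-late discontinuity")
  }
  base <- simulate_focal_lat(mesh, focus = focus,
                             conduction_velocity = conduction_velocity,
                             noise_sd = noise_sd, seed = seed)
  if (is.null(plane_point)) plane_point <- colMeans(mesh$vertices)
  s <- as.numeric((mesh$vertices - matrix(plane_point, nrow(mesh$vertices),
                                          3L, byrow = TRUE)) %*% plane_normal)
  side <- s > 0
  if (all(side) || !any(side)) {
    stop("boundary plane does not intersect the mesh")
  }
  g <- mesh_graph(mesh)
  crossing <- sum(side[g$edges[, 1]] != side[g$edges[, 2]])
  values <- as.numeric(base) + jump_ms * side
  list(values = values, side = side, n_crossing = as.integer(crossing),
       focus = attr(base, "focus"))
}

#' Draw synthetic catheter observations from a per-vertex field
#'
#' Emulates an electroanatomic acquisition: `m` distinct random vertices are
#' probed, catheter positions are jittered off the surface vertices, and
#' values optionally carry extra observation noise. Returns raw
#' [lat_samples()] suitable for the full pipeline (snapping included).
#'
#' @param mesh a [tri_mesh()].
#' @param field per-vertex LAT values (ms).
#' @param m number of observations.
#' @param seed integer seed.
#' @param coord_jitter SD of the positional error in mm (default 0.5).
#' @param value_noise SD of extra observation noise in ms (default 0).
#' @return A [lat_samples()] with attribute `"vertex_indices"`.
#' @export
sample_observations <- function(mesh, field, m, seed, coord_jitter = 0.5,
                                value_noise = 0) {
  n <- nrow(mesh$vertices)
  if (length(field) != n) stop("field must have one value per vertex")
  if (m < 1L || m > n) stop(sprintf("m must be in [1, %d]", n))
  with_seed(seed, {
    idx <- sample.int(n, m)
    coords <- mesh$vertices[idx, , drop = FALSE] +
      matrix(stats::rnorm(3L * m, 0, coord_jitter), m, 3L)
    vals <- field[idx]
    if (value_noise > 0) vals <- vals + stats::rnorm(m, 0, value_noise)
    out <- lat_samples(coords, vals)
    attr(out, "vertex_indices") <- idx
    out
  })
}
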