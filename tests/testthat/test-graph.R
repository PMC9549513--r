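test_that("mesh edges are the union of face edges, deduplicated", {
  expect_equal(nrow(mesh_graph(equilateral_mesh())$edges), 3L)
  expect_equal(nrow(mesh_graph(square_mesh())$edges), 5L)
  # icosahedron: Euler's formula V - E + F = 2 gives E = 12 + 20 - 2 = 30
  ico <- make_mesh("icosphere", subdivisions = 0)
  expect_equal(nrow(mesh_graph(ico)$edges),
               nrow(ico$vertices) + nrow(ico$faces) - 2L)
})

test_that("equilateral triangle has the analytic cotangent weight", {
  g <- cotan_laplacian(equilateral_mesh())
  expect_equal(g$weights, rep(1 / tan(pi / 3) / 2, 3), tolerance = 1e-12)
})

test_that("zero cotangent sums are clamped to the positive floor", {
  # square diagonal: opposite angles are both 90 deg, cot sums to 0
  g <- cotan_laplacian(square_mesh())
  diag_edge <- which(g$edges[, 1] == 1L & g$edges[, 2] == 3L)
  expect_equal(g$weights[diag_edge], 1e-6)
  expect_true(all(g$weights > 0))
})

test_that("degenerate faces are rejected by name", {
  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  mesh <- structure(list(vertices = collinear,
                         faces = matrix(c(1L, 4L, 2L, 1L, 3L, 2L), 2, 3,
                                        byrow = TRUE)),
                    class = "tri_mesh")
  expect_error(cotan_laplacian(mesh), "degenerate face 2")
})

test_that("the Laplacian satisfies its operator contract on varied meshes", {
  meshes <- list(equilateral_mesh(), square_mesh(),
                 make_mesh("icosphere", subdivisions = 2),
                 make_mesh("ellipsoid", subdivisions = 2),
                 make_mesh("cylinder", segments = 12, rings = 6))
  for (mesh in meshes) {
    g <- cotan_laplacian(mesh)
    L <- g$laplacian
    expect_true(Matrix::isSymmetric(L))
    expect_true(all(g$weights > 0))
    max_deg <- max(Matrix::diag(L))
    expect_lt(max(abs(Matrix::rowSums(L))), 1e-9 * max_deg)
    # constant vector in the null space
    expect_lt(max(abs(as.numeric(L %*% rep(1, g$n)))), 1e-9 * max_deg)
    expect_gt(min(eigen(as.matrix(L), symmetric = TRUE,
                        only.values = TRUE)$values), -1e-8)
  }
})

test_that("cotangent weights agree with an independent per-face angle sum", {
  # independent route: explicit angles via acos, cot via 1/tan, accumulated
  # edge by edge in a dense matrix
  mesh <- make_mesh("icosphere", subdivisions = 2)
  n <- nrow(mesh$vertices)
  W <- matrix(0, n, n)
  for (t in seq_len(nrow(mesh$faces))) {
    f <- mesh$faces[t, ]
    for (corner in 1:3) {
      opp <- f[-corner]
      at <- f[corner]
      u <- mesh$vertices[opp[1], ] - mesh$vertices[at, ]
      v <- mesh$vertices[opp[2], ] - mesh$vertices[at, ]
      ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
      W[opp[1], opp[2]] <- W[opp[1], opp[2]] + 0.5 / tan(ang)
      W[opp[2], opp[1]] <- W[opp[2], opp[1]] + 0.5 / tan(ang)
    }
  }
  g <- cotan_laplacian(mesh)
  got <- W[cbind(g$edges[, 1], g$edges[, 2])]
  expect_lt(max(abs(got - g$weights)), 1e-6)
})

test_that("nn_quantize assigns each vertex its nearest observed value", {
  mesh <- make_mesh("icosphere", subdivisions = 1)
  n <- nrow(mesh$vertices)
  # single observation: constant field
  one <- labeled_set(5L, -42)
  expect_equal(nn_quantize(mesh, one), rep(-42, n))
  # labelled vertices keep their own values; all outputs are observed values
  set.seed(2)
  idx <- sort(sample.int(n, 8))
  labels <- labeled_set(idx, rnorm(8, sd = 50))
  q <- nn_quantize(mesh, labels)
  expect_equal(q[idx], labels$values)
  expect_true(all(q %in% labels$values))
  # brute-force nearest-label oracle
  expected <- vapply(seq_len(n), function(i) {
    labels$values[which.min(colSums((t(mesh$vertices[idx, , drop = FALSE]) -
                                       mesh$vertices[i, ])^2))]
  }, numeric(1))
  expected[idx] <- labels$values
  expect_equal(q, expected)
})

test_that("two observations on a line quantize to a step at the midpoint", {
  mesh <- tri_mesh(cbind(0:6, 0, 0), rbind(c(1, 2, 3)))
  labels <- labeled_set(c(1L, 7L), c(0, 60))
  expect_equal(nn_quantize(mesh, labels), c(0, 0, 0, 0, 60, 60, 60))
})

test_that("edges across large quantized jumps are removed, >= boundary", {
  mesh <- tri_mesh(cbind(0:6, 0, 0), rbind(c(1, 2, 3)))
  g <- surface_graph(7, cbind(1:6, 2:7), weights = rep(1, 6))
  q60 <- c(0, 0, 0, 0, 60, 60, 60)
  s <- sparsify_edges(g, q60, delta_lat = 50)
  expect_equal(nrow(s$removed_edges), 1L)
  expect_equal(as.integer(s$removed_edges), c(4L, 5L))
  # below threshold kept; exactly at threshold removed (inequality is >=)
  expect_equal(nrow(sparsify_edges(g, q60 * 49.9 / 60, 50)$removed_edges), 0L)
  expect_equal(nrow(sparsify_edges(g, q60 * 50 / 60, 50)$removed_edges), 1L)
})

test_that("sparsification limits behave and the Laplacian stays consistent", {
  mesh <- make_mesh("icosphere", subdivisions = 2)
  g <- cotan_laplacian(mesh)
  q <- nn_quantize(mesh, labeled_set(c(1L, 80L), c(0, 200)))
  s <- sparsify_edges(g, q, delta_lat = 50)
  expect_gt(nrow(s$removed_edges), 0L)
  # removed and retained sets are disjoint
  key <- function(e) paste(e[, 1], e[, 2])
  expect_length(intersect(key(s$edges), key(s$removed_edges)), 0L)
  # operator contract survives edge removal
  max_deg <- max(Matrix::diag(s$laplacian))
  expect_lt(max(abs(Matrix::rowSums(s$laplacian))), 1e-9 * max_deg)
  expect_true(all(s$weights > 0))
  # delta = Inf is the identity; delta = 0 removes every differing edge
  expect_identical(sparsify_edges(g, q, Inf)$edges, g$edges)
  all_gone <- sparsify_edges(g, q, 0)
  differ <- q[g$edges[, 1]] != q[g$edges[, 2]]
  expect_equal(nrow(all_gone$removed_edges), sum(differ))
})
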