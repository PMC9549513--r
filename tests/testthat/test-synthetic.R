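test_that("icosphere vertex and face counts follow the closed form", {
  m0 <- make_mesh("icosphere", subdivisions = 0)
  expect_equal(nrow(m0$vertices), 12L)
  expect_equal(nrow(m0$faces), 20L)
  m2 <- make_mesh("icosphere", subdivisions = 2)
  expect_equal(nrow(m2$vertices), 10L * 4^2 + 2L)   # 162
  expect_equal(nrow(m2$faces), 20L * 4^2)
  # all vertices on the sphere of the requested radius
  expect_lt(max(abs(sqrt(rowSums(m2$vertices^2)) - 25)), 1e-9)
})

test_that("icosphere is a closed manifold; the cylinder tube is open", {
  m <- make_mesh("icosphere", subdivisions = 1)
  f <- m$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(table(key) == 2L))   # every edge in exactly 2 faces
  # consistent orientation: each directed boundary edge appears exactly once
  de <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  dkey <- paste(de[, 1], de[, 2])
  expect_false(anyDuplicated(dkey) > 0)

  cyl <- make_mesh("cylinder", segments = 10, rings = 4)
  fc <- cyl$faces
  ec <- rbind(fc[, c(1, 2)], fc[, c(2, 3)], fc[, c(1, 3)])
  kc <- paste(pmin(ec[, 1], ec[, 2]), pmax(ec[, 1], ec[, 2]))
  counts <- table(kc)
  expect_true(all(counts <= 2L))
  expect_gt(sum(counts == 1L), 0L)     # boundary edges at the open rims
})

test_that("focal activation grows with geodesic distance from the focus", {
  # equilateral triangle, side 1 mm, cv = 1 mm/ms: distances 0, 1, 1
  tri <- equilateral_mesh(side = 1)
  lat <- simulate_focal_lat(tri, focus = 1, conduction_velocity = 1)
  expect_equal(as.numeric(lat), c(0, 1, 1))
  # two-triangle strip: vertex 4 reached via an edge path
  strip <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, 1, 0), c(1.5, 1, 0)),
                    rbind(c(1, 2, 3), c(2, 4, 3)))
  lat2 <- simulate_focal_lat(strip, focus = 1, conduction_velocity = 1)
  d24 <- sqrt(sum((strip$vertices[4, ] - strip$vertices[2, ])^2))
  expect_equal(lat2[4], min(1 + d24, sqrt(1.25) + 1))
})

test_that("noise-free focal maps have their minimum at the focus", {
  mesh <- make_mesh("icosphere", subdivisions = 2)
  lat <- simulate_focal_lat(mesh, focus = 17, noise_sd = 0)
  expect_equal(which.min(lat), 17L)
  expect_equal(min(lat), 0)
  # doubling conduction velocity halves every activation time
  lat_fast <- simulate_focal_lat(mesh, focus = 17, conduction_velocity = 1.6)
  expect_equal(as.numeric(lat_fast), as.numeric(lat) / 2, tolerance = 1e-12)
})

test_that("noise realisations are seeded and deterministic", {
  mesh <- make_mesh("icosphere", subdivisions = 1)
  a <- simulate_focal_lat(mesh, focus = 1, noise_sd = 3, seed = 5)
  b <- simulate_focal_lat(mesh, focus = 1, noise_sd = 3, seed = 5)
  c_ <- simulate_focal_lat(mesh, focus = 1, noise_sd = 3, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, c_))
  expect_error(simulate_focal_lat(mesh, focus = 999), "out of range")
})

test_that("early-meets-late fields carry a super-threshold jump", {
  mesh <- make_mesh("icosphere", subdivisions = 2)
  eml <- simulate_early_meets_late(mesh, focus = 1, noise_sd = 0, seed = 1,
                                   jump_ms = 250)
  g <- mesh_graph(mesh)
  jumps <- abs(eml$values[g$edges[, 1]] - eml$values[g$edges[, 2]])
  expect_gte(max(jumps), 50)
  # brute-force count of plane-straddling edges
  expected <- sum(eml$side[g$edges[, 1]] != eml$side[g$edges[, 2]])
  expect_identical(eml$n_crossing, as.integer(expected))
  expect_gt(eml$n_crossing, 0L)

  expect_error(simulate_early_meets_late(mesh, jump_ms = 0), ">= 50")
  expect_error(simulate_early_meets_late(mesh, jump_ms = 250,
                                         plane_point = c(0, 0, 1e4)),
               "does not intersect")
})

test_that("sparsification removes boundary edges and helps the interpolant", {
  mesh <- make_mesh("icosphere", subdivisions = 3)
  eml <- simulate_early_meets_late(mesh, focus = 1, noise_sd = 3, seed = 2)
  obs <- sample_observations(mesh, eml$values, m = 250, seed = 3)
  fit <- magic_lat(mesh, obs)
  expect_gt(nrow(fit$graph$removed_edges), 0L)
})

test_that("synthetic observations are deterministic and carry their sites", {
  mesh <- make_mesh("icosphere", subdivisions = 1)
  lat <- simulate_focal_lat(mesh, focus = 1, noise_sd = 0)
  a <- sample_observations(mesh, lat, m = 20, seed = 4)
  b <- sample_observations(mesh, lat, m = 20, seed = 4)
  expect_identical(a$coords, b$coords)
  idx <- attr(a, "vertex_indices")
  expect_length(unique(idx), 20L)
  expect_equal(a$values, lat[idx], ignore_attr = TRUE)
  # jittered coordinates stay near their source vertices
  expect_lt(max(sqrt(rowSums((a$coords - mesh$vertices[idx, ])^2))), 5)
})
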