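# Shared fixtures: tiny analytic meshes, random weighted graphs, and random
# interpolation problems. Everything is generated in code under fixed seeds.

# unit-side equilateral triangle in the z = 0 plane
equilateral_mesh <- function(side = 1) {
  tri_mesh(rbind(c(0, 0, 0), c(side, 0, 0), c(side / 2, side * sqrt(3) / 2, 0)),
           rbind(c(1, 2, 3)))
}

# unit square split along the diagonal 1-3 into two right isoceles triangles
square_mesh <- function() {
  tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
           rbind(c(1, 2, 3), c(1, 3, 4)))
}

# connected random weighted graph: a random spanning tree plus extra edges
random_graph <- function(n, seed, extra = n) {
  set.seed(seed)
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  more <- unique(t(replicate(extra, sort(sample.int(n, 2L)))))
  edges <- unique(rbind(cbind(pmin(edges[, 1], edges[, 2]),
                              pmax(edges[, 1], edges[, 2])), more))
  surface_graph(n, edges, weights = stats::runif(nrow(edges), 0.1, 2))
}

# a random interpolation problem on `graph`: labelled subset + observed values
random_problem <- function(graph, seed, frac = 0.4) {
  set.seed(seed)
  n <- graph$n
  labeled <- sort(sample.int(n, max(1L, round(frac * n))))
  list(labeled = labeled, values = stats::rnorm(length(labeled), sd = 50))
}

# dense reference solve of (M_l + alpha M_u + beta L) f = f_s, kept
# independent of the package's sparse path
dense_solve_oracle <- function(graph, values, labeled, alpha, beta) {
  n <- graph$n
  L <- as.matrix(graph$laplacian)
  d <- rep(alpha, n)
  d[labeled] <- 1
  fs <- numeric(n)
  fs[labeled] <- values
  solve(diag(d) + beta * L, fs)
}
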