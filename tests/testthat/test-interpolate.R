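test_that("fully labelled problems with beta = 0 are reproduced exactly", {
  g <- random_graph(30, seed = 1)
  vals <- rnorm(30, sd = 40)
  expect_equal(magic_lat_solve(g, vals, 1:30, alpha = 1e-5, beta = 0), vals)
})

test_that("the two-vertex problem matches the dense closed form", {
  g <- surface_graph(2, rbind(c(1, 2)), weights = 1)
  f <- magic_lat_solve(g, 10, labeled = 1)
  # dense 2x2 oracle: solve([[1.01, -0.01], [-0.01, 0.01001]], [10, 0])
  oracle <- solve(matrix(c(1.01, -0.01, -0.01, 1e-5 + 0.01), 2, 2), c(10, 0))
  expect_equal(f, oracle, tolerance = 1e-12)
  expect_equal(f, c(9.99990, 9.98991), tolerance = 1e-6)
})

test_that("zero input yields zero output and the solve is linear in f_s", {
  g <- random_graph(60, seed = 2)
  p <- random_problem(g, seed = 3)
  zero <- magic_lat_solve(g, rep(0, length(p$labeled)), p$labeled)
  expect_equal(zero, rep(0, 60))
  u <- rnorm(length(p$labeled)); v <- rnorm(length(p$labeled))
  lhs <- magic_lat_solve(g, 2 * u - 3 * v, p$labeled)
  rhs <- 2 * magic_lat_solve(g, u, p$labeled) -
    3 * magic_lat_solve(g, v, p$labeled)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)
})

test_that("the system matrix is SPD with smallest eigenvalue >= min(1, alpha)", {
  for (seed in 1:5) {
    g <- random_graph(40, seed = seed)
    alpha <- 10^runif(1, -5, 0)
    A <- diag(ifelse(seq_len(40) %in% random_problem(g, seed)$labeled,
                     1, alpha)) + 1e-2 * as.matrix(g$laplacian)
    ev <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), min(1, alpha) - 1e-10)
  }
})

test_that("sparse solves match the dense oracle on random graphs", {
  for (seed in 1:10) {
    g <- random_graph(sample(20:120, 1), seed = seed)
    p <- random_problem(g, seed = seed + 100)
    f <- magic_lat_solve(g, p$values, p$labeled)
    oracle <- dense_solve_oracle(g, p$values, p$labeled, 1e-5, 1e-2)
    expect_lt(max(abs(f - oracle)) / max(abs(oracle)), 1e-9)
  }
})

test_that("spectral filtering reduces to the identity and the DC gain", {
  g <- random_graph(25, seed = 4)
  dec <- laplacian_eigen(g)
  expect_lt(max(abs(dec$values[1])), 1e-8)            # lambda_1 = 0
  expect_lt(max(abs(crossprod(dec$vectors) - diag(25))), 1e-8)
  fs <- rnorm(25)
  expect_equal(spectral_interpolate(dec, fs, function(l) 1), fs,
               tolerance = 1e-9)
  # constant fully-labelled signal lives on the lambda = 0 eigenvector
  const <- rep(7, 25)
  out <- spectral_interpolate(dec, const, function(l) exp(-l))
  expect_equal(out, const, tolerance = 1e-8)
})

test_that("for alpha = beta = 1 the solve is the 1/(1+lambda) graph filter", {
  for (seed in 1:5) {
    g <- random_graph(sample(20:150, 1), seed = seed + 30)
    p <- random_problem(g, seed = seed + 60)
    fs <- numeric(g$n); fs[p$labeled] <- p$values
    direct <- magic_lat_solve(g, p$values, p$labeled, alpha = 1, beta = 1)
    filtered <- spectral_interpolate(laplacian_eigen(g), fs,
                                     function(l) 1 / (1 + l))
    expect_lt(max(abs(direct - filtered)) / max(abs(direct)), 1e-6)
  }
})

test_that("GPR reproduces training data and decays to the prior mean", {
  set.seed(5)
  x <- matrix(runif(30), 10, 3)
  y <- rnorm(10, sd = 30)
  pred <- gpr_baseline(x, y, x, jitter = 1e-12, rescale = FALSE)
  expect_lt(max(abs(pred - y)), 1e-4)
  far <- matrix(rep(1e3, 3), 1, 3)
  expect_lt(abs(gpr_baseline(x, y, far, rescale = FALSE)),
            1e-6 * max(abs(y)))
})

test_that("single-point GPR matches the closed-form posterior", {
  x <- matrix(c(0, 0, 0), 1, 3)
  xq <- matrix(c(0.05, 0, 0), 1, 3)
  y <- 12
  jitter <- 1e-8
  k <- function(a, b) sum(exp(-sum((a - b)^2) / (2 * c(0.01, 0.1, 1)^2)))
  expected <- y * k(xq, x) / (k(x, x) + jitter)
  expect_equal(gpr_baseline(x, y, xq, jitter = jitter, rescale = FALSE),
               expected, tolerance = 1e-10)
})

test_that("duplicate training coordinates are rejected with advice", {
  x <- matrix(0, 2, 3)
  expect_error(gpr_baseline(x, c(1, 2), x), "merge")
})

test_that("too little smoothing hurts far more than extra smoothing", {
  # on a smooth focal map, dropping beta to 1e-5 (nearly unregularised
  # unlabelled vertices collapse towards 0) raises MDE much more than
  # raising beta to 1 (mild oversmoothing) changes it
  mesh <- make_mesh("icosphere", subdivisions = 3)
  truth <- simulate_focal_lat(mesh, focus = 1, noise_sd = 3, seed = 9)
  obs <- sample_observations(mesh, truth, m = 200, seed = 10)
  mde_for <- function(beta) {
    r <- crossval(mesh, obs, m = 100, reps = 10, methods = "magic",
                  seed = 42, beta = beta)
    r$summary$mde_mean
  }
  base <- mde_for(1e-2)
  rise_small_beta <- mde_for(1e-5) - base
  shift_large_beta <- abs(mde_for(1) - base)
  expect_gt(rise_small_beta, shift_large_beta)
})
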