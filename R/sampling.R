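# Clinically motivated non-uniform sub-sampling of LAT observations.
# A mapping technician densely samples mid-to-early activation while hunting
# for the earliest site, but every region keeps a non-trivial chance of being
# probed. The protocol: shift values non-negative, place the probability peak
# at x' = x_min + lambda1 * x_avg, decrease linearly with distance from x'
# (slope lambda2, minimum score 1), floor the scores to integer repetition
# counts, and normalise.

#' Construct the sub-sampling distribution over observations
#'
#' @param values observed LAT values (ms).
#' @param lambda1 position of the probability peak between the earliest
#'   (`0`) and the mean (`1`) activation value; default 0.5.
#' @param lambda2 per-ms slope of the linear decay away from the peak;
#'   default 0.25. Small values keep all probabilities non-trivial.
#' @return An object of class `sampling_distribution`: shifted values `x`,
#'   peak `x_peak`, distances `d`, `d_max`, raw scores `r` (all >= 1),
#'   integer repetitions `f` (all >= 1) and probabilities `p` (sum 1).
#' @examples
#' sd <- sampling_distribution(c(0, 10, 20, 30))
#' sd$p   # 4/14, 6/14, 3/14, 1/14
#' @export
sampling_distribution <- function(values, lambda1 = 0.5, lambda2 = 0.25) {
  if (!length(values)) stop("at least one value is required")
  if (lambda1 < 0 || lambda2 < 0) stop("lambda1 and lambda2 must be >= 0")
  x <- if (min(values) < 0) values + abs(min(values)) else values
  x_peak <- min(x) + lambda1 * mean(x)
  d <- abs(x - x_peak)
  d_max <- max(d)
  r <- lambda2 * (d_max - d) + 1
  f <- floor(r)
  p <- f / sum(f)
  structure(list(x = x, x_peak = x_peak, d = d, d_max = d_max, r = r,
                 f = f, p = p, lambda1 = lambda1, lambda2 = lambda2),
            class = "sampling_distribution")
}

#' @method print sampling_distribution
#' @export
print.sampling_distribution <- function(x, ...) {
  cat(sprintf("Sub-sampling distribution over %d observations (lambda1 = %g, lambda2 = %g)\n",
              length(x$p), x$lambda1, x$lambda2))
  cat(sprintf("  peak at shifted LAT %.1f ms; p in [%.4f, %.4f]\n",
              x$x_peak, min(x$p), max(x$p)))
  invisible(x)
}

# evaluate `expr` under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Draw a reproducible subset of observations
#'
#' Draws `m` distinct observation indices without replacement, each draw
#' proportional to the remaining integer repetition counts `f` of the
#' distribution. Identical `(seed, dist, m)` give identical subsets; the
#' global RNG state is left untouched.
#'
#' @param dist a [sampling_distribution()].
#' @param m subset size, `1 <= m <= length(dist$p)`.
#' @param seed integer seed.
#' @return Integer vector of `m` distinct 1-based observation indices.
#' @export
draw_subset <- function(dist, m, seed) {
  n_obs <- length(dist$p)
  if (m < 1L || m > n_obs) {
    stop(sprintf("m must be in [1, %d]", n_obs))
  }
  with_seed(seed, sample.int(n_obs, size = m, replace = FALSE,
                             prob = dist$f))
}
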