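# Cross-validation with random selection and repetition: per repetition a
# training subset of the usable observations is drawn with the clinical
# sub-sampling protocol, each method interpolates from the identical subset,
# and MDE/NMSE are scored on the held-out complement.

#' Cross-validate interpolation methods on one map
#'
#' Pre-processing (snapping, optional anomaly rejection) runs once, before
#' any repetition, yielding the usable observation set V_S. Per repetition
#' `r`, `m` training vertices are drawn (seed `seed + r`) from the
#' [sampling_distribution()] over V_S values; every requested method is fit
#' on the identical training subset and scored on the complement with
#' [mde()] (over a fixed map-wide color range) and [nmse()].
#'
#' @param mesh a [tri_mesh()].
#' @param samples a [lat_samples()] or [labeled_set()].
#' @param m training-subset size, `< |V_S|`.
#' @param reps number of random repetitions (default 50).
#' @param methods subset of `c("magic", "gpr")`.
#' @param seed base seed; repetition r uses `seed + r`.
#' @param alpha,beta,delta_lat interpolation parameters (see
#'   [magic_lat_solve()], [sparsify_edges()]).
#' @param lambda1,lambda2 sub-sampling protocol parameters.
#' @param range colormap range for MDE; default the min/max of the V_S
#'   values, fixed across repetitions.
#' @param filter_anomalies run [remove_anomalous()] during pre-processing
#'   (default TRUE).
#' @param verbose log per-repetition seeds, graph sizes and removed-edge
#'   counts via [message()].
#' @return An object of class `lat_crossval`: `per_rep` (data frame of rep,
#'   seed, method, mde, nmse), `summary` (per-method mean/sd), `subsets`
#'   (per-repetition training positions into the labelled set), `labeled`
#'   (the post-preprocessing [labeled_set()]), `meta`.
#' @export
crossval <- function(mesh, samples, m, reps = 50,
                     methods = c("magic", "gpr"), seed = 1, alpha = 1e-5,
                     beta = 1e-2, delta_lat = 50, lambda1 = 0.5,
                     lambda2 = 0.25, range = NULL, filter_anomalies = TRUE,
                     verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  labeled <- if (inherits(samples, "labeled_set")) samples
             else snap_to_vertices(mesh, samples)
  if (filter_anomalies) labeled <- remove_anomalous(labeled, mesh)
  n_s <- length(labeled$values)
  if (m >= n_s) {
    stop(sprintf("m = %d must be smaller than |V_S| = %d", m, n_s))
  }
  if (is.null(range)) range <- base::range(labeled$values)
  graph0 <- cotan_laplacian(mesh)
  dist <- sampling_distribution(labeled$values, lambda1, lambda2)
  coords_s <- mesh$vertices[labeled$vertex_indices, , drop = FALSE]
  rows <- vector("list", reps * length(methods))
  subsets <- vector("list", reps)
  ri <- 0L
  for (r in seq_len(reps)) {
    seed_r <- seed + r
    train_pos <- sort(draw_subset(dist, m, seed_r))
    subsets[[r]] <- train_pos
    test_pos <- setdiff(seq_len(n_s), train_pos)
    truth <- labeled$values[test_pos]
    for (method in methods) {
      if (method == "magic") {
        train_set <- labeled_set(labeled$vertex_indices[train_pos],
                                 labeled$values[train_pos])
        q <- nn_quantize(mesh, train_set)
        graph <- sparsify_edges(graph0, q, delta_lat = delta_lat)
        f <- magic_lat_solve(graph, train_set$values,
                             train_set$vertex_indices,
                             alpha = alpha, beta = beta)
        pred <- f[labeled$vertex_indices[test_pos]]
        if (verbose) {
          message(sprintf("rep %d seed %d magic: n=%d, removed %d edges",
                          r, seed_r, graph$n, nrow(graph$removed_edges)))
        }
      } else {
        pred <- gpr_baseline(coords_s[train_pos, , drop = FALSE],
                             labeled$values[train_pos],
                             coords_s[test_pos, , drop = FALSE])
        if (verbose) {
          message(sprintf("rep %d seed %d gpr: m=%d train points",
                          r, seed_r, m))
        }
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(rep = r, seed = seed_r, method = method,
                               mde = mde(pred, truth, range),
                               nmse = nmse(pred, truth))
    }
  }
  per_rep <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_rep, per_rep$method), function(d) {
    data.frame(method = d$method[1], mde_mean = mean(d$mde),
               mde_sd = stats::sd(d$mde), nmse_mean = mean(d$nmse),
               nmse_sd = stats::sd(d$nmse))
  }))
  rownames(summ) <- NULL
  structure(list(per_rep = per_rep, summary = summ, subsets = subsets,
                 labeled = labeled,
                 meta = list(m = m, reps = reps, methods = methods,
                             seed = seed, alpha = alpha, beta = beta,
                             delta_lat = delta_lat, lambda1 = lambda1,
                             lambda2 = lambda2, range = range,
                             n_vertices = nrow(mesh$vertices),
                             n_labeled = n_s)),
            class = "lat_crossval")
}

#' @method print lat_crossval
#' @export
print.lat_crossval <- function(x, ...) {
  cat(sprintf("Cross-validation: m = %d of %d observations, %d repetitions\n",
              x$meta$m, x$meta$n_labeled, x$meta$reps))
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %-5s MDE %.3f +/- %.3f   NMSE %.4f +/- %.4f\n",
                s$method, s$mde_mean, s$mde_sd, s$nmse_mean, s$nmse_sd))
  }
  invisible(x)
}

#' Serialise a cross-validation result to JSON
#'
#' Deterministic (no timestamps, fixed significant digits): identical inputs
#' and seed give a byte-identical string.
#'
#' @param result a [crossval()] result.
#' @param path optional file to write to.
#' @return The JSON string, invisibly if `path` is given.
#' @export
crossval_json <- function(result, path = NULL) {
  json <- jsonlite::toJSON(list(meta = result$meta, summary = result$summary,
                                per_rep = result$per_rep),
                           dataframe = "columns", auto_unbox = TRUE,
                           digits = I(15), pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Sweep the training-subset size
#'
#' Repeats [crossval()] for each entry of `m_values`. Each entry gets its own
#' deterministic seed stream derived from the base seed by position, so
#' duplicated m values produce independent draws.
#'
#' @inheritParams crossval
#' @param m_values integer vector of training sizes.
#' @param ... passed on to [crossval()].
#' @return List of `lat_crossval` results, one per entry of `m_values`.
#' @export
sweep_m <- function(mesh, samples, m_values, reps = 25,
                    methods = "magic", seed = 1, ...) {
  out <- vector("list", length(m_values))
  for (i in seq_along(m_values)) {
    out[[i]] <- crossval(mesh, samples, m = m_values[i], reps = reps,
                         methods = methods, seed = seed + (i - 1L) * 1009L,
                         ...)
  }
  if (length(m_values)) names(out) <- paste0("m", m_values)
  out
}
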