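#' Mean silhouette score of a clustering
#'
#' For each point i, `S(i) = (b(i) - a(i)) / max(a(i), b(i))`, where
#' `a(i)` is the mean Euclidean distance to the other members of its
#' cluster (excluding itself) and `b(i)` is the smallest mean distance to
#' any other cluster. Points in singleton clusters score 0. Noise points
#' (label -1) are excluded from the computation. Returns the mean over
#' scored points, or `NA` when fewer than two clusters remain after
#' removing noise (an undefined score, not an error).
#'
#' @param points numeric matrix, one point per row.
#' @param labels integer cluster labels (-1 = noise).
#' @return mean silhouette in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
silhouette_score <- function(points, labels) {
  points <- rbind(points)
  stopifnot(nrow(points) == length(labels))
  keep <- labels != -1L
  if (sum(keep) == 0L) return(NA_real_)
  X <- points[keep, , drop = FALSE]
  lb <- labels[keep]
  cl <- sort(unique(lb))
  if (length(cl) < 2L) return(NA_real_)
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  s <- numeric(n)
  sizes <- table(factor(lb, levels = cl))
  # mean distance from every point to every cluster
  md <- sapply(cl, function(c0) rowSums(D[, lb == c0, drop = FALSE]))
  for (i in seq_len(n)) {
    own <- match(lb[i], cl)
    ni <- sizes[[own]]
    if (ni == 1L) { s[i] <- 0; next }
    a <- md[i, own] / (ni - 1L)
    b <- min(md[i, -own] / as.numeric(sizes[-own]))
    s[i] <- if (a == b) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Cluster pooled embeddings
#'
#' Runs the density-based clustering on a pooled-embedding matrix with
#' the parameters passed through verbatim.
#'
#' @param pooled numeric matrix of pooled embeddings (rows = sequences).
#' @param params a [density_cluster_params()].
#' @return integer labels, -1 for noise.
#' @export
cluster_embeddings <- function(pooled, params = density_cluster_params()) {
  hdbscan_cluster(pooled, params)
}

#' Bootstrap configuration for the clustering benchmark
#'
#' @param iterations number of bootstrap iterations (the full-scale
#'   protocol uses 1,000).
#' @param groups_per_iteration orthologous groups sampled per iteration
#'   without replacement (full-scale: 500), each contributing all its
#'   sequences.
#' @param seed base seed; iteration i samples under `seed + i`.
#' @return object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(iterations = 1000L,
                             groups_per_iteration = 500L, seed = 1L) {
  stopifnot(iterations >= 1, groups_per_iteration >= 1)
  structure(list(iterations = as.integer(iterations),
                 groups_per_iteration = as.integer(groups_per_iteration),
                 seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Bootstrap clustering benchmark with silhouette scoring
#'
#' Per iteration: sample `groups_per_iteration` orthologous groups
#' without replacement, take all their member sequences, cluster the
#' pooled embeddings, and score the clustering with the mean silhouette.
#' Iterations whose clustering yields fewer than two clusters are
#' recorded as undefined and excluded from the summary maximum, which
#' serves as the best-case metric for comparing encoders.
#'
#' @param data an [ortholog_group_set()].
#' @param pooled pooled-embedding matrix covering all sequence ids.
#' @param boot a [bootstrap_config()]; `groups_per_iteration` must not
#'   exceed the number of available groups.
#' @param params a [density_cluster_params()].
#' @return object of class `clustering_report`: `per_iteration_scores`
#'   (NA where undefined), `max_score`, `n_defined`, `skipped` (count of
#'   undefined iterations with reasons).
#' @export
bootstrap_cluster_silhouette <- function(data, pooled, boot,
                                         params = density_cluster_params()) {
  stopifnot(inherits(data, "ortholog_group_set"),
            inherits(boot, "bootstrap_config"))
  gnames <- names(data$groups)
  if (boot$groups_per_iteration > length(gnames))
    stop("groups_per_iteration exceeds the number of available groups")
  missing <- setdiff(names(data$records), rownames(pooled))
  if (length(missing))
    stop("missing pooled embeddings for ",
         paste(utils::head(missing, 5L), collapse = ", "))
  scores <- rep(NA_real_, boot$iterations)
  reasons <- character(0)
  for (i in seq_len(boot$iterations)) {
    gs <- with_seed(boot$seed + i,
                    sample(gnames, boot$groups_per_iteration))
    ids <- unlist(data$groups[gs], use.names = FALSE)
    X <- pooled[ids, , drop = FALSE]
    lab <- tryCatch(cluster_embeddings(X, params), error = function(e) e)
    if (inherits(lab, "error")) {
      reasons <- c(reasons, sprintf("iteration %d: %s", i,
                                    conditionMessage(lab)))
      next
    }
    s <- silhouette_score(X, lab)
    if (is.na(s))
      reasons <- c(reasons,
                   sprintf("iteration %d: fewer than 2 clusters", i))
    scores[i] <- s
  }
  defined <- scores[!is.na(scores)]
  structure(list(per_iteration_scores = scores,
                 max_score = if (length(defined)) max(defined) else NA_real_,
                 n_defined = length(defined),
                 skipped = list(count = sum(is.na(scores)),
                                reasons = reasons)),
            class = "clustering_report")
}

#' @export
print.clustering_report <- function(x, ...) {
  cat(sprintf("<clustering_report> %d iterations (%d defined), max silhouette %.4f\n",
              length(x$per_iteration_scores), x$n_defined, x$max_score))
  invisible(x)
}
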