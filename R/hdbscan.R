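#' Density-clustering parameters
#'
#' Parameters of the hierarchical density-based clustering (HDBSCAN*)
#' used on pooled embeddings. Defaults are the settings used for
#' clustering pooled protein embeddings: min_cluster_size = 10,
#' min_samples = 5, selection epsilon = 1.0, alpha = 1.0.
#'
#' @param min_cluster_size smallest group of points treated as a cluster
#'   (>= 2).
#' @param min_samples neighborhood size k for the core distance (distance
#'   to the k-th nearest neighbor, the point itself counted first).
#' @param selection_epsilon cluster-selection epsilon: selected clusters
#'   born below this mutual-reachability distance are merged into their
#'   first ancestor born at or above it.
#' @param alpha distance scaling; distances are divided by `alpha` before
#'   computing mutual reachability.
#' @return object of class `density_cluster_params`.
#' @export
density_cluster_params <- function(min_cluster_size = 10L, min_samples = 5L,
                                   selection_epsilon = 1.0, alpha = 1.0) {
  stopifnot(min_cluster_size >= 2, min_samples >= 1,
            selection_epsilon >= 0, alpha > 0)
  structure(list(min_cluster_size = as.integer(min_cluster_size),
                 min_samples = as.integer(min_samples),
                 selection_epsilon = selection_epsilon, alpha = alpha),
            class = "density_cluster_params")
}

# Prim's algorithm MST on a dense symmetric weight matrix.
# Returns data.frame(from, to, w) with n-1 edges.
dense_mst <- function(W) {
  n <- nrow(W)
  in_tree <- logical(n)
  best <- rep(Inf, n)
  best_from <- integer(n)
  in_tree[1L] <- TRUE
  best <- W[1L, ]
  best_from[] <- 1L
  best[1L] <- Inf
  edges <- matrix(0, n - 1L, 3L)
  for (k in seq_len(n - 1L)) {
    j <- which.min(replace(best, in_tree, Inf))
    edges[k, ] <- c(best_from[j], j, best[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & W[j, ] < best
    best_from[upd] <- j
    best[upd] <- W[j, upd]
  }
  data.frame(from = as.integer(edges[, 1L]), to = as.integer(edges[, 2L]),
             w = edges[, 3L])
}

#' Hierarchical density-based clustering (HDBSCAN*)
#'
#' Native implementation of the HDBSCAN* pipeline: core distances at
#' `min_samples`, mutual-reachability distances, a minimum spanning tree,
#' the condensed cluster tree at `min_cluster_size`, and excess-of-mass
#' cluster selection with the epsilon merge rule. Points not falling
#' inside any selected cluster are labeled noise (-1).
#'
#' @param X numeric matrix, one point per row (Euclidean distances).
#' @param params a [density_cluster_params()].
#' @return integer label vector: -1 for noise, 0, 1, ... for clusters.
#' @export
hdbscan_cluster <- function(X, params = density_cluster_params()) {
  stopifnot(inherits(params, "density_cluster_params"))
  X <- rbind(X)
  n <- nrow(X)
  if (n < params$min_cluster_size)
    stop(sprintf("need at least min_cluster_size = %d points, got %d",
                 params$min_cluster_size, n))
  if (params$min_samples > n)
    stop("min_samples exceeds the number of points")
  D <- as.matrix(stats::dist(X)) / params$alpha
  core <- apply(D, 1L, function(r) sort(r)[params$min_samples])
  MR <- pmax(D, outer(core, core, pmax))
  mst <- dense_mst(MR)
  mst <- mst[order(mst$w, mst$from, mst$to), ]

  # single-linkage dendrogram via union-find; internal nodes n+1 .. 2n-1
  parent <- integer(2L * n - 1L)        # union-find forest roots
  node_of <- seq_len(n)                 # current dendrogram node per root
  uf_find <- function(x) {
    while (parent[x] != 0L) x <- parent[x]
    x
  }
  n_nodes <- 2L * n - 1L
  left <- integer(n_nodes); right <- integer(n_nodes)
  ndist <- numeric(n_nodes); nsize <- integer(n_nodes)
  nsize[seq_len(n)] <- 1L
  nxt <- n
  for (k in seq_len(nrow(mst))) {
    ra <- uf_find(mst$from[k]); rb <- uf_find(mst$to[k])
    nxt <- nxt + 1L
    left[nxt] <- node_of[ra]; right[nxt] <- node_of[rb]
    ndist[nxt] <- mst$w[k]
    nsize[nxt] <- nsize[node_of[ra]] + nsize[node_of[rb]]
    parent[ra] <- nxt; parent[rb] <- nxt
    parent[nxt] <- 0L
    node_of[nxt] <- nxt
  }
  root <- nxt

  leaves_under <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack)) {
      nd <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (nd <= n) out <- c(out, nd)
      else stack <- c(stack, left[nd], right[nd])
    }
    out
  }
  lam <- function(d) 1 / max(d, 1e-12)

  # condensed tree
  mcs <- params$min_cluster_size
  cl_parent <- integer(0); cl_birth <- numeric(0)
  point_cluster <- integer(n); point_lambda <- numeric(n)
  new_cluster <- function(par, birth) {
    cl_parent[length(cl_parent) + 1L] <<- par
    cl_birth[length(cl_birth) + 1L] <<- birth
    length(cl_parent)
  }
  root_cl <- new_cluster(0L, lam(ndist[root]))
  # stack entries: (dendrogram node, condensed cluster id)
  stack <- list(c(root, root_cl))
  while (length(stack)) {
    ent <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    node <- ent[1L]; cl <- ent[2L]
    repeat {
      if (node <= n) {  # singleton remnant falls out at its own lambda
        point_cluster[node] <- cl
        point_lambda[node] <- lam(ndist[node])  # unreachable; guard below
        break
      }
      l <- left[node]; r <- right[node]
      la <- lam(ndist[node])
      sl <- nsize[l]; sr <- nsize[r]
      if (sl >= mcs && sr >= mcs) {
        cl_l <- new_cluster(cl, la)
        cl_r <- new_cluster(cl, la)
        stack[[length(stack) + 1L]] <- c(l, cl_l)
        node <- r; cl <- cl_r
      } else if (sl < mcs && sr < mcs) {
        for (p in leaves_under(node)) {
          point_cluster[p] <- cl
          point_lambda[p] <- la
        }
        break
      } else {
        small <- if (sl < mcs) l else r
        big <- if (sl < mcs) r else l
        for (p in leaves_under(small)) {
          point_cluster[p] <- cl
          point_lambda[p] <- la
        }
        node <- big
      }
    }
  }

  n_cl <- length(cl_parent)
  # stability: every departure from cluster C contributes
  # size * (lambda_leave - lambda_birth)
  stability <- numeric(n_cl)
  for (p in seq_len(n)) {
    c0 <- point_cluster[p]
    stability[c0] <- stability[c0] + (point_lambda[p] - cl_birth[c0])
  }
  children <- split(seq_len(n_cl)[-1L], cl_parent[-1L])
  # cluster point counts (points that ever belong to the subtree)
  cl_size <- integer(n_cl)
  for (p in seq_len(n)) {
    c0 <- point_cluster[p]
    while (c0 != 0L) { cl_size[c0] <- cl_size[c0] + 1L; c0 <- cl_parent[c0] }
  }
  for (c0 in seq_len(n_cl)[-1L]) {
    par <- cl_parent[c0]
    stability[par] <- stability[par] +
      cl_size[c0] * (cl_birth[c0] - cl_birth[par])
  }

  # excess-of-mass selection (root excluded)
  selected <- logical(n_cl)
  value <- numeric(n_cl)
  kids_of <- function(c0) {
    k <- children[[as.character(c0)]]
    if (is.null(k)) integer(0) else k
  }
  for (c0 in rev(seq_len(n_cl))) {
    if (c0 == root_cl) next
    k <- kids_of(c0)
    if (!length(k)) {
      selected[c0] <- TRUE
      value[c0] <- stability[c0]
    } else if (stability[c0] >= sum(value[k])) {
      selected[c0] <- TRUE
      value[c0] <- stability[c0]
    } else {
      value[c0] <- sum(value[k])
    }
  }
  # enforce the antichain: drop selections with a selected proper ancestor
  anc_selected <- function(c0) {
    c0 <- cl_parent[c0]
    while (c0 != 0L) {
      if (selected[c0]) return(TRUE)
      c0 <- cl_parent[c0]
    }
    FALSE
  }
  for (c0 in seq_len(n_cl)) {
    if (selected[c0] && anc_selected(c0)) selected[c0] <- FALSE
  }

  # epsilon merge: selected clusters born below the epsilon distance are
  # replaced by their first ancestor born at or above it (root excluded)
  if (params$selection_epsilon > 0) {
    eps <- params$selection_epsilon
    chosen <- which(selected)
    for (c0 in chosen) {
      if (!selected[c0]) next
      if (1 / cl_birth[c0] < eps) {
        up <- cl_parent[c0]
        target <- 0L
        while (up != 0L && up != root_cl) {
          if (1 / cl_birth[up] >= eps) { target <- up; break }
          up <- cl_parent[up]
        }
        if (target != 0L) {
          # deselect everything under the target, select the target
          for (cc in seq_len(n_cl)) {
            if (selected[cc]) {
              a <- cc
              while (a != 0L) {
                if (a == target) { selected[cc] <- FALSE; break }
                a <- cl_parent[a]
              }
            }
          }
          selected[target] <- TRUE
        }
      }
    }
  }

  final <- which(selected)
  labels <- rep(-1L, n)
  if (length(final)) {
    lab_of <- integer(n_cl)
    lab_of[final] <- seq_along(final) - 1L
    for (p in seq_len(n)) {
      c0 <- point_cluster[p]
      while (c0 != 0L) {
        if (selected[c0]) { labels[p] <- lab_of[c0]; break }
        c0 <- cl_parent[c0]
      }
    }
  }
  labels
}
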