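# Hierarchical density-based clustering (HDBSCAN): core distances and the
# mutual-reachability minimum spanning tree are computed in C++; the
# single-linkage hierarchy, condensed tree, cluster stabilities and
# excess-of-mass cluster extraction follow the Campello et al. algorithm.
# Points not inside any selected cluster are labeled -1 (noise/transition).

#' HDBSCAN clustering
#'
#' @param X Numeric matrix of points (rows) to cluster with Euclidean
#'   distances.
#' @param min_cluster_size Smallest number of points that can form a
#'   cluster (>= 2).
#' @param min_samples Neighbourhood size for the core distance (defaults
#'   to `min_cluster_size`).
#' @param allow_single_cluster Whether the hierarchy root may be selected
#'   as a cluster (default `FALSE`, the standard behaviour).
#' @return Integer vector of labels per row: `0 .. K-1` for clusters,
#'   `-1` for noise.
#' @export
hdbscan_labels <- function(X, min_cluster_size, min_samples = NULL,
                           allow_single_cluster = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  min_cluster_size <- as.integer(min_cluster_size)
  if (min_cluster_size < 2L) stop("min_cluster_size must be >= 2")
  if (is.null(min_samples)) min_samples <- min_cluster_size
  min_samples <- min(as.integer(min_samples), n)
  if (n < min_cluster_size) return(rep(-1L, n))

  core <- .core_distances(X, min_samples)
  mst <- .mutual_reachability_mst(X, core)
  o <- order(mst$weight)
  efrom <- mst$from[o]; eto <- mst$to[o]; ew <- mst$weight[o]

  # single-linkage hierarchy from the sorted MST edges (union-find);
  # nodes 1..n are points, n+e is the component created by edge e
  n_nodes <- 2L * n - 1L
  ufp <- seq_len(n_nodes)
  find_root <- function(x) {
    while (ufp[x] != x) {
      ufp[x] <<- ufp[ufp[x]]
      x <- ufp[x]
    }
    x
  }
  child1 <- integer(n - 1L); child2 <- integer(n - 1L)
  height <- numeric(n - 1L)
  size <- c(rep(1L, n), integer(n - 1L))
  for (e in seq_len(n - 1L)) {
    a <- find_root(efrom[e]); b <- find_root(eto[e])
    node <- n + e
    child1[e] <- a; child2[e] <- b; height[e] <- ew[e]
    size[node] <- size[a] + size[b]
    ufp[a] <- node; ufp[b] <- node
  }

  # condensed tree: walk from the root; a child component smaller than
  # min_cluster_size "falls out" of the current cluster at the split's
  # lambda = 1/distance, a split into two large children creates two new
  # clusters
  mcs <- min_cluster_size
  lam_of <- function(h) 1 / max(h, 1e-300)
  max_rows <- n + 2L * n
  row_parent <- integer(max_rows); row_child <- integer(max_rows)
  row_lambda <- numeric(max_rows); row_size <- integer(max_rows)
  n_row <- 0L
  add_row <- function(p, ch, lam, sz) {
    n_row <<- n_row + 1L
    row_parent[n_row] <<- p; row_child[n_row] <<- ch
    row_lambda[n_row] <<- lam; row_size[n_row] <<- sz
  }
  leaves_of <- function(node) {
    out <- integer(size[node]); n_out <- 0L
    stack <- node
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v <= n) {
        n_out <- n_out + 1L; out[n_out] <- v
      } else {
        e <- v - n
        stack <- c(stack, child1[e], child2[e])
      }
    }
    out
  }
  n_cl <- 1L
  cl_parent <- 0L; cl_birth <- 0
  relabel <- integer(n_nodes)
  root <- n_nodes
  relabel[root] <- 1L
  stack <- root
  while (length(stack)) {
    node <- stack[length(stack)]; stack <- stack[-length(stack)]
    e <- node - n
    L <- child1[e]; R <- child2[e]
    lam <- lam_of(height[e])
    cur <- relabel[node]
    sL <- size[L]; sR <- size[R]
    bigL <- sL >= mcs; bigR <- sR >= mcs
    if (bigL && bigR) {
      for (ch in c(L, R)) {
        n_cl <- n_cl + 1L
        cl_parent <- c(cl_parent, cur)
        cl_birth <- c(cl_birth, lam)
        add_row(cur, -n_cl, lam, size[ch])
        relabel[ch] <- n_cl
        stack <- c(stack, ch)   # ch >= mcs >= 2 so it is internal
      }
    } else if (!bigL && !bigR) {
      for (p in leaves_of(L)) add_row(cur, p, lam, 1L)
      for (p in leaves_of(R)) add_row(cur, p, lam, 1L)
    } else {
      big <- if (bigL) L else R
      small <- if (bigL) R else L
      for (p in leaves_of(small)) add_row(cur, p, lam, 1L)
      relabel[big] <- cur
      if (big > n) stack <- c(stack, big) else add_row(cur, big, lam, 1L)
    }
  }
  row_parent <- row_parent[seq_len(n_row)]
  row_child <- row_child[seq_len(n_row)]
  row_lambda <- row_lambda[seq_len(n_row)]
  row_size <- row_size[seq_len(n_row)]

  # stability of each condensed cluster
  contrib <- (row_lambda - cl_birth[row_parent]) * row_size
  stab <- numeric(n_cl)
  agg <- tapply(contrib, row_parent, sum)
  stab[as.integer(names(agg))] <- as.numeric(agg)

  # excess-of-mass selection, children before parents (ids increase
  # downward); a selected cluster deselects all its descendants
  selected <- logical(n_cl)
  kids <- lapply(seq_len(n_cl), function(c) which(cl_parent == c))
  if (n_cl > 1L) {
    for (cl in n_cl:2L) {
      ch <- kids[[cl]]
      sub <- sum(stab[ch])
      if (length(ch) && stab[cl] < sub) {
        stab[cl] <- sub
        selected[cl] <- FALSE
      } else {
        selected[cl] <- TRUE
        desc <- ch
        while (length(desc)) {
          selected[desc] <- FALSE
          desc <- unlist(kids[desc])
        }
      }
    }
  }
  if (allow_single_cluster && !any(selected)) selected[1L] <- TRUE

  # point labels: climb from the point's direct cluster to the first
  # selected ancestor
  sel_ids <- which(selected)
  label_of_cluster <- rep(-1L, n_cl)
  label_of_cluster[sel_ids] <- seq_along(sel_ids) - 1L
  climb <- function(cl) {
    while (cl > 0L && !selected[cl]) cl <- cl_parent[cl]
    if (cl > 0L) label_of_cluster[cl] else -1L
  }
  ancestor_label <- vapply(seq_len(n_cl), climb, integer(1L))
  labels <- rep(-1L, n)
  pt <- row_child > 0L
  labels[row_child[pt]] <- ancestor_label[row_parent[pt]]
  # points recorded as cluster rows only (child < 0) inherit through the
  # cluster they seed; every point appears exactly once as child > 0, so
  # nothing else to do
  labels
}
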