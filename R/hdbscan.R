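#' Hierarchical density-based clustering with outlier marking (HDBSCAN)
#'
#' Implements the HDBSCAN algorithm: (1) transform the metric space by the
#' mutual reachability distance `d_mreach(a, b) = max(core_k(a), core_k(b),
#' d(a, b))`, where `core_k(x)` is the distance from `x` to its k-th nearest
#' neighbor (the point itself counted); (2) build a minimum spanning tree of
#' the mutual reachability graph; (3) turn it into a single-linkage cluster
#' hierarchy; (4) condense the hierarchy with `min_cluster_size` and extract
#' the stable clusters by excess of mass. Points in low-density regions are
#' labeled `-1` (noise). The root of the condensed hierarchy is allowed to be
#' selected, so data forming a single dense blob yields one cluster rather
#' than being split.
#'
#' @param x Numeric matrix of observations (rows) in feature space.
#' @param min_cluster_size Smallest number of points a cluster may contain.
#' @param min_samples Neighbor count for the core distance (density
#'   smoothing); larger values declare more points noise.
#' @return A list of class `ht_hdbscan` with elements `labels` (integer,
#'   `-1` = noise, clusters `0..n_clusters-1`), `n_clusters`, and
#'   `cluster_sizes`.
#' @references Campello, Moulavi & Sander (2013) Density-based clustering
#'   based on hierarchical density estimates; McInnes, Healy & Astels (2017)
#'   hdbscan: Hierarchical density based clustering.
#' @export
hdbscan <- function(x, min_cluster_size = 10, min_samples = 5) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(min_cluster_size >= 2, min_samples >= 1)
  if (n < max(2, min_cluster_size)) {
    return(hdbscan_result(rep(-1L, n)))
  }
  d <- as.matrix(stats::dist(x))
  if (max(d) <= .Machine$double.eps^0.5) {
    # all points coincide: one maximally dense cluster
    return(hdbscan_result(rep(0L, n)))
  }
  k <- min(min_samples, n)
  core <- apply(d, 1, function(r) sort(r, partial = k)[k])
  mreach <- pmax(d, outer(core, core, pmax))
  diag(mreach) <- 0

  mst <- prim_mst(mreach)
  hier <- single_linkage(mst, n)
  cond <- condense_tree(hier, n, min_cluster_size)
  if (length(cond$parent) == 0) {
    return(hdbscan_result(rep(-1L, n)))
  }
  labels <- extract_eom(cond, n)
  hdbscan_result(labels)
}

hdbscan_result <- function(labels) {
  n_clusters <- length(setdiff(unique(labels), -1L))
  structure(
    list(
      labels = as.integer(labels),
      n_clusters = n_clusters,
      cluster_sizes = if (n_clusters > 0) table(labels[labels >= 0]) else table(integer(0))
    ),
    class = "ht_hdbscan"
  )
}

# Prim's algorithm on a dense distance matrix; O(n^2) with vectorized
# relaxation. Returns edges (from, to, weight) with 1-based vertex ids.
prim_mst <- function(w) {
  n <- nrow(w)
  in_tree <- logical(n)
  in_tree[1] <- TRUE
  best <- w[1, ]
  from <- rep(1L, n)
  edges <- matrix(0, n - 1, 3)
  for (step in seq_len(n - 1)) {
    cand <- best
    cand[in_tree] <- Inf
    j <- which.min(cand)
    edges[step, ] <- c(from[j], j, best[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & w[j, ] < best
    best[upd] <- w[j, upd]
    from[upd] <- j
  }
  edges
}

# Single-linkage dendrogram from MST edges, scipy layout: row i merges
# children (left, right) at height dist into new node n + i - 1 (0-based ids:
# points 0..n-1, internal nodes n..2n-2). Sizes accumulate.
single_linkage <- function(mst_edges, n) {
  ord <- order(mst_edges[, 3])
  e <- mst_edges[ord, , drop = FALSE]
  parent <- uf_new(2L * n - 1L)
  top <- seq_len(2L * n - 1L) # current top node holding each uf root
  size <- c(rep(1L, n), integer(n - 1L))
  left <- integer(n - 1L)
  right <- integer(n - 1L)
  height <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    ra <- uf_find(parent, e[i, 1])
    rb <- uf_find(parent, e[i, 2])
    la <- top[ra]
    lb <- top[rb]
    new_id <- n + i # 1-based slot; 0-based node id is n + i - 1
    left[i] <- la
    right[i] <- lb
    height[i] <- e[i, 3]
    size[new_id] <- size[la] + size[lb]
    parent <- uf_union(parent, ra, rb)
    top[uf_find(parent, ra)] <- new_id
  }
  # convert to 0-based node ids
  list(left = left - 1L, right = right - 1L, height = height, size = size)
}

# all nodes (0-based ids) in the subtree rooted at `node`, top-down
bfs_hierarchy <- function(hier, n, node) {
  res <- integer(0)
  q <- node
  while (length(q) > 0) {
    res <- c(res, q)
    internal <- q[q >= n]
    if (length(internal) == 0) break
    rows <- internal - n + 1L
    q <- c(hier$left[rows], hier$right[rows])
  }
  res
}

# Condense the single-linkage tree: walking down from the root, a split where
# both sides have >= min_cluster_size points creates two child clusters; a
# split where one side is smaller sheds those points from the persisting
# cluster at that height. Output is an edge list (parent, child, lambda,
# size) where lambda = 1/distance, clusters get ids n, n+1, ... and points
# keep ids 0..n-1.
condense_tree <- function(hier, n, min_cluster_size) {
  root <- 2L * n - 2L
  node_list <- bfs_hierarchy(hier, n, root)
  relabel <- integer(2L * n - 1L) # index: node id + 1
  relabel[root + 1L] <- n
  next_label <- n + 1L
  ignore <- logical(2L * n - 1L)
  parent <- integer(0); child <- integer(0); lam <- numeric(0); csize <- integer(0)
  emit <- function(p, c, l, s) {
    parent[length(parent) + 1L] <<- p
    child[length(child) + 1L] <<- c
    lam[length(lam) + 1L] <<- l
    csize[length(csize) + 1L] <<- s
  }
  node_size <- function(id) if (id >= n) hier$size[id + 1L] else 1L
  for (node in node_list) {
    if (ignore[node + 1L] || node < n) next
    row <- node - n + 1L
    l <- hier$left[row]; r <- hier$right[row]
    dist <- hier$height[row]
    lambda_val <- if (dist > 0) 1 / dist else Inf
    lc <- node_size(l); rc <- node_size(r)
    this <- relabel[node + 1L]
    if (lc >= min_cluster_size && rc >= min_cluster_size) {
      relabel[l + 1L] <- next_label
      emit(this, next_label, lambda_val, lc)
      next_label <- next_label + 1L
      relabel[r + 1L] <- next_label
      emit(this, next_label, lambda_val, rc)
      next_label <- next_label + 1L
    } else if (lc < min_cluster_size && rc < min_cluster_size) {
      for (sub in bfs_hierarchy(hier, n, l)) {
        if (sub < n) emit(this, sub, lambda_val, 1L)
        ignore[sub + 1L] <- TRUE
      }
      for (sub in bfs_hierarchy(hier, n, r)) {
        if (sub < n) emit(this, sub, lambda_val, 1L)
        ignore[sub + 1L] <- TRUE
      }
    } else if (lc < min_cluster_size) {
      relabel[r + 1L] <- this
      for (sub in bfs_hierarchy(hier, n, l)) {
        if (sub < n) emit(this, sub, lambda_val, 1L)
        ignore[sub + 1L] <- TRUE
      }
    } else {
      relabel[l + 1L] <- this
      for (sub in bfs_hierarchy(hier, n, r)) {
        if (sub < n) emit(this, sub, lambda_val, 1L)
        ignore[sub + 1L] <- TRUE
      }
    }
  }
  list(parent = parent, child = child, lambda = lam, size = csize)
}

# Cluster stability: sum over members of (lambda_leave - lambda_birth).
compute_stability <- function(cond) {
  ids <- sort(unique(cond$parent))
  birth <- structure(numeric(length(ids)), names = as.character(ids))
  is_cl <- cond$child %in% ids
  birth[as.character(cond$child[is_cl])] <- cond$lambda[is_cl]
  birth[as.character(min(ids))] <- 0
  contrib <- (cond$lambda - birth[as.character(cond$parent)]) * cond$size
  stab <- tapply(contrib, cond$parent, sum)
  structure(as.numeric(stab), names = names(stab))
}

# Excess-of-mass cluster selection (root selectable) followed by labelling.
extract_eom <- function(cond, n) {
  stab <- compute_stability(cond)
  cluster_ids <- as.integer(names(stab))
  root_id <- min(cluster_ids)
  # cluster-to-cluster edges of the condensed tree
  ccl <- cond$size > 1L
  ct_parent <- cond$parent[ccl]
  ct_child <- cond$child[ccl]

  descendants <- function(node) {
    res <- integer(0)
    q <- node
    while (length(q) > 0) {
      kids <- ct_child[ct_parent %in% q]
      res <- c(res, kids)
      q <- kids
    }
    res
  }

  is_cluster <- structure(rep(TRUE, length(cluster_ids)), names = as.character(cluster_ids))
  for (node in sort(cluster_ids, decreasing = TRUE)) {
    kids <- ct_child[ct_parent == node]
    subtree <- if (length(kids) > 0) sum(stab[as.character(kids)]) else 0
    key <- as.character(node)
    if (subtree > stab[key]) {
      is_cluster[key] <- FALSE
      stab[key] <- subtree
    } else {
      desc <- descendants(node)
      if (length(desc) > 0) is_cluster[as.character(desc)] <- FALSE
    }
  }
  selected <- cluster_ids[is_cluster[as.character(cluster_ids)]]

  # points climb to the topmost cluster not separated from them by a selected
  # boundary; union is directed so the parent side always stays the root
  max_id <- max(c(cond$parent, cond$child))
  uf <- uf_new(max_id + 1L) # 1-based slot for 0-based id
  for (i in seq_along(cond$parent)) {
    if (!(cond$child[i] %in% selected)) {
      rp <- uf_find(uf, cond$parent[i] + 1L)
      rc <- uf_find(uf, cond$child[i] + 1L)
      if (rp != rc) uf[rc] <- rp
    }
  }
  label_map <- structure(seq_along(selected) - 1L, names = as.character(sort(selected)))
  point_lambda <- numeric(n)
  pt <- cond$child < n
  point_lambda[cond$child[pt] + 1L] <- cond$lambda[pt]

  labels <- rep(-1L, n)
  single_root <- length(selected) == 1 && selected[1] == root_id
  if (single_root) {
    root_kids <- ct_child[ct_parent == root_id]
    if (length(root_kids) > 0) {
      # the root once split into subclusters: points must persist to that
      # split to count as members
      threshold <- max(cond$lambda[cond$parent == root_id])
    } else {
      # no split ever: density-based membership cut at half the core
      # lambda (GLOSH outlier score 0.5) — requiring the full max lambda
      # would keep only the final handful of points of a clean blob
      threshold <- max(cond$lambda[cond$parent == root_id]) / 2
    }
  }
  for (p in seq_len(n)) {
    r <- uf_find(uf, p) - 1L # back to 0-based id
    key <- as.character(r)
    if (r != root_id && !is.na(label_map[key])) {
      labels[p] <- label_map[[key]]
    } else if (single_root && r == root_id) {
      if (point_lambda[p] >= threshold) labels[p] <- label_map[[as.character(root_id)]]
    }
  }
  labels
}
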