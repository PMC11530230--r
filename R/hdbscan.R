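# Native HDBSCAN (hierarchical density-based clustering). No R
# implementation is available to this package, so the algorithm is authored
# here: (1) core distances from k-nearest neighbours, (2) a minimum spanning
# tree of the mutual-reachability graph (Prim, O(n^2), row-wise against the
# Euclidean distance matrix so the n x n mutual-reachability matrix is never
# materialized), (3) the single-linkage merge tree, (4) condensation by
# minimum cluster size, and (5) excess-of-mass cluster selection on
# stabilities, with points outside every selected cluster labelled noise (0).
#
# Scaling: the implementation is quadratic in n; it is intended for the
# ensemble sizes this package embeds (up to a few tens of thousands of
# points in 10-D after UMAP).

#' HDBSCAN clustering
#'
#' @param x numeric matrix (points in rows), e.g. a UMAP embedding.
#' @param min_cluster_size smallest cluster that survives condensation.
#' @param min_samples neighbourhood size for core distances; defaults to
#'   `min_cluster_size` so occupancy is the single tuning knob.
#' @return a list with `labels` (integer per point, 1..K by tree order, 0 =
#'   noise), `K`, and `stabilities`.
#' @export
hdbscan_fit <- function(x, min_cluster_size, min_samples = min_cluster_size) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(min_cluster_size >= 2L, n >= 2L)
  if (n <= min_cluster_size)
    return(list(labels = rep(0L, n), K = 0L, stabilities = numeric()))
  dm <- as.matrix(stats::dist(x))
  if (all(dm < 1e-12)) {
    warning("degenerate input: all points identical; returning one cluster")
    return(list(labels = rep(1L, n), K = 1L, stabilities = NA_real_))
  }
  k <- min(min_samples, n - 1L)
  # core distance: distance to the k-th nearest neighbour (self excluded)
  core <- apply(dm, 1L, function(r) sort.int(r, partial = k + 1L)[k + 1L])

  ## --- MST of the mutual reachability graph (Prim) ---
  in_tree <- logical(n)
  best_w <- rep(Inf, n)
  best_from <- integer(n)
  e_from <- integer(n - 1L); e_to <- integer(n - 1L); e_w <- numeric(n - 1L)
  cur <- 1L
  in_tree[cur] <- TRUE
  for (it in seq_len(n - 1L)) {
    w <- pmax(dm[cur, ], core[cur], core)
    upd <- !in_tree & w < best_w
    best_w[upd] <- w[upd]
    best_from[upd] <- cur
    cand <- best_w
    cand[in_tree] <- Inf
    nxt <- which.min(cand)
    e_from[it] <- best_from[nxt]; e_to[it] <- nxt; e_w[it] <- best_w[nxt]
    in_tree[nxt] <- TRUE
    cur <- nxt
  }

  ## --- single-linkage merge tree over MST edges (union-find) ---
  ord <- order(e_w)
  parent <- seq_len(2L * n - 1L)          # union-find over points + merge nodes
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  comp_node <- seq_len(n)                 # current tree node of each component root
  left <- integer(n - 1L); right <- integer(n - 1L); height <- numeric(n - 1L)
  sz <- c(rep(1L, n), integer(n - 1L))    # leaf count per tree node
  for (t in seq_len(n - 1L)) {
    e <- ord[t]
    ra <- find(e_from[e]); rb <- find(e_to[e])
    na <- comp_node[ra]; nb <- comp_node[rb]
    node <- n + t
    left[t] <- na; right[t] <- nb; height[t] <- e_w[e]
    sz[node] <- sz[na] + sz[nb]
    parent[ra] <- rb
    comp_node[rb] <- node
  }

  ## --- condensation ---
  # Walk the merge tree from the root. Each condensed cluster accrues points
  # that "fall out" at lambda = 1/height of the merge where they separate;
  # a merge whose two sides both have >= min_cluster_size points is a true
  # split spawning two child clusters.
  root <- 2L * n - 1L
  n_nodes <- 2L * n - 1L
  # children of internal nodes by id
  ch_l <- c(rep(NA_integer_, n), left)
  ch_r <- c(rep(NA_integer_, n), right)
  hgt <- c(rep(NA_real_, n), height)

  cl_parent <- integer(0)   # condensed-tree parent of each cluster
  cl_birth <- numeric(0)    # lambda at which the cluster appears
  cl_stab <- numeric(0)     # accumulated stability
  cl_children <- list()
  labels_of <- integer(n)   # condensed cluster owning each point (0 = none)

  new_cluster <- function(parent_id, lambda) {
    cl_parent[length(cl_parent) + 1L] <<- parent_id
    cl_birth[length(cl_birth) + 1L] <<- lambda
    cl_stab[length(cl_stab) + 1L] <<- 0
    cl_children[[length(cl_birth)]] <<- integer(0)
    if (parent_id > 0L)
      cl_children[[parent_id]] <<- c(cl_children[[parent_id]], length(cl_birth))
    length(cl_birth)
  }

  # collect leaves of a subtree iteratively
  subtree_leaves <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (v <= n) out <- c(out, v)
      else stack <- c(stack, ch_l[v], ch_r[v])
    }
    out
  }

  root_cl <- new_cluster(0L, 0)
  # stack of (tree node, condensed cluster id)
  st_node <- root; st_cl <- root_cl
  while (length(st_node)) {
    v <- st_node[length(st_node)]; cl <- st_cl[length(st_cl)]
    st_node <- st_node[-length(st_node)]; st_cl <- st_cl[-length(st_cl)]
    repeat {
      if (v <= n) {          # single point left in this cluster
        lam <- Inf           # capped below by the merge heights above it
        labels_of[v] <- cl
        # point persists to lambda of the smallest edge it was merged at:
        # handled by fall-out bookkeeping of the parent; here it simply
        # remains; stability contribution added at fall-out time
        break
      }
      a <- ch_l[v]; b <- ch_r[v]
      lam <- 1 / hgt[v]
      big_a <- sz[a] >= min_cluster_size
      big_b <- sz[b] >= min_cluster_size
      if (big_a && big_b) {  # true split
        ca <- new_cluster(cl, lam)
        cb <- new_cluster(cl, lam)
        # points passing to children contribute (lambda_split - birth)
        cl_stab[cl] <- cl_stab[cl] + sz[v] * (lam - cl_birth[cl])
        st_node <- c(st_node, a); st_cl <- c(st_cl, ca)
        v <- b; cl <- cb
      } else if (big_a || big_b) {
        small <- if (big_a) b else a
        keep <- if (big_a) a else b
        pts <- subtree_leaves(small)
        labels_of[pts] <- cl
        cl_stab[cl] <- cl_stab[cl] + length(pts) * (lam - cl_birth[cl])
        v <- keep
      } else {               # cluster dissolves
        pts <- subtree_leaves(v)
        labels_of[pts] <- cl
        cl_stab[cl] <- cl_stab[cl] + length(pts) * (lam - cl_birth[cl])
        break
      }
    }
  }

  n_cl <- length(cl_birth)
  if (n_cl == 1L) {
    # no true split anywhere: everything is noise under excess-of-mass
    # selection with the root excluded
    return(list(labels = rep(0L, n), K = 0L, stabilities = numeric()))
  }

  ## --- excess-of-mass selection (root never selectable) ---
  selected <- logical(n_cl)
  score <- numeric(n_cl)
  # process deepest-first: children always carry larger ids than parents
  for (cl in n_cl:1L) {
    kids <- cl_children[[cl]]
    if (!length(kids)) {
      selected[cl] <- TRUE
      score[cl] <- cl_stab[cl]
    } else {
      kid_sum <- sum(score[kids])
      if (cl != root_cl && cl_stab[cl] > kid_sum) {
        selected[cl] <- TRUE
        score[cl] <- cl_stab[cl]
      } else {
        score[cl] <- kid_sum
      }
    }
  }
  # deselect descendants of selected clusters (top-down)
  for (cl in seq_len(n_cl)) {
    if (!selected[cl]) next
    stack <- cl_children[[cl]]
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      selected[v] <- FALSE
      stack <- c(stack, cl_children[[v]])
    }
  }
  sel_ids <- which(selected)
  # map every point to its nearest selected ancestor (if any)
  owner <- integer(n_cl)  # selected cluster owning each condensed cluster
  for (cl in seq_len(n_cl)) {
    v <- cl
    own <- 0L
    while (v > 0L) {
      if (selected[v]) { own <- v; break }
      v <- cl_parent[v]
    }
    owner[cl] <- own
  }
  lab <- owner[labels_of]
  relab <- match(lab, sel_ids)
  labels <- ifelse(is.na(relab) | lab == 0L, 0L, relab)
  list(labels = as.integer(labels), K = length(sel_ids),
       stabilities = cl_stab[sel_ids])
}
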