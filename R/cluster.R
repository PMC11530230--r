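# Embedding + density-based partitioning of feature rows, and partition
# comparison. UMAP goes through uwot with threading pinned to one worker so
# a fixed seed reproduces the embedding exactly; clustering is the native
# HDBSCAN of hdbscan.R with the minimum cluster occupancy as its single
# knob.

#' Embed feature rows with UMAP
#'
#' @param features a `feature_matrix` (or bare numeric matrix).
#' @param dim embedding dimension (default 10; use 2 for visualization).
#' @param seed integer seed; the embedding is deterministic for a fixed seed
#'   and library version.
#' @param n_neighbors,min_dist UMAP neighbourhood size and minimum distance
#'   (defaults 30 and 0.1; Euclidean metric on rows).
#' @return an `embedding` object: list with `points` (n x dim), `seed`,
#'   `settings`.
#' @export
embed_features <- function(features, dim = 10L, seed = 0L,
                           n_neighbors = 30L, min_dist = 0.1) {
  x <- if (inherits(features, "feature_matrix")) features$values else as.matrix(features)
  stopifnot(dim >= 2L)
  n <- nrow(x)
  if (n < n_neighbors)
    stop("n = ", n, " rows is below n_neighbors = ", n_neighbors,
         "; use a smaller neighbour count")
  if (n <= dim)
    stop("n = ", n, " rows cannot support a ", dim,
         "-dimensional embedding; reduce dim")
  set.seed(seed)
  pts <- uwot::umap(x, n_components = dim, n_neighbors = n_neighbors,
                    min_dist = min_dist, metric = "euclidean",
                    n_threads = 1L, n_sgd_threads = 0L, verbose = FALSE)
  structure(list(points = pts, seed = seed,
                 settings = list(dim = dim, n_neighbors = n_neighbors,
                                 min_dist = min_dist)),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat("UMAP embedding:", nrow(x$points), "points in", ncol(x$points),
      "dimensions (seed", x$seed, ")\n")
  invisible(x)
}

#' Partition an embedding with HDBSCAN
#'
#' The minimum cluster size is `max(2, round(min_cluster_fraction * n))`;
#' the number of clusters is selected by the algorithm. Clusters are
#' renumbered by decreasing occupancy (largest = 1) for report stability --
#' the numbering itself carries no meaning. Points in no cluster keep the
#' noise label 0.
#'
#' @param emb an `embedding` (or numeric matrix).
#' @param min_cluster_fraction minimum cluster occupancy as a fraction of n
#'   (default 0.01).
#' @return a `cluster_assignment`: list with `labels` (0 = noise), `K`,
#'   `min_cluster_fraction`, `cluster_sizes`.
#' @export
partition_embedding <- function(emb, min_cluster_fraction = 0.01) {
  stopifnot(min_cluster_fraction > 0, min_cluster_fraction < 1)
  pts <- if (inherits(emb, "embedding")) emb$points else as.matrix(emb)
  n <- nrow(pts)
  mcs <- max(2L, as.integer(round(min_cluster_fraction * n)))
  fit <- hdbscan_fit(pts, min_cluster_size = mcs)
  labels <- fit$labels
  if (fit$K > 1L) {
    sizes <- tabulate(labels, nbins = fit$K)
    ord <- order(sizes, decreasing = TRUE)
    remap <- integer(fit$K)
    remap[ord] <- seq_len(fit$K)
    labels <- ifelse(labels == 0L, 0L, remap[labels])
  }
  structure(list(labels = as.integer(labels), K = fit$K,
                 min_cluster_fraction = min_cluster_fraction,
                 cluster_sizes = if (fit$K) tabulate(labels, nbins = fit$K)
                                 else integer()),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  n <- length(x$labels)
  cat("Cluster assignment: K =", x$K, "clusters over", n, "conformations;",
      sprintf("%.1f%%", 100 * mean(x$labels == 0L)), "noise\n")
  if (x$K)
    cat("Occupancies:",
        paste(sprintf("%.1f%%", 100 * x$cluster_sizes / n), collapse = ", "),
        "\n")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement in `[-1, 1]`; 1 iff the partitions are
#' identical up to relabelling. Noise (label 0) is treated as its own class
#' by default, or excluded pairwise with `noise = "exclude"`.
#'
#' @param a,b `cluster_assignment` objects or bare label vectors of equal
#'   length.
#' @param noise `"class"` (default) or `"exclude"`.
#' @return the ARI.
#' @export
adjusted_rand_index <- function(a, b, noise = c("class", "exclude")) {
  noise <- match.arg(noise)
  la <- if (inherits(a, "cluster_assignment")) a$labels else a
  lb <- if (inherits(b, "cluster_assignment")) b$labels else b
  if (length(la) != length(lb))
    stop("partitions have different lengths (", length(la), " vs ",
         length(lb), ")")
  if (noise == "exclude") {
    keep <- la != 0L & lb != 0L
    la <- la[keep]; lb <- lb[keep]
  }
  mclust::adjustedRandIndex(la, lb)
}
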