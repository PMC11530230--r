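# The user-facing model fit: wfcm() takes an ensemble (and a contact
# parameter table), runs featurization -> UMAP embedding -> HDBSCAN
# partition -> weighted family of contact maps, and returns a classed object
# with the usual accessor methods.

#' Fit a weighted family of contact maps to a conformational ensemble
#'
#' The full characterization pipeline: conformations are featured by the
#' continuous contact function (or a baseline featurization), embedded into
#' a low-dimensional UMAP space, partitioned with HDBSCAN using the minimum
#' cluster occupancy as the single resolution knob, and summarized as one
#' occupancy-weighted mean contact map per cluster plus per-cluster
#' secondary-structure and size descriptors.
#'
#' @param ensemble an `ensemble` (see [load_ensemble()], [make_ensemble()]).
#' @param table a `contact_param_table`; required for
#'   `feature_kind = "omega"` (see [estimate_parameters()]).
#' @param feature_kind `"omega"` (the contact function; default),
#'   `"distance"` or `"lj"` (baselines).
#' @param dim UMAP embedding dimension (default 10).
#' @param n_neighbors,min_dist UMAP settings (defaults 30, 0.1).
#' @param min_cluster_fraction minimum cluster occupancy (default 0.01, i.e.
#'   1% of n).
#' @param seed seed controlling every stochastic stage.
#' @param descriptors compute per-cluster structural descriptors (default
#'   TRUE; the only stage that needs secondary-structure assignment).
#' @return an object of class `wfcm`: list with `characterization`,
#'   `assignment`, `embedding`, `features`, `descriptors`, `seed`, `call`.
#' @export
#' @examples
#' specs <- list(family_spec("coil", count = 60),
#'               family_spec("helix_segment", segment = c(8, 20), count = 60))
#' syn <- make_ensemble(specs, strrep("A", 27), seed = 7)
#' tab <- estimate_parameters(make_reference_set(25, seed = 1),
#'                            settings = list(min_support = 1e9))
#' fit <- wfcm(syn$ensemble, tab, n_neighbors = 15, min_cluster_fraction = 0.05)
#' print(fit)
wfcm <- function(ensemble, table = NULL,
                 feature_kind = c("omega", "distance", "lj"),
                 dim = 10L, n_neighbors = 30L, min_dist = 0.1,
                 min_cluster_fraction = 0.01, seed = 0L,
                 descriptors = TRUE) {
  feature_kind <- match.arg(feature_kind)
  stopifnot(inherits(ensemble, "ensemble"))
  features <- switch(feature_kind,
    omega = {
      if (is.null(table))
        stop("a contact_param_table is required for omega featurization")
      featurize_omega(ensemble, table)
    },
    distance = featurize_distance(ensemble),
    lj = featurize_lj(ensemble))
  emb <- embed_features(features, dim = dim, seed = seed,
                        n_neighbors = n_neighbors, min_dist = min_dist)
  assignment <- partition_embedding(emb, min_cluster_fraction)
  char <- if (feature_kind == "omega") {
    characterize_ensemble(features, assignment)
  } else NULL
  desc <- NULL
  if (descriptors && assignment$K > 0L) {
    desc <- lapply(seq_len(assignment$K), function(k)
      cluster_descriptors(ensemble, which(assignment$labels == k)))
  }
  structure(list(characterization = char, assignment = assignment,
                 embedding = emb, features = features, descriptors = desc,
                 ensemble = ensemble, feature_kind = feature_kind,
                 seed = seed, call = match.call()),
            class = "wfcm")
}

#' @export
print.wfcm <- function(x, ...) {
  cat("Weighted-family-of-contact-maps fit (", x$feature_kind,
      " features)\n", sep = "")
  cat("n =", x$ensemble$n, "conformations, L =", x$ensemble$L,
      "residues, seed", x$seed, "\n")
  print(x$assignment)
  invisible(x)
}

#' @export
summary.wfcm <- function(object, ...) {
  a <- object$assignment
  n <- length(a$labels)
  tab <- data.frame(cluster = seq_len(a$K),
                    size = a$cluster_sizes,
                    weight = a$cluster_sizes / n)
  if (!is.null(object$descriptors)) {
    tab$rg_mean <- vapply(object$descriptors, `[[`, numeric(1L), "rg_mean")
    tab$rg_sd <- vapply(object$descriptors, `[[`, numeric(1L), "rg_sd")
    tab$end_to_end <- vapply(object$descriptors, `[[`, numeric(1L),
                             "end_to_end_mean")
    tab$helix <- vapply(object$descriptors, function(d)
      mean(d$ss_propensity[, "helix"]), numeric(1L))
    tab$strand <- vapply(object$descriptors, function(d)
      mean(d$ss_propensity[, "strand"]), numeric(1L))
  }
  out <- list(feature_kind = object$feature_kind, n = n,
              L = object$ensemble$L, K = a$K,
              noise_fraction = mean(a$labels == 0L), clusters = tab)
  class(out) <- "summary.wfcm"
  out
}

#' @export
print.summary.wfcm <- function(x, ...) {
  cat("wfcm fit:", x$K, "clusters over n =", x$n, "conformations (",
      sprintf("%.1f%%", 100 * x$noise_fraction), "noise ), L =", x$L, "\n\n")
  print(x$clusters, digits = 3L, row.names = FALSE)
  invisible(x)
}

#' Cluster labels of a wfcm fit
#'
#' @param object a `wfcm` fit.
#' @param ... unused.
#' @return integer labels, 0 = noise.
#' @export
labels.wfcm <- function(object, ...) object$assignment$labels

#' Plot a wfcm fit
#'
#' `which = "map"` draws the omega-contact map of one cluster (by occupancy
#' rank); `which = "embedding"` the first two embedding coordinates coloured
#' by cluster.
#'
#' @param x a `wfcm` fit.
#' @param which `"map"` or `"embedding"`.
#' @param cluster occupancy rank of the map to draw (default 1).
#' @param ... passed to the underlying plotting function.
#' @export
plot.wfcm <- function(x, which = c("map", "embedding"), cluster = 1L, ...) {
  which <- match.arg(which)
  if (which == "map") {
    if (is.null(x$characterization))
      stop("contact maps exist only for omega featurization")
    m <- x$characterization$maps[[cluster]]
    L <- nrow(m$values)
    graphics::image(seq_len(L), seq_len(L), t(m$values[L:1, ]),
                    zlim = c(0, 1),
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    xlab = "residue", ylab = "residue",
                    main = sprintf("cluster %d (%.1f%%)", m$cluster_id,
                                   100 * m$weight), ...)
  } else {
    pts <- x$embedding$points
    lab <- x$assignment$labels
    graphics::plot(pts[, 1L], pts[, 2L], col = lab + 1L, pch = 20L,
                   cex = 0.5, xlab = "UMAP 1", ylab = "UMAP 2", ...)
  }
  invisible(x)
}
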