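# Cluster-level summaries: the weighted family of cluster-specific
# omega-contact maps (each the within-cluster mean of contact-function rows,
# weighted by occupancy |C_k|/n), plus per-cluster structural descriptors
# (secondary-structure propensities, radius of gyration, end-to-end
# distance) and a file report.

.ATOM_MASS <- c(N = 14.007, CA = 12.011, C = 12.011, O = 15.999, CB = 12.011)

#' Cluster-specific omega-contact map
#'
#' The mean over the member conformations' contact-function rows, reshaped
#' as a symmetric L x L matrix with zero diagonal, weighted by the cluster's
#' occupancy fraction.
#'
#' @param features an omega `feature_matrix`.
#' @param members conformation indices of the cluster (non-empty).
#' @param n ensemble size used for the weight (defaults to `features$n`).
#' @param cluster_id identifier stored with the map.
#' @return an `omega_contact_map`: list with `values` (L x L), `weight`,
#'   `occupancy`, `cluster_id`.
#' @export
cluster_contact_map <- function(features, members, n = features$n,
                                cluster_id = NA_integer_) {
  if (!length(members)) stop("empty member set")
  if (features$kind != "omega")
    stop("cluster contact maps are defined for omega features, not '",
         features$kind, "'")
  mu <- colMeans(features$values[members, , drop = FALSE])
  L <- features$L
  m <- matrix(0, L, L)
  m[features$pairs] <- mu
  m[features$pairs[, c(2L, 1L), drop = FALSE]] <- mu
  structure(list(values = m, weight = length(members) / n,
                 occupancy = length(members), cluster_id = cluster_id),
            class = "omega_contact_map")
}

#' @export
print.omega_contact_map <- function(x, ...) {
  cat(sprintf("omega-contact map, cluster %s: %d conformations (%.2f%%)\n",
              x$cluster_id, x$occupancy, 100 * x$weight))
  invisible(x)
}

#' Mass-weighted radius of gyration
#'
#' Over all available heavy atoms of the backbone representation (N, CA, C,
#' O, CB with standard element masses).
#'
#' @param conf a `conformation`.
#' @return radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(conf) {
  xyz <- NULL; w <- numeric()
  for (at in names(conf$coords)) {
    m <- conf$coords[[at]]
    pres <- which(stats::complete.cases(m))
    if (!length(pres)) next
    xyz <- rbind(xyz, m[pres, , drop = FALSE])
    w <- c(w, rep(.ATOM_MASS[[at]], length(pres)))
  }
  ctr <- colSums(xyz * w) / sum(w)
  sq <- rowSums((xyz - matrix(ctr, nrow(xyz), 3L, byrow = TRUE))^2)
  sqrt(sum(w * sq) / sum(w))
}

#' Per-cluster structural descriptors
#'
#' Secondary-structure propensities (per-residue fraction of member
#' conformations in the collapsed helix/strand/coil states), mass-weighted
#' radius-of-gyration mean and sd, and mean CA(1)-CA(L) end-to-end distance.
#'
#' @param ens an `ensemble`.
#' @param members conformation indices (non-empty).
#' @return a `cluster_descriptors` list.
#' @export
cluster_descriptors <- function(ens, members) {
  if (!length(members)) stop("empty member set")
  L <- ens$L
  counts <- matrix(0, L, 3L, dimnames = list(NULL, c("helix", "strand", "coil")))
  rg <- numeric(length(members))
  e2e <- numeric(length(members))
  for (m in seq_along(members)) {
    conf <- ens$conformations[[members[m]]]
    st <- collapse_ss(secondary_structure(conf))
    counts[cbind(seq_len(L), match(st, colnames(counts)))] <-
      counts[cbind(seq_len(L), match(st, colnames(counts)))] + 1
    rg[m] <- radius_of_gyration(conf)
    ca <- conf$coords$CA
    e2e[m] <- vnorm(ca[L, ] - ca[1L, ])
  }
  structure(list(ss_propensity = counts / length(members),
                 rg_mean = mean(rg), rg_sd = stats::sd(rg),
                 end_to_end_mean = mean(e2e), n_members = length(members)),
            class = "cluster_descriptors")
}

#' Weighted family of contact maps for a clustered ensemble
#'
#' Builds one omega-contact map per cluster, ordered by decreasing
#' occupancy weight; weights plus the noise fraction conserve mass exactly.
#'
#' @param features an omega `feature_matrix`.
#' @param assignment a `cluster_assignment` over the same conformations.
#' @return an `ensemble_characterization`: list with `maps`, `weights`,
#'   `noise_fraction`, `K`.
#' @export
characterize_ensemble <- function(features, assignment) {
  labels <- assignment$labels
  if (length(labels) != features$n)
    stop("features (n = ", features$n, ") and assignment (n = ",
         length(labels), ") do not match")
  K <- assignment$K
  maps <- vector("list", K)
  for (k in seq_len(K))
    maps[[k]] <- cluster_contact_map(features, which(labels == k),
                                     n = features$n, cluster_id = k)
  w <- vapply(maps, function(m) m$weight, numeric(1L))
  ord <- order(w, decreasing = TRUE)
  structure(list(maps = maps[ord], weights = w[ord],
                 noise_fraction = mean(labels == 0L), K = K,
                 n = features$n, sequence = features$sequence),
            class = "ensemble_characterization")
}

#' @export
print.ensemble_characterization <- function(x, ...) {
  cat("Weighted family of", x$K, "omega-contact maps over n =", x$n,
      "conformations\n")
  cat(sprintf("Weights: %s; noise %.2f%%\n",
              paste(sprintf("%.2f%%", 100 * x$weights), collapse = ", "),
              100 * x$noise_fraction))
  invisible(x)
}

#' Write a characterization report
#'
#' Writes a JSON summary (weights, noise fraction, per-cluster descriptors),
#' per-cluster map renders, per-cluster representative conformations as
#' multi-model PDB, a labels CSV, and the naive 8 A binary contact map for
#' contrast.
#'
#' @param char an `ensemble_characterization`.
#' @param ens the underlying `ensemble`.
#' @param assignment the `cluster_assignment`.
#' @param outdir output directory (created if needed).
#' @param n_samples representative conformations per cluster (default 10).
#' @param descriptors optional precomputed list of per-cluster
#'   [cluster_descriptors()] (computed here when NULL).
#' @param seed seed for the representative sampling.
#' @return the output directory, invisibly.
#' @export
write_report <- function(char, ens, assignment, outdir, n_samples = 10L,
                         descriptors = NULL, seed = 0L) {
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  set.seed(seed)
  labels <- assignment$labels
  if (is.null(descriptors)) {
    descriptors <- lapply(seq_len(char$K), function(k)
      cluster_descriptors(ens, which(labels == k)))
  }
  summ <- list(
    n = char$n, L = nchar(char$sequence), sequence = char$sequence,
    K = char$K, noise_fraction = char$noise_fraction,
    clusters = lapply(seq_along(char$maps), function(m) {
      k <- char$maps[[m]]$cluster_id
      d <- descriptors[[k]]
      list(cluster_id = k, weight = char$maps[[m]]$weight,
           occupancy = char$maps[[m]]$occupancy,
           rg_mean = d$rg_mean, rg_sd = d$rg_sd,
           end_to_end_mean = d$end_to_end_mean,
           map_file = sprintf("map_cluster%02d.png", k),
           pdb_file = sprintf("cluster%02d_samples.pdb", k))
    }))
  jsonlite::write_json(summ, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(data.frame(conformation = seq_along(labels),
                              label = labels),
                   file.path(outdir, "labels.csv"), row.names = FALSE)
  .render_map <- function(m, file, main) {
    grDevices::png(file, width = 600, height = 600)
    L <- nrow(m)
    graphics::image(seq_len(L), seq_len(L), t(m[L:1, ]), zlim = c(0, 1),
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    xlab = "residue", ylab = "residue", main = main,
                    axes = FALSE)
    graphics::axis(1); graphics::axis(2, at = seq_len(L), labels = L:1)
    grDevices::dev.off()
  }
  for (m in char$maps) {
    k <- m$cluster_id
    .render_map(m$values, file.path(outdir, sprintf("map_cluster%02d.png", k)),
                sprintf("cluster %d (%.1f%%)", k, 100 * m$weight))
    members <- which(labels == k)
    samp <- if (length(members) > n_samples) sample(members, n_samples)
            else members
    write_ensemble_pdb(ens, file.path(outdir,
                                      sprintf("cluster%02d_samples.pdb", k)),
                       indices = samp)
  }
  .render_map(mean_binary_contact_map(ens),
              file.path(outdir, "naive_binary_map.png"),
              "naive 8 A contact probability")
  invisible(outdir)
}
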