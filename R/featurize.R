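# Featurization of an ensemble: each conformation becomes one row of an
# n x L(L-1)/2 matrix over all residue pairs in lexicographic order
# (1,2), (1,3), ..., (L-1,L). Feature kinds: the continuous contact function
# (omega), raw CB-CB distances, a 12-6 Lennard-Jones inter-residue energy
# baseline, and the naive thresholded contact-probability map used for
# contrast.

## Lexicographic pair index for chain length L: a 2-column matrix (i, j), i<j.
pair_index <- function(L) {
  i <- rep(seq_len(L - 1L), times = (L - 1L):1L)
  j <- unlist(lapply(seq_len(L - 1L), function(a) (a + 1L):L))
  cbind(i = i, j = j)
}

new_feature_matrix <- function(values, pairs, kind, sequence) {
  structure(list(values = values, pairs = pairs, kind = kind,
                 sequence = sequence, n = nrow(values), L = nchar(sequence)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix (", x$kind, "): ", x$n, " x ", ncol(x$values),
      " (L = ", x$L, ")\n", sep = "")
  invisible(x)
}

## Distances for all pairs of one conformation, in lexicographic pair order.
.pair_distances <- function(conf, pairs) {
  ic <- interaction_coords(conf)
  rows_norm(ic[pairs[, 1L], , drop = FALSE] - ic[pairs[, 2L], , drop = FALSE])
}

## Resolve parameters for every column once per (sequence, table).
.column_params <- function(sequence, pairs, table) {
  aa <- strsplit(sequence, "")[[1L]]
  P <- nrow(pairs)
  rc <- range_class(pairs[, 2L] - pairs[, 1L])
  d_lo <- d_hi <- alpha <- theta_max <- numeric(P)
  qpref <- matrix(NA_real_, P, 4L)
  oriented <- logical(P)
  for (p in seq_len(P)) {
    pp <- resolve_params(table, aa[pairs[p, 1L]], aa[pairs[p, 2L]], rc[p])
    d_lo[p] <- pp$d_lo; d_hi[p] <- pp$d_hi; alpha[p] <- pp$alpha_max
    if (rc[p] %in% ORIENTED_RANGES && !is.null(pp$q_pref) &&
        !is.null(pp$theta_max)) {
      oriented[p] <- TRUE
      qpref[p, ] <- pp$q_pref
      theta_max[p] <- pp$theta_max
    }
  }
  list(rc = rc, d_lo = d_lo, d_hi = d_hi, alpha = alpha,
       theta_max = theta_max, qpref = qpref, oriented = oriented)
}

#' Contact-function featurization
#'
#' Row k, column (i, j) holds the contact function of residues i and j in
#' conformation k. Orientation terms are evaluated for ranges 2-4 from the
#' per-residue backbone frames; columns are in lexicographic pair order.
#'
#' @param ens an `ensemble`.
#' @param table a `contact_param_table`.
#' @return a `feature_matrix` with `kind = "omega"`, entries in `[0, 1]`.
#' @export
featurize_omega <- function(ens, table) {
  pairs <- pair_index(ens$L)
  cp <- .column_params(ens$sequence, pairs, table)
  ori <- which(cp$oriented)
  io <- pairs[ori, 1L]; jo <- pairs[ori, 2L]
  qo <- cp$qpref[ori, , drop = FALSE]
  vals <- matrix(0, ens$n, nrow(pairs))
  for (k in seq_len(ens$n)) {
    conf <- ens$conformations[[k]]
    d <- .pair_distances(conf, pairs)
    dp <- d
    if (length(ori)) {
      fr <- build_frames(conf)
      qres <- rot_to_quat(fr$rotation)
      qij <- quat_mult(quat_conj(qres[io, , drop = FALSE]),
                       qres[jo, , drop = FALSE])
      theta <- quat_angle(qij, qo)
      s_aff <- pmax(0, 1 - theta / cp$theta_max[ori])
      cut <- .orient_cutoff(d[ori], cp$d_hi[ori])
      dp[ori] <- pmax(0, d[ori] - cp$alpha[ori] * cut * s_aff)
    }
    w <- 0.5 * (1 + cos(pi * (dp - cp$d_lo) / (cp$d_hi - cp$d_lo)))
    vals[k, ] <- ifelse(dp <= cp$d_lo, 1, ifelse(dp >= cp$d_hi, 0, w))
  }
  new_feature_matrix(vals, pairs, "omega", ens$sequence)
}

#' Pairwise-distance featurization
#'
#' Row k holds all CB-CB (CA for glycine) distances of conformation k -- the
#' distance-based baseline featurization.
#'
#' @param ens an `ensemble`.
#' @return a `feature_matrix` with `kind = "distance"`, entries in Angstrom.
#' @export
featurize_distance <- function(ens) {
  pairs <- pair_index(ens$L)
  vals <- t(vapply(ens$conformations, .pair_distances,
                   numeric(nrow(pairs)), pairs = pairs))
  new_feature_matrix(vals, pairs, "distance", ens$sequence)
}

#' Default Lennard-Jones atom-class parameters
#'
#' A minimal generic table over heavy-atom element classes (C, N, O, S):
#' `sigma` in Angstrom, `epsilon` in kcal/mol. Replaceable via the
#' `lj_params` argument of [featurize_lj()].
#'
#' @return a data.frame with columns `class`, `sigma`, `epsilon`.
#' @export
default_lj_params <- function() {
  data.frame(class = c("C", "N", "O", "S"),
             sigma = c(3.40, 3.25, 2.96, 3.56),
             epsilon = c(0.086, 0.170, 0.210, 0.250))
}

#' Lennard-Jones inter-residue energy featurization
#'
#' Row k, column (i, j) holds the summed 12-6 LJ energy over all heavy-atom
#' pairs between residues i and j: `4 eps [(sig/r)^12 - (sig/r)^6]` with
#' Lorentz-Berthelot combination, truncated and shifted at `cutoff`.
#'
#' @param ens an `ensemble`.
#' @param lj_params atom-class table (see [default_lj_params()]).
#' @param cutoff truncation distance in Angstrom (default 10).
#' @return a `feature_matrix` with `kind = "lj"`, entries in kcal/mol.
#' @export
featurize_lj <- function(ens, lj_params = default_lj_params(), cutoff = 10) {
  pairs <- pair_index(ens$L)
  # element class of each backbone atom slot
  slot_class <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")
  cls <- lj_params$class
  sig <- lj_params$sigma; names(sig) <- cls
  eps <- lj_params$epsilon; names(eps) <- cls
  unknown <- setdiff(unname(slot_class), cls)
  if (length(unknown)) {
    warning("unknown atom class(es) ", paste(unknown, collapse = ", "),
            "; using class C parameters")
    for (u in unknown) { sig[u] <- sig[["C"]]; eps[u] <- eps[["C"]] }
  }
  # backbone topology index for bonded-pair exclusion: N-CA-C runs along the
  # chain (C_i bonded to N_{i+1}); O and CB are one-bond branches off C and
  # CA. Atom pairs within 3 bonds (1-2, 1-3 and 1-4 interactions) are
  # excluded, as in standard nonbonded energy evaluations.
  slot_tpos <- c(N = 0, CA = 1, C = 2, O = 2, CB = 1)
  slot_branch <- c(N = 0, CA = 0, C = 0, O = 1, CB = 1)
  vals <- matrix(0, ens$n, nrow(pairs))
  for (k in seq_len(ens$n)) {
    conf <- ens$conformations[[k]]
    # stack all present atoms with residue index, class and topology index
    xyz <- NULL; res <- integer(); acl <- character()
    tpos <- numeric(); tbr <- numeric()
    for (at in names(conf$coords)) {
      m <- conf$coords[[at]]
      pres <- which(stats::complete.cases(m))
      if (!length(pres)) next
      xyz <- rbind(xyz, m[pres, , drop = FALSE])
      res <- c(res, pres)
      acl <- c(acl, rep(slot_class[[at]], length(pres)))
      tpos <- c(tpos, 3 * (pres - 1L) + slot_tpos[[at]])
      tbr <- c(tbr, rep(slot_branch[[at]], length(pres)))
    }
    dm <- as.matrix(stats::dist(xyz))
    sij <- outer(sig[acl], sig[acl], `+`) / 2
    eij <- sqrt(outer(eps[acl], eps[acl]))
    sr6 <- (sij / dm)^6
    v <- 4 * eij * (sr6^2 - sr6)
    src6 <- (sij / cutoff)^6
    v <- v - 4 * eij * (src6^2 - src6)  # shift so V(cutoff) = 0
    v[dm >= cutoff] <- 0
    bonds <- abs(outer(tpos, tpos, `-`)) + outer(tbr, tbr, `+`)
    v[bonds <= 3] <- 0
    # accumulate per residue pair
    ut <- upper.tri(dm)
    ri <- pmin(res[row(dm)[ut]], res[col(dm)[ut]])
    rj <- pmax(res[row(dm)[ut]], res[col(dm)[ut]])
    keep <- ri != rj & v[ut] != 0
    agg <- tapply(v[ut][keep], paste(ri[keep], rj[keep]), sum)
    colk <- numeric(nrow(pairs))
    hit <- match(paste(pairs[, 1L], pairs[, 2L]), names(agg))
    colk[!is.na(hit)] <- agg[hit[!is.na(hit)]]
    vals[k, ] <- colk
  }
  new_feature_matrix(vals, pairs, "lj", ens$sequence)
}

#' Naive mean binary contact map
#'
#' Entry (i, j) is the fraction of conformations whose interaction distance
#' is at most `threshold` -- the conventional ensemble-averaged contact
#' probability map that dilutes transient features, provided for contrast.
#'
#' @param ens an `ensemble`.
#' @param threshold contact threshold in Angstrom (default 8).
#' @return a symmetric L x L probability matrix with zero diagonal.
#' @export
mean_binary_contact_map <- function(ens, threshold = 8) {
  stopifnot(threshold > 0)
  pairs <- pair_index(ens$L)
  hits <- numeric(nrow(pairs))
  for (k in seq_len(ens$n))
    hits <- hits + (.pair_distances(ens$conformations[[k]], pairs) <= threshold)
  map <- matrix(0, ens$L, ens$L)
  map[pairs] <- hits / ens$n
  map[pairs[, c(2L, 1L), drop = FALSE]] <- hits / ens$n
  map
}
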