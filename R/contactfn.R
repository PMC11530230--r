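# The continuous contact function: a proxy in [0, 1] for the interaction of
# a residue pair, depending on amino-acid identities, sequence separation
# ("range"), Euclidean CB-CB distance, and -- for ranges 2-4 -- the relative
# orientation of the two residue frames. Parameters (the Euclidean contact
# interval, the preferred relative rotation and its tolerance) are estimated
# per (pair, range) class from a reference set of structures, with pooled
# backoff for sparsely observed classes.
#
# Functional forms: omega is a cosine ramp from 1 at d_lo to 0 at d_hi of
# the relative pose distance d' = d - alpha_max * c(d) * s(theta), where
# s(theta) = max(0, 1 - theta/theta_max) is the orientation affinity and
# c(d) fades smoothly from 1 at d_hi to 0 at d_hi + 2 A. For range 1 and
# long range (separation >= 5) d' = d exactly, so the contact value depends
# on distance alone.

RANGE_LEVELS <- c("1", "2", "3", "4", "long")
ORIENTED_RANGES <- c("2", "3", "4")

#' Sequence-range class of a residue pair
#'
#' @param sep sequence separation `|i - j|` (positive integer, vectorized).
#' @return character vector over `"1","2","3","4","long"`; `"long"` means
#'   separation of at least 5, beyond which no preferred orientations are
#'   modelled.
#' @export
range_class <- function(sep) {
  stopifnot(all(sep >= 1L))
  ifelse(sep >= 5L, "long", as.character(sep))
}

.param_key <- function(a, b, range) paste(a, b, range, sep = ":")

.default_settings <- function(settings = list()) {
  utils::modifyList(list(min_support = 200L, interval_mass = 0.6,
                         max_mode = 12, max_dist = 14,
                         theta_quantile = 0.75, peak_floor = 0.1), settings)
}

#' Estimate contact parameters for one pair/range class
#'
#' The per-class core of [estimate_parameters()]: from observed CB-CB
#' distances (and, for oriented ranges, relative rotations) it (a) smooths
#' the distance distribution with a Gaussian kernel (Silverman bandwidth)
#' over (0, `max_dist`] A, locates the first interior local density maximum
#' below `max_mode` A whose height is at least `peak_floor` of the global
#' maximum, and takes as Euclidean contact interval the shortest interval
#' around that maximum holding `interval_mass` of the sub-`max_mode`
#' density, grown greedily toward the denser side but confined to the
#' mode's own density basin (between the nearest flanking local minima) so
#' the interval cannot absorb mass belonging to a longer-distance mode;
#' (b) estimates the preferred rotation as the chordal mean
#' quaternion over in-interval observations and sets the orientation
#' tolerance `theta_max` to the `theta_quantile` quantile of angular
#' deviations. `alpha_max`, the maximum orientation-induced distance
#' reduction, defaults to `min(d_lo, 0.5 * (d_hi - d_lo))`, which keeps the
#' pose distance non-negative.
#'
#' @param d numeric vector of observed interaction distances (Angstrom).
#' @param quat optional n x 4 matrix of relative rotations (quaternions),
#'   required for oriented ranges.
#' @param settings list overriding the estimation defaults.
#' @return a `pair_params` list: `d_lo`, `d_hi`, `q_pref` (or NULL),
#'   `theta_max` (or NULL), `alpha_max`, `support`.
#' @export
estimate_pair_params <- function(d, quat = NULL, settings = list()) {
  s <- .default_settings(settings)
  keep <- is.finite(d) & d > 0 & d <= s$max_dist
  d <- d[keep]
  if (!is.null(quat)) quat <- quat[keep, , drop = FALSE]
  if (length(d) < 2L) {
    if (length(d) == 1L) {
      # degenerate single observation: a 1 A band around it
      lo <- max(0.1, d - 0.5); hi <- d + 0.5
      return(structure(list(d_lo = lo, d_hi = hi, q_pref = NULL,
                            theta_max = NULL,
                            alpha_max = min(lo, 0.25), support = 1L),
                       class = "pair_params"))
    }
    stop("no usable distance observations")
  }
  dens <- stats::density(d, bw = "nrd0", from = 1e-3, to = s$max_dist, n = 512L)
  x <- dens$x; y <- dens$y
  sub <- x <= s$max_mode
  ys <- y[sub]; xs <- x[sub]
  m <- length(ys)
  # interior local maxima, with a height floor so far-tail numerical
  # plateaus of the kernel estimate are never mistaken for a contact mode
  is_max <- c(FALSE,
              ys[2:(m - 1L)] >= ys[1:(m - 2L)] & ys[2:(m - 1L)] > ys[3:m],
              FALSE)
  peaks <- which(is_max & ys >= s$peak_floor * max(ys))
  if (!length(peaks))
    stop("no density maximum below ", s$max_mode,
         " A; reference data look malformed")
  mode_i <- peaks[1L]
  # the mode's own density basin: bounded by the nearest local minima (or
  # the grid ends), so the contact interval cannot absorb density that
  # belongs to a different, longer-distance mode
  is_min <- c(TRUE,
              ys[2:(m - 1L)] <= ys[1:(m - 2L)] & ys[2:(m - 1L)] < ys[3:m],
              TRUE)
  mins <- which(is_min)
  b_lo <- max(mins[mins < mode_i], 1L)
  b_hi <- min(mins[mins > mode_i], m)
  # shortest interval around the mode holding interval_mass of the mode's
  # basin density, grown greedily toward the denser neighbour and confined
  # to the basin (for unimodal data the basin is the whole support, so this
  # reduces to the shortest interval with interval_mass of the total)
  target <- s$interval_mass * sum(ys[b_lo:b_hi])
  lo <- hi <- mode_i
  acc <- ys[mode_i]
  while (acc < target && (lo > b_lo || hi < b_hi)) {
    left <- if (lo > b_lo) ys[lo - 1L] else -Inf
    right <- if (hi < b_hi) ys[hi + 1L] else -Inf
    if (left >= right) { lo <- lo - 1L; acc <- acc + ys[lo] }
    else { hi <- hi + 1L; acc <- acc + ys[hi] }
  }
  d_lo <- max(xs[lo], 0.1)
  d_hi <- min(xs[hi], 20)
  if (d_hi <= d_lo) d_hi <- d_lo + 0.1
  q_pref <- NULL; theta_max <- NULL
  if (!is.null(quat)) {
    qin <- quat[d <= d_hi, , drop = FALSE]
    if (nrow(qin) >= 2L) {
      q_pref <- quat_mean(qin)
      theta <- quat_angle(qin, q_pref)
      theta_max <- max(1e-3, unname(stats::quantile(theta, s$theta_quantile)))
    }
  }
  structure(list(d_lo = d_lo, d_hi = d_hi, q_pref = q_pref,
                 theta_max = theta_max,
                 alpha_max = min(d_lo, 0.5 * (d_hi - d_lo)),
                 support = length(d)),
            class = "pair_params")
}

## Collect per-class observations from a list of conformations:
## distances <= max_dist for every pair, relative quaternions for ranges 2-4.
## Pair identity is canonicalized alphabetically; when swapped, the relative
## rotation is conjugated so stored rotations always point canonical->other.
.collect_observations <- function(confs, max_dist) {
  per_key <- list(); per_d <- list(); per_q <- list()
  for (ci in seq_along(confs)) {
    conf <- confs[[ci]]
    L <- length(conf$aa)
    ic <- interaction_coords(conf)
    dm <- as.matrix(stats::dist(ic))
    sel <- which(upper.tri(dm) & dm <= max_dist, arr.ind = TRUE)
    if (!nrow(sel)) next
    i <- sel[, 1L]; j <- sel[, 2L]   # upper triangle: i < j
    dv <- dm[sel]
    rc <- range_class(j - i)
    a <- conf$aa[i]; b <- conf$aa[j]
    swap <- a > b
    keys <- ifelse(swap, .param_key(b, a, rc), .param_key(a, b, rc))
    qmat <- matrix(NA_real_, length(i), 4L)
    ori <- rc %in% ORIENTED_RANGES
    if (any(ori)) {
      fr <- build_frames(conf)
      qres <- rot_to_quat(fr$rotation)
      qij <- quat_mult(quat_conj(qres[i[ori], , drop = FALSE]),
                       qres[j[ori], , drop = FALSE])
      sw <- swap[ori]
      qij[sw, 2:4] <- -qij[sw, 2:4]
      qmat[ori, ] <- qij
    }
    per_key[[ci]] <- c(keys, .param_key("ANY", "ANY", rc))
    per_d[[ci]] <- c(dv, dv)
    per_q[[ci]] <- rbind(qmat, qmat)
  }
  keys <- unlist(per_key)
  if (is.null(keys)) stop("no residue pairs within ", max_dist,
                          " A in the reference set")
  dall <- unlist(per_d)
  qall <- do.call(rbind, per_q)
  grp <- split(seq_along(keys), keys)
  obs_d <- lapply(grp, function(ix) dall[ix])
  obs_q <- lapply(grp, function(ix) {
    q <- qall[ix, , drop = FALSE]
    q <- q[!is.na(q[, 1L]), , drop = FALSE]
    if (nrow(q)) q else NULL
  })
  list(d = obs_d, q = obs_q)
}

#' Estimate a contact-parameter table from reference structures
#'
#' Scans every residue pair of every reference conformation, accumulates
#' distance and relative-orientation observations per (amino-acid pair,
#' range) class, and fits [estimate_pair_params()] to each class with at
#' least `min_support` observations. Pooled `(ANY, ANY, range)` entries are
#' always fitted and serve as backoff, so every query resolves.
#'
#' @param reference a list of `conformation` objects (or an `ensemble`).
#' @param settings estimation settings; see [estimate_pair_params()].
#' @return a `contact_param_table`.
#' @export
estimate_parameters <- function(reference, settings = list()) {
  if (inherits(reference, "ensemble")) reference <- reference$conformations
  if (!length(reference)) stop("empty reference set")
  s <- .default_settings(settings)
  obs <- .collect_observations(reference, s$max_dist)
  entries <- list()
  for (key in names(obs$d)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1L]]
    pooled <- parts[1L] == "ANY"
    n_obs <- length(obs$d[[key]])
    if (!pooled && n_obs < s$min_support) next
    q <- if (parts[3L] %in% ORIENTED_RANGES) obs$q[[key]] else NULL
    entries[[key]] <- tryCatch(
      estimate_pair_params(obs$d[[key]], q, s),
      error = function(e) {
        if (pooled) stop("pooled class ", key, ": ", conditionMessage(e))
        NULL
      })
  }
  entries <- entries[!vapply(entries, is.null, logical(1L))]
  for (rc in RANGE_LEVELS) {
    if (is.null(entries[[.param_key("ANY", "ANY", rc)]]))
      stop("reference set yields no pooled entry for range ", rc)
  }
  structure(list(entries = entries,
                 metadata = list(n_structures = length(reference),
                                 settings = s,
                                 created = format(Sys.time(), "%Y-%m-%d"))),
            class = "contact_param_table")
}

#' @export
print.contact_param_table <- function(x, ...) {
  cat("Contact parameter table:", length(x$entries), "classes (",
      sum(!grepl("^ANY", names(x$entries))), "pair-specific )\n")
  cat("Estimated from", x$metadata$n_structures, "reference structures\n")
  invisible(x)
}

#' Resolve contact parameters for a residue pair
#'
#' Looks up the (aa_i, aa_j, range) entry with alphabetical canonicalization
#' (conjugating the preferred rotation when the query order is swapped) and
#' falls back to the pooled `(ANY, ANY, range)` entry below the support
#' threshold.
#'
#' @param table a `contact_param_table`.
#' @param aa_i,aa_j 1-letter amino-acid codes in pair order `i < j`.
#' @param range a range class (`"1"`, `"2"`, `"3"`, `"4"`, `"long"`).
#' @return a `pair_params` object oriented for the (i, j) query order.
#' @export
resolve_params <- function(table, aa_i, aa_j, range) {
  swap <- aa_i > aa_j
  key <- if (swap) .param_key(aa_j, aa_i, range) else .param_key(aa_i, aa_j, range)
  p <- table$entries[[key]]
  if (is.null(p)) p <- table$entries[[.param_key("ANY", "ANY", range)]]
  if (is.null(p)) stop("no parameters resolvable for range ", range)
  if (swap && !is.null(p$q_pref)) p$q_pref <- as.vector(quat_conj(p$q_pref))
  p
}

#' Relative pose of two residue frames
#'
#' @param frame_i,frame_j residue frames: lists with a 3x3 `rotation` (or
#'   bare 3x3 matrices).
#' @param d Euclidean interaction distance (Angstrom).
#' @param params resolved `pair_params` for the pair; when they carry no
#'   preferred rotation (range 1 / long) `theta` is `NA` and downstream
#'   orientation terms vanish.
#' @return list with `d` and `theta` (geodesic angle to the preferred
#'   rotation, radians in `[0, pi]`).
#' @export
relative_pose <- function(frame_i, frame_j, d, params) {
  Ri <- if (is.list(frame_i)) frame_i$rotation else frame_i
  Rj <- if (is.list(frame_j)) frame_j$rotation else frame_j
  theta <- NA_real_
  if (!is.null(params$q_pref)) {
    qij <- rot_to_quat(crossprod(Ri, Rj))
    theta <- quat_angle(qij, params$q_pref)
  }
  list(d = d, theta = theta)
}

## Smooth distance cutoff for the orientation bonus: 1 up to d_hi, cosine
## fade to 0 over [d_hi, d_hi + 2].
.orient_cutoff <- function(d, d_hi, fade = 2) {
  ifelse(d <= d_hi, 1,
         ifelse(d >= d_hi + fade, 0,
                0.5 * (1 + cos(pi * (d - d_hi) / fade))))
}

#' Relative pose distance
#'
#' Reduces the Euclidean distance by an orientation bonus
#' `alpha_max * c(d) * s(theta)` where `s(theta) = max(0, 1 - theta/theta_max)`
#' and `c(d)` fades from 1 at `d_hi` to 0 at `d_hi + 2` A. For range 1 and
#' long-range pairs (no preferred rotation) the Euclidean distance is
#' returned unchanged. Always satisfies `0 <= d' <= d`.
#'
#' @param pose list with `d` and `theta` as returned by [relative_pose()]
#'   (vectorized over both).
#' @param params resolved `pair_params`.
#' @param range the pair's range class.
#' @return the pose distance d' (Angstrom).
#' @export
pose_distance <- function(pose, params, range) {
  d <- pose$d
  if (!(range %in% ORIENTED_RANGES) || is.null(params$q_pref) ||
      is.null(params$theta_max))
    return(d)
  th <- pose$theta
  s_aff <- ifelse(is.na(th), 0, pmax(0, 1 - th / params$theta_max))
  # clamp at zero: for d below alpha_max the full bonus would overshoot
  pmax(0, d - params$alpha_max * .orient_cutoff(d, params$d_hi) * s_aff)
}

#' Contact value from a pose distance
#'
#' The decreasing cosine ramp: 1 for `d' <= d_lo`, 0 for `d' >= d_hi`, and
#' `0.5 * (1 + cos(pi (d' - d_lo)/(d_hi - d_lo)))` in between -- smooth,
#' strictly decreasing across the contact interval, continuous at both
#' edges.
#'
#' @param d_prime pose distance(s), >= 0.
#' @param params resolved `pair_params` carrying `d_lo`, `d_hi`.
#' @return contact value(s) in `[0, 1]`.
#' @export
contact_value <- function(d_prime, params) {
  lo <- params$d_lo; hi <- params$d_hi
  w <- 0.5 * (1 + cos(pi * (d_prime - lo) / (hi - lo)))
  ifelse(d_prime <= lo, 1, ifelse(d_prime >= hi, 0, w))
}

#' Contact function for one residue pair of a conformation
#'
#' Composes distance, relative pose, pose distance and contact value with
#' parameter resolution (including pooled backoff). Deterministic.
#'
#' @param conf a `conformation`.
#' @param i,j residue indices with `i < j`.
#' @param table a `contact_param_table`.
#' @param frames optional precomputed [build_frames()] result.
#' @return the contact value omega in `[0, 1]`.
#' @export
pair_contact <- function(conf, i, j, table, frames = NULL) {
  stopifnot(i < j)
  rc <- range_class(j - i)
  p <- resolve_params(table, conf$aa[i], conf$aa[j], rc)
  d <- interaction_distance(conf, i, j)
  if (rc %in% ORIENTED_RANGES && !is.null(p$q_pref)) {
    if (is.null(frames)) frames <- build_frames(conf)
    pose <- relative_pose(frames$rotation[, , i], frames$rotation[, , j], d, p)
  } else {
    pose <- list(d = d, theta = NA_real_)
  }
  contact_value(pose_distance(pose, p, rc), p)
}

#' Serialize a contact-parameter table to JSON
#'
#' Entries are written with full double precision so that a round-tripped
#' table reproduces contact values exactly.
#'
#' @param table a `contact_param_table`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_param_table <- function(table, path) {
  ent <- lapply(names(table$entries), function(key) {
    p <- table$entries[[key]]
    parts <- strsplit(key, ":", fixed = TRUE)[[1L]]
    list(pair = parts[1:2], range = parts[3L], d_lo = p$d_lo, d_hi = p$d_hi,
         quaternion = if (is.null(p$q_pref)) NULL else as.vector(p$q_pref),
         theta_max = p$theta_max, alpha_max = p$alpha_max,
         support_count = p$support)
  })
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(list(entries = ent, metadata = table$metadata),
                       path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' Read a contact-parameter table from JSON
#'
#' @param path file written by [write_param_table()].
#' @return a `contact_param_table`.
#' @export
read_param_table <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  entries <- list()
  for (e in raw$entries) {
    key <- .param_key(e$pair[[1L]], e$pair[[2L]], e$range)
    q <- if (is.null(e$quaternion)) NULL else unlist(e$quaternion)
    entries[[key]] <- structure(
      list(d_lo = e$d_lo, d_hi = e$d_hi, q_pref = q,
           theta_max = e$theta_max, alpha_max = e$alpha_max,
           support = e$support_count),
      class = "pair_params")
  }
  structure(list(entries = entries,
                 metadata = lapply(raw$metadata, identity)),
            class = "contact_param_table")
}

#' Plot the contact curve of one parameter class
#'
#' Contact value against Euclidean distance at a set of orientation
#' deviations, visualizing how alignment with the preferred rotation shifts
#' the curve left edge of the contact interval.
#'
#' @param table a `contact_param_table`.
#' @param aa_i,aa_j amino-acid codes (default pooled class).
#' @param range range class (default `"4"`).
#' @param thetas orientation deviations (radians) to draw.
#' @return invisibly, the matrix of curve values.
#' @export
plot_contact_curve <- function(table, aa_i = "ANY", aa_j = "ANY",
                               range = "4", thetas = c(0, 0.5, 1, Inf)) {
  p <- resolve_params(table, aa_i, aa_j, range)
  d <- seq(0.5, p$d_hi + 3, length.out = 300L)
  curves <- sapply(thetas, function(th) {
    pose <- list(d = d, theta = rep(th, length(d)))
    contact_value(pose_distance(pose, p, range), p)
  })
  graphics::matplot(d, curves, type = "l", lty = 1,
                    xlab = "CB-CB distance (A)", ylab = "contact value",
                    main = sprintf("%s-%s, range %s", aa_i, aa_j, range))
  graphics::legend("topright", legend = sprintf("theta = %.2g", thetas),
                   col = seq_along(thetas), lty = 1, cex = 0.8)
  invisible(curves)
}
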