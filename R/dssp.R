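# Native secondary-structure assignment following the Kabsch-Sander
# hydrogen-bond rules: the amide hydrogen is reconstructed geometrically,
# backbone H-bonds are detected with the electrostatic energy model, and the
# usual pattern rules yield the 8-state alphabet H/G/I/E/B/T/S/"-", collapsed
# to helix/strand/coil for propensity reporting.

#' Reconstruct amide hydrogens
#'
#' H is placed 1.01 A from N along the bisector of the N->CA and N->C(prev)
#' directions, opposite the preceding carbonyl -- the standard geometric
#' reconstruction when hydrogens are absent from the model. The first
#' residue (no preceding carbonyl) and prolines (no amide H) get NA.
#'
#' @param conf a `conformation` with N, CA, C present.
#' @return an L x 3 matrix of H positions (NA rows where undefined).
#' @keywords internal
reconstruct_amide_h <- function(conf) {
  N <- conf$coords$N; CA <- conf$coords$CA; C <- conf$coords$C
  L <- nrow(N)
  H <- matrix(NA_real_, L, 3L)
  for (i in 2:L) {
    if (conf$aa[i] == "P") next
    d <- unitv(unitv(N[i, ] - C[i - 1L, ]) + unitv(N[i, ] - CA[i, ]))
    H[i, ] <- N[i, ] + 1.01 * d
  }
  H
}

## Backbone H-bond matrix: hb[i, j] is TRUE when the N-H of residue i
## donates to the C=O of residue j, using the Kabsch-Sander energy
## E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol and the
## -0.5 kcal/mol threshold. Bonds to the own and preceding residue are
## excluded (the donor H is covalently adjacent to the preceding carbonyl).
.hbond_matrix <- function(conf) {
  N <- conf$coords$N; C <- conf$coords$C; O <- conf$coords$O
  L <- nrow(N)
  H <- reconstruct_amide_h(conf)
  hb <- matrix(FALSE, L, L)
  q <- 0.084 * 332
  for (i in seq_len(L)) {
    if (anyNA(H[i, ])) next
    for (j in seq_len(L)) {
      if (j == i || j == i - 1L) next
      if (anyNA(O[j, ])) next
      r_on <- vnorm(O[j, ] - N[i, ])
      if (r_on > 5.2) next  # beyond any plausible H-bond; saves the rest
      e <- q * (1 / r_on + 1 / vnorm(C[j, ] - H[i, ]) -
                  1 / vnorm(O[j, ] - H[i, ]) - 1 / vnorm(C[j, ] - N[i, ]))
      hb[i, j] <- e < -0.5
    }
  }
  hb
}

#' Secondary structure of a conformation
#'
#' Eight-state assignment from backbone hydrogen-bond patterns: n-turns give
#' helices (two consecutive 4-turns = H, 3-turns = G, 5-turns = I), bridge
#' patterns give strands (ladders = E, isolated bridges = B), remaining
#' turn-spanned residues = T, sharp CA-trace bends = S, else "-". Priority
#' H, E, B, G, I, T, S. Chains shorter than 5 residues are returned all
#' coil with a warning.
#'
#' @param conf a `conformation` with N, CA, C, O present.
#' @return character vector of length L over H/G/I/E/B/T/S/-.
#' @export
secondary_structure <- function(conf) {
  L <- length(conf$aa)
  if (L < 5L) {
    warning("chain shorter than 5 residues: all coil")
    return(rep("-", L))
  }
  hb <- .hbond_matrix(conf)
  ss <- rep("-", L)

  # n-turns: turn_n[i] when the N-H of residue i+n bonds the C=O of i
  turn <- list()
  for (n in 3:5) {
    t <- rep(FALSE, L)
    idx <- seq_len(L - n)
    t[idx] <- hb[cbind(idx + n, idx)]
    turn[[as.character(n)]] <- t
  }

  # bridges: parallel / antiparallel patterns for |i - j| >= 3
  bridge <- matrix(0L, L, L)  # 1 = parallel, 2 = antiparallel
  for (i in 2:(L - 1L)) {
    for (j in 2:(L - 1L)) {
      if (abs(i - j) < 3L) next
      par <- (hb[j, i - 1L] && hb[i + 1L, j]) ||
             (hb[i, j - 1L] && hb[j + 1L, i])
      anti <- (hb[i, j] && hb[j, i]) ||
              (hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
      if (par) bridge[i, j] <- 1L else if (anti) bridge[i, j] <- 2L
    }
  }
  # ladders: consecutive bridges of the same type; residues in ladders of
  # length >= 2 are E, isolated bridges are B
  in_e <- rep(FALSE, L); in_b <- rep(FALSE, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (!bridge[i, j]) next
      ty <- bridge[i, j]
      ext <- (i > 1L && j > 1L && bridge[i - 1L, j - 1L] == ty) ||
             (i < L && j < L && bridge[i + 1L, j + 1L] == ty) ||
             (i > 1L && j < L && bridge[i - 1L, j + 1L] == ty) ||
             (i < L && j > 1L && bridge[i + 1L, j - 1L] == ty)
      if (ext) in_e[i] <- TRUE else in_b[i] <- TRUE
    }
  }

  # helices: two consecutive n-turns start a minimal helix at i covering
  # residues i .. i+n-1
  mark_helix <- function(n) {
    m <- rep(FALSE, L)
    t <- turn[[as.character(n)]]
    for (i in 2:(L - n)) {
      if (t[i - 1L] && t[i]) m[i:(i + n - 1L)] <- TRUE
    }
    m
  }
  is_h <- mark_helix(4L)
  is_g <- mark_helix(3L)
  is_i <- mark_helix(5L)

  # turn state: residues strictly inside any single n-turn
  is_t <- rep(FALSE, L)
  for (n in 3:5) {
    t <- turn[[as.character(n)]]
    for (i in which(t)) {
      span <- (i + 1L):(i + n - 1L)
      is_t[span[span <= L]] <- TRUE
    }
  }

  # bend: CA-trace direction change above 70 degrees
  is_s <- rep(FALSE, L)
  ca <- conf$coords$CA
  for (i in 3:(L - 2L)) {
    u <- ca[i, ] - ca[i - 2L, ]
    v <- ca[i + 2L, ] - ca[i, ]
    ang <- acos(pmin(1, pmax(-1, sum(u * v) / (vnorm(u) * vnorm(v)))))
    is_s[i] <- ang > deg2rad(70)
  }

  ss[is_s] <- "S"
  ss[is_t] <- "T"
  ss[is_i] <- "I"
  ss[is_g] <- "G"
  ss[in_b] <- "B"
  ss[in_e] <- "E"
  ss[is_h] <- "H"
  ss
}

#' Collapse 8-state secondary structure to helix/strand/coil
#'
#' @param ss character vector over H/G/I/E/B/T/S/-.
#' @return character vector over `"helix"`, `"strand"`, `"coil"`.
#' @export
collapse_ss <- function(ss) {
  out <- rep("coil", length(ss))
  out[ss %in% c("H", "G", "I")] <- "helix"
  out[ss %in% c("E", "B")] <- "strand"
  out
}
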