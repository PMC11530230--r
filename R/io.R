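# Ensemble input/output and per-residue geometry: conformations are stored as
# per-atom coordinate matrices (N, CA, C, O, CB; rows of NA where an atom is
# absent), an ensemble is an ordered list of conformations sharing one
# sequence. Residue indexing is 1-based and sequence-contiguous after chain
# extraction; insertion codes are collapsed and alternate locations resolved
# by bio3d on read.

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "CB")

new_conformation <- function(aa, coords, residue_ids = seq_along(aa)) {
  stopifnot(is.character(aa), all(names(coords) %in% BACKBONE_ATOMS))
  structure(list(aa = aa, coords = coords, residue_ids = residue_ids),
            class = "conformation")
}

#' Validate a conformation
#'
#' Checks the structural invariants assumed throughout the package: finite
#' coordinates for every present atom, a CA atom in every residue, chain
#' length of at least 5 residues, and consecutive CA-CA distances within
#' 2.0-4.8 Angstrom (a violation of the last is reported as a warning, since
#' chain breaks are common in deposited models and only degrade, not
#' invalidate, contact features).
#'
#' @param conf a `conformation` object.
#' @param min_length minimum chain length enforced (default 5).
#' @return the conformation, invisibly; errors or warns otherwise.
#' @export
validate_conformation <- function(conf, min_length = 5L) {
  L <- length(conf$aa)
  if (L < min_length)
    stop("chain length ", L, " is below the minimum of ", min_length)
  ca <- conf$coords$CA
  if (is.null(ca) || nrow(ca) != L || anyNA(ca))
    stop("every residue must have a CA atom")
  for (at in names(conf$coords)) {
    m <- conf$coords[[at]]
    if (any(is.infinite(m) | is.nan(m)))
      stop("non-finite coordinates in atom ", at)
  }
  if (L > 1L) {
    d <- rows_norm(ca[-1L, , drop = FALSE] - ca[-L, , drop = FALSE])
    out <- which(d < 2.0 | d > 4.8)
    if (length(out))
      warning("consecutive CA-CA distance outside [2.0, 4.8] A at ",
              length(out), " position(s), first at residue ", out[1L])
  }
  invisible(conf)
}

new_ensemble <- function(sequence, conformations, provenance = character()) {
  stopifnot(length(conformations) >= 1L)
  L <- nchar(sequence)
  for (k in seq_along(conformations)) {
    if (paste(conformations[[k]]$aa, collapse = "") != sequence)
      stop("conformation ", k, " does not match the ensemble sequence")
  }
  structure(list(sequence = sequence, conformations = conformations,
                 provenance = provenance, n = length(conformations), L = L),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("Conformational ensemble: n =", x$n, "conformations, L =", x$L,
      "residues\n")
  cat("Sequence:", x$sequence, "\n")
  if (length(x$provenance)) cat("Source:", paste(x$provenance, collapse = ", "), "\n")
  invisible(x)
}

## Extract per-residue atom coordinate matrices from a bio3d atom table plus
## one xyz row. Residues are taken in file order; insertion codes collapse
## into the sequential index.
## Map atom-table rows to their xyz column triplets (row r -> columns
## (r-1)*3 + 1:3 of the matching xyz row vector).
.xyz_cols <- function(rows) {
  base <- (rows - 1L) * 3L
  as.vector(rbind(base + 1L, base + 2L, base + 3L))
}

.atoms_from_bio3d <- function(atom, xyz) {
  key <- paste(atom$resno, atom$insert, sep = "_")
  resk <- unique(key)
  L <- length(resk)
  idx <- match(key, resk)
  aa3 <- atom$resid[!duplicated(key)]
  aa <- bio3d::aa321(aa3)
  coords <- lapply(BACKBONE_ATOMS, function(at) {
    m <- matrix(NA_real_, L, 3L)
    sel <- which(atom$elety == at)
    if (length(sel)) {
      sel <- sel[!duplicated(idx[sel])]  # first occurrence per residue
      m[idx[sel], ] <- matrix(xyz[.xyz_cols(sel)], ncol = 3L, byrow = TRUE)
    }
    m
  })
  names(coords) <- BACKBONE_ATOMS
  list(aa = aa, coords = coords)
}

.load_pdb_models <- function(path, chain) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = TRUE, verbose = FALSE)
  atom <- pdb$atom
  keep <- atom$type == "ATOM" & atom$elety %in% BACKBONE_ATOMS
  chains <- unique(atom$chain[keep])
  if (is.null(chain)) {
    if (length(chains) > 1L)
      stop("file ", path, " contains chains ", paste(chains, collapse = ", "),
           "; select one with chain_id (chains are never concatenated)")
    chain <- chains[1L]
  }
  keep <- keep & (atom$chain %in% chain)
  if (!any(keep)) stop("no backbone atoms for chain ", chain, " in ", path)
  rows <- which(keep)
  atom <- atom[rows, , drop = FALSE]
  xyz <- pdb$xyz[, .xyz_cols(rows), drop = FALSE]
  lapply(seq_len(nrow(xyz)), function(m) .atoms_from_bio3d(atom, xyz[m, ]))
}

.load_dcd <- function(path, topology, chain) {
  if (is.null(topology))
    stop("a PDB topology file is required to read trajectory ", path)
  pdb <- bio3d::read.pdb(topology, rm.alt = TRUE, verbose = FALSE)
  traj <- bio3d::read.dcd(path, verbose = FALSE)
  atom <- pdb$atom
  keep <- atom$type == "ATOM" & atom$elety %in% BACKBONE_ATOMS
  chains <- unique(atom$chain[keep])
  if (is.null(chain)) {
    if (length(chains) > 1L)
      stop("topology contains chains ", paste(chains, collapse = ", "),
           "; select one with chain_id")
    chain <- chains[1L]
  }
  keep <- keep & (atom$chain %in% chain)
  rows <- which(keep)
  atom <- atom[rows, , drop = FALSE]
  xyz <- traj[, .xyz_cols(rows), drop = FALSE]
  lapply(seq_len(nrow(xyz)), function(m) .atoms_from_bio3d(atom, xyz[m, ]))
}

#' Load a conformational ensemble
#'
#' Reads one or more multi-model PDB files, or DCD trajectories with a PDB
#' topology, into a single ensemble. Models/frames are concatenated in input
#' order. All inputs must describe the same single protein chain; a sequence
#' mismatch across files is a hard error naming the first differing residue.
#'
#' @param paths character vector of input files (multi-model PDB or DCD).
#' @param topology optional PDB topology, required for DCD inputs.
#' @param chain chain identifier; may be `NULL` only when the file holds a
#'   single chain (multiple chains are never silently concatenated).
#' @param stride keep every `stride`-th model (subsampling, default 1).
#' @param first,last first and last model to keep, applied per file before
#'   striding.
#' @return an `ensemble` object with fields `sequence`, `conformations`,
#'   `provenance`, `n`, `L`.
#' @export
#' @examples
#' ens <- make_ensemble(list(family_spec("coil", count = 2)),
#'                      sequence = strrep("A", 10), seed = 1)$ensemble
#' f <- tempfile(fileext = ".pdb")
#' write_ensemble_pdb(ens, f)
#' ens2 <- load_ensemble(f)
#' ens2$n
load_ensemble <- function(paths, topology = NULL, chain = NULL, stride = 1L,
                          first = 1L, last = Inf) {
  stopifnot(length(paths) >= 1L, stride >= 1L)
  models <- list()
  for (p in paths) {
    ext <- tolower(tools::file_ext(p))
    raw <- if (ext == "dcd") .load_dcd(p, topology, chain)
           else .load_pdb_models(p, chain)
    hi <- min(length(raw), last)
    raw <- raw[seq(from = first, to = hi, by = stride)]
    models <- c(models, raw)
  }
  if (!length(models)) stop("no models found in input")
  seqs <- vapply(models, function(m) paste(m$aa, collapse = ""), character(1L))
  if (length(unique(seqs)) > 1L) {
    ref <- strsplit(seqs[1L], "")[[1L]]
    alt <- strsplit(seqs[seqs != seqs[1L]][1L], "")[[1L]]
    n <- min(length(ref), length(alt))
    pos <- which(ref[seq_len(n)] != alt[seq_len(n)])
    pos <- if (length(pos)) pos[1L] else n + 1L
    stop("inconsistent sequences across inputs; first mismatch at residue ",
         pos, " (", ref[min(pos, length(ref))], " vs ",
         alt[min(pos, length(alt))], ")")
  }
  confs <- lapply(models, function(m) {
    cf <- new_conformation(m$aa, m$coords)
    validate_conformation(cf)
    cf
  })
  new_ensemble(seqs[1L], confs, provenance = basename(paths))
}

#' Write an ensemble as a canonical multi-model PDB
#'
#' @param ens an `ensemble`.
#' @param file output path.
#' @param indices optional conformation indices to write (default all).
#' @return `file`, invisibly.
#' @export
write_ensemble_pdb <- function(ens, file, indices = NULL) {
  if (is.null(indices)) indices <- seq_len(ens$n)
  conf1 <- ens$conformations[[indices[1L]]]
  L <- ens$L
  present <- lapply(BACKBONE_ATOMS, function(at) {
    m <- conf1$coords[[at]]
    if (is.null(m)) integer() else which(stats::complete.cases(m))
  })
  names(present) <- BACKBONE_ATOMS
  resno <- integer(); elety <- character(); resid3 <- character()
  for (i in seq_len(L)) {
    for (at in BACKBONE_ATOMS) {
      if (i %in% present[[at]]) {
        resno <- c(resno, i); elety <- c(elety, at)
        resid3 <- c(resid3, bio3d::aa123(conf1$aa[i]))
      }
    }
  }
  na <- length(resno)
  xyz <- matrix(0, length(indices), 3L * na)
  for (m in seq_along(indices)) {
    cf <- ens$conformations[[indices[m]]]
    row <- numeric(0)
    for (i in seq_len(L)) for (at in BACKBONE_ATOMS)
      if (i %in% present[[at]]) row <- c(row, cf$coords[[at]][i, ])
    xyz[m, ] <- row
  }
  elesy <- substr(elety, 1L, 1L)
  pdb <- list(atom = data.frame(type = "ATOM", eleno = seq_len(na),
                                elety = elety, alt = "", resid = resid3,
                                chain = "A", resno = resno, insert = "",
                                o = 1, b = 0, segid = "", elesy = elesy,
                                charge = ""),
              xyz = xyz)
  class(pdb) <- "pdb"
  bio3d::write.pdb(pdb, file = file, xyz = xyz)
  invisible(file)
}

#' Build per-residue local frames
#'
#' Each residue gets an orthonormal right-handed frame from its backbone:
#' x = unit(CA->C), z = unit(x cross unit(CA->N)), y = z cross x, with the CA
#' position as origin. The construction uses only the three universally
#' present backbone atoms and is equivariant under global rigid motion.
#'
#' @param conf a `conformation` with N, CA, C present for every residue.
#' @return a list with `origin` (L x 3 matrix of CA positions) and `rotation`
#'   (3 x 3 x L array; columns of each matrix are the frame axes x, y, z).
#' @export
build_frames <- function(conf) {
  N <- conf$coords$N; CA <- conf$coords$CA; C <- conf$coords$C
  if (is.null(N) || is.null(C) || anyNA(N) || anyNA(C) || anyNA(CA))
    stop("N, CA and C atoms are required for every residue to build frames")
  L <- nrow(CA)
  x <- rows_unit(C - CA)
  u <- rows_unit(N - CA)
  zraw <- rows_cross(x, u)
  zn <- rows_norm(zraw)
  if (any(zn < 1e-6))
    stop("collinear N-CA-C backbone at residue ", which(zn < 1e-6)[1L])
  z <- zraw / zn
  y <- rows_cross(z, x)
  rot <- array(0, dim = c(3L, 3L, L))
  rot[, 1L, ] <- t(x); rot[, 2L, ] <- t(y); rot[, 3L, ] <- t(z)
  list(origin = CA, rotation = rot)
}

## Interaction coordinates: CB, substituting CA where CB is absent (glycine
## or missing side chain).
interaction_coords <- function(conf) {
  cb <- conf$coords$CB
  ca <- conf$coords$CA
  if (is.null(cb)) return(ca)
  miss <- !stats::complete.cases(cb)
  cb[miss, ] <- ca[miss, ]
  cb
}

#' Inter-residue interaction distance
#'
#' Euclidean distance between the CB atoms of residues `i` and `j`, with CA
#' substituted where CB is absent (glycine, or missing in the model).
#' Symmetric in its arguments; the diagonal is excluded.
#'
#' @param conf a `conformation`.
#' @param i,j distinct residue indices in `[1, L]`.
#' @return distance in Angstrom.
#' @export
interaction_distance <- function(conf, i, j) {
  L <- length(conf$aa)
  if (any(c(i, j) < 1L) || any(c(i, j) > L)) stop("residue index out of range")
  if (i == j) stop("interaction distance is undefined for i == j")
  ic <- interaction_coords(conf)
  vnorm(ic[i, ] - ic[j, ])
}
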