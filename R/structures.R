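## Domain containers: molecular structures and trajectories.
##
## A MolecularStructure is a light S3 wrapper around an atom table in the
## style of bio3d's pdb$atom data.frame, with optional per-atom geometry
## (vdW radius) and energetics (partial charge, Lennard-Jones) columns.

ATOM_COLUMNS <- c("type", "serial", "name", "altloc", "resname", "chain",
                  "resnum", "x", "y", "z", "occupancy", "bfactor", "element",
                  "radius", "charge", "eps", "rmin_half")

#' Create a molecular structure
#'
#' Builds the package's structure container from an atom table. Most users
#' obtain structures from [read_pdb()] or the synthetic generators rather
#' than calling this directly.
#'
#' @param atoms data.frame with at least columns `name`, `element`,
#'   `resname`, `resnum`, `chain`, `x`, `y`, `z`. Missing bookkeeping
#'   columns (`type`, `serial`, `altloc`, `occupancy`, `bfactor`, `radius`,
#'   `charge`, `eps`, `rmin_half`) are filled with defaults.
#' @param bonds optional two-column integer matrix of atom-index pairs.
#' @return an object of class `mol_structure`.
#' @export
molecular_structure <- function(atoms, bonds = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("name", "element", "resname", "resnum", "chain", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stopf("atom table lacks columns: %s", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (is.null(atoms$type)) atoms$type <- "ATOM"
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$bfactor)) atoms$bfactor <- 0
  if (is.null(atoms$radius)) atoms$radius <- NA_real_
  if (is.null(atoms$charge)) atoms$charge <- NA_real_
  if (is.null(atoms$eps)) atoms$eps <- NA_real_
  if (is.null(atoms$rmin_half)) atoms$rmin_half <- NA_real_
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (n > 0 && !all(is.finite(xyz))) stopf("non-finite atom coordinates")
  if (any(!is.na(atoms$radius) & atoms$radius <= 0))
    stopf("vdW radii must be positive")
  if (any(!is.na(atoms$eps) & atoms$eps < 0))
    stopf("Lennard-Jones epsilon must be non-negative")
  atoms <- atoms[, ATOM_COLUMNS]
  rownames(atoms) <- NULL
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (n > 0 && (any(bonds < 1) || any(bonds > n)))
      stopf("bond indices out of range")
  }
  structure(list(atoms = atoms, bonds = bonds), class = "mol_structure")
}

#' Number of atoms in a structure or trajectory topology
#' @param x a `mol_structure` or `mol_trajectory`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "mol_trajectory")) x <- x$topology
  nrow(x$atoms)
}

#' Atom coordinates as an n x 3 matrix
#' @param x a `mol_structure`.
#' @return numeric matrix with one row per atom (Angstrom).
#' @export
coords <- function(x) {
  unname(as.matrix(x$atoms[, c("x", "y", "z")]))
}

#' Replace atom coordinates
#' @param x a `mol_structure`.
#' @param value n x 3 numeric matrix.
#' @return the modified structure.
#' @export
`coords<-` <- function(x, value) {
  value <- as.matrix(value)
  if (!all(dim(value) == c(n_atoms(x), 3))) stopf("coordinate dimensions must be %d x 3", n_atoms(x))
  if (!all(is.finite(value))) stopf("non-finite coordinates")
  x$atoms$x <- value[, 1]; x$atoms$y <- value[, 2]; x$atoms$z <- value[, 3]
  x
}

#' @export
print.mol_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("mol_structure: %d atoms, %d residues, chains: %s\n",
              nrow(a), length(unique(paste(a$chain, a$resnum))),
              paste(sort(unique(a$chain)), collapse = " ")))
  if (any(a$type == "HETATM"))
    cat(sprintf("  HETATM residues: %s\n",
                paste(unique(a$resname[a$type == "HETATM"]), collapse = " ")))
  invisible(x)
}

#' Residue index of a structure
#'
#' Maps each (chain, residue number) pair to the atom indices it spans.
#'
#' @param structure a `mol_structure`.
#' @return named list of integer vectors; names are `"<chain>:<resnum>"`.
#' @export
residue_index <- function(structure) {
  key <- paste(structure$atoms$chain, structure$atoms$resnum, sep = ":")
  split(seq_len(nrow(structure$atoms)), factor(key, levels = unique(key)))
}

#' Create a trajectory
#'
#' @param topology `mol_structure` shared by all frames.
#' @param frames numeric array of dimension `c(n_atoms, 3, n_frames)`, or a
#'   list of n x 3 coordinate matrices.
#' @param box optional per-frame orthorhombic box lengths, an
#'   `n_frames x 3` matrix or a length-3 vector recycled to all frames (Angstrom).
#' @return an object of class `mol_trajectory`.
#' @export
trajectory <- function(topology, frames, box = NULL) {
  stopifnot(inherits(topology, "mol_structure"))
  na <- n_atoms(topology)
  if (is.list(frames)) {
    nf <- length(frames)
    arr <- array(NA_real_, c(na, 3, nf))
    for (i in seq_len(nf)) {
      f <- as.matrix(frames[[i]])
      if (!all(dim(f) == c(na, 3)))
        stopf("frame %d has %d atoms; topology has %d", i, nrow(f), na)
      arr[, , i] <- f
    }
    frames <- arr
  }
  if (length(dim(frames)) != 3 || dim(frames)[1] != na || dim(frames)[2] != 3)
    stopf("frames must be an n_atoms x 3 x n_frames array")
  if (!all(is.finite(frames))) stopf("non-finite trajectory coordinates")
  if (!is.null(box)) {
    if (is.null(dim(box))) box <- matrix(box, nrow = dim(frames)[3], ncol = 3, byrow = TRUE)
    box <- as.matrix(box)
    if (nrow(box) != dim(frames)[3]) stopf("box rows must equal frame count")
  }
  structure(list(topology = topology, coords = frames, box = box),
            class = "mol_trajectory")
}

#' Number of frames in a trajectory
#' @param trj a `mol_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(trj) dim(trj$coords)[3]

#' Coordinates of one frame
#' @param trj a `mol_trajectory`.
#' @param i frame index.
#' @return n x 3 coordinate matrix.
#' @export
frame_coords <- function(trj, i) {
  if (i < 1 || i > n_frames(trj)) stopf("frame index %d out of range", i)
  trj$coords[, , i]
}

#' Extract one frame as a structure
#' @param trj a `mol_trajectory`.
#' @param i frame index.
#' @return `mol_structure` with the topology's atom table and frame i coordinates.
#' @export
frame_structure <- function(trj, i) {
  s <- trj$topology
  coords(s) <- frame_coords(trj, i)
  s
}

#' @export
print.mol_trajectory <- function(x, ...) {
  cat(sprintf("mol_trajectory: %d frames x %d atoms%s\n", n_frames(x), n_atoms(x),
              if (!is.null(x$box)) " (periodic box)" else ""))
  invisible(x)
}
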