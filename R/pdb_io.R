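## PDB and XYZ readers/writers. Fixed-column PDB parsing and writing are
## delegated to bio3d; this layer adds the package's altloc policy
## (highest occupancy), chain filtering, multi-model trajectories, and
## strict validation with informative errors.

## Pre-scan ATOM/HETATM coordinate columns so parse failures name the line.
check_pdb_coordinates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  idx <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in idx) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (any(is.na(xyz)))
      stopf("malformed coordinate columns at line %d of %s", i, path)
  }
  invisible(TRUE)
}

## Resolve altloc duplicates: keep the highest-occupancy record per
## (chain, resnum, insert, name) group; ties broken by altloc label order.
resolve_altloc <- function(atom) {
  alt <- atom$alt
  alt[is.na(alt)] <- ""
  key <- paste(atom$chain, atom$resno, atom$insert %||% "", atom$elety, sep = "\r")
  keep <- rep(TRUE, nrow(atom))
  for (g in split(seq_len(nrow(atom)), key)) {
    if (length(g) < 2) next
    occ <- atom$o[g]
    occ[is.na(occ)] <- 1
    best <- g[order(-occ, alt[g])][1]
    keep[setdiff(g, best)] <- FALSE
  }
  keep
}

bio3d_to_structure <- function(atom) {
  elem <- atom$elesy
  if (is.null(elem)) elem <- NA_character_
  guess <- toupper(substr(trimws(atom$elety), 1, 1))
  elem <- ifelse(is.na(elem) | trimws(elem) == "", guess, trimws(elem))
  molecular_structure(data.frame(
    type = atom$type, serial = atom$eleno, name = trimws(atom$elety),
    altloc = ifelse(is.na(atom$alt), "", atom$alt),
    resname = trimws(atom$resid), chain = ifelse(is.na(atom$chain), " ", atom$chain),
    resnum = atom$resno, x = atom$x, y = atom$y, z = atom$z,
    occupancy = ifelse(is.na(atom$o), 1, atom$o),
    bfactor = ifelse(is.na(atom$b), 0, atom$b),
    element = toupper(elem), stringsAsFactors = FALSE))
}

#' Read a PDB file
#'
#' Reads ATOM and HETATM records (heme and other cofactors are retained).
#' Altloc duplicates are resolved to the highest-occupancy record, ties
#' broken by label order. With `model_policy = "all"` a multi-MODEL file
#' becomes a [trajectory()].
#'
#' @param path PDB file path.
#' @param chain_filter optional chain identifier; all other chains dropped.
#' @param model_policy `"first"` (default) returns a `mol_structure` from
#'   the first MODEL; `"all"` returns a `mol_trajectory` over all MODELs.
#' @return `mol_structure`, or `mol_trajectory` when `model_policy = "all"`
#'   and the file has more than one MODEL.
#' @export
read_pdb <- function(path, chain_filter = NULL, model_policy = c("first", "all")) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stopf("file not found: %s", path)
  check_pdb_coordinates(path)
  pdb <- suppressWarnings(suppressMessages(
    bio3d::read.pdb(path, multi = (model_policy == "all"), rm.alt = FALSE)))
  atom <- pdb$atom
  keep <- resolve_altloc(atom)
  if (!is.null(chain_filter)) keep <- keep & atom$chain %in% chain_filter
  if (!any(keep)) stopf("empty selection: no atoms%s in %s",
                        if (!is.null(chain_filter))
                          sprintf(" on chain %s", paste(chain_filter, collapse = "/"))
                        else "", path)
  s <- bio3d_to_structure(atom[keep, , drop = FALSE])
  nmodel <- nrow(pdb$xyz)
  if (model_policy == "all" && !is.null(nmodel) && nmodel > 1) {
    cols <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1, 3 * which(keep)))
    arr <- array(NA_real_, c(n_atoms(s), 3, nmodel))
    for (m in seq_len(nmodel))
      arr[, , m] <- matrix(pdb$xyz[m, cols], ncol = 3, byrow = TRUE)
    coords(s) <- arr[, , 1]
    return(trajectory(s, arr))
  }
  s
}

#' Write a structure as PDB
#'
#' Round-trips through [read_pdb()] to 0.001 Angstrom on coordinates and exactly
#' on atom identity fields, including the ATOM/HETATM record type.
#'
#' @param structure a `mol_structure`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  xyz <- coords(structure)
  if (any(abs(xyz) >= 10000) || any(xyz <= -1000))
    stopf("coordinates exceed the PDB fixed-width field range")
  if (any(a$resnum > 9999) || any(a$resnum < -999))
    stopf("residue numbers outside the PDB field range (-999..9999)")
  if (any(a$serial > 99999)) stopf("atom serials exceed the PDB field range")
  bio3d::write.pdb(file = path, xyz = as.vector(t(xyz)), type = a$type,
                   resno = a$resnum, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain, o = a$occupancy,
                   b = a$bfactor, elesy = a$element)
  invisible(path)
}

#' Write a trajectory as a multi-MODEL PDB
#'
#' @param trj a `mol_trajectory`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_pdb_trajectory <- function(trj, path) {
  a <- trj$topology$atoms
  con <- file(path, "w"); on.exit(close(con))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  for (m in seq_len(n_frames(trj))) {
    writeLines(sprintf("MODEL     %4d", m), con)
    bio3d::write.pdb(file = tmp, xyz = as.vector(t(frame_coords(trj, m))),
                     type = a$type, resno = a$resnum, resid = a$resname,
                     eleno = a$serial, elety = a$name, chain = a$chain,
                     o = a$occupancy, b = a$bfactor, elesy = a$element, end = FALSE)
    writeLines(readLines(tmp, warn = FALSE), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' Plain multi-frame XYZ: per frame an atom-count line, a comment line, and
#' `element x y z` records. Every frame must match the topology's atom count
#' and element symbols.
#'
#' @param path XYZ file path.
#' @param topology `mol_structure` supplying atom identities.
#' @return a `mol_trajectory`.
#' @export
read_xyz_trajectory <- function(path, topology) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  na <- n_atoms(topology)
  frames <- list(); pos <- 1L; fi <- 0L
  while (pos <= length(lines)) {
    fi <- fi + 1L
    cnt <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(cnt)) stopf("frame %d: expected an atom count at line %d", fi, pos)
    if (cnt != na) stopf("frame %d has %d atoms; topology has %d", fi, cnt, na)
    if (pos + 1L + cnt > length(lines)) stopf("frame %d truncated", fi)
    block <- lines[(pos + 2L):(pos + 1L + cnt)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    elem <- toupper(vapply(parts, `[`, "", 1L))
    if (!all(elem == toupper(topology$atoms$element)))
      stopf("frame %d: element symbols do not match the topology", fi)
    m <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))), ncol = 3, byrow = TRUE)
    if (any(is.na(m))) stopf("frame %d: malformed coordinates", fi)
    frames[[fi]] <- m
    pos <- pos + 2L + cnt
  }
  trajectory(topology, frames)
}

#' Write an XYZ trajectory
#' @param trj a `mol_trajectory`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_xyz_trajectory <- function(trj, path) {
  elem <- trj$topology$atoms$element
  con <- file(path, "w"); on.exit(close(con))
  for (m in seq_len(n_frames(trj))) {
    xyz <- frame_coords(trj, m)
    writeLines(c(sprintf("%d", length(elem)), sprintf("frame %d", m),
                 sprintf("%-3s %12.5f %12.5f %12.5f", elem, xyz[, 1], xyz[, 2], xyz[, 3])),
               con)
  }
  invisible(path)
}
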