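## Ligand-centric binding analyses: per-residue contact fractions,
## extended/folded conformation classification, near-attack-conformation
## (NAC) cleavage-site profiling with the fragment-size spectrum, and
## linear interaction energy (LIE) decomposition.

COULOMB_K <- 332.0636  # kcal A / (mol e^2)

#' Per-residue ligand contact fractions
#'
#' A residue is in contact in a frame when the minimum heavy-atom distance
#' between the ligand and the residue is at most `cutoff`. Fractions are
#' contact frames over total frames; the report suppresses residues at or
#' below `report_threshold` but all fractions are retained.
#'
#' @param trj a `mol_trajectory`.
#' @param ligand_selection selection string or indices of the ligand.
#' @param cutoff contact distance (Angstrom, default 5).
#' @param report_threshold minimum reported fraction (default 0.045).
#' @param environment_selection atoms considered as the protein side
#'   (default: all heavy atoms not in the ligand selection).
#' @return a `contact_profile`: data.frame (`chain`, `resnum`, `resname`,
#'   `fraction`, `reported`) with attributes `cutoff` and `report_threshold`.
#' @export
contact_profile <- function(trj, ligand_selection, cutoff = 5.0,
                            report_threshold = 0.045,
                            environment_selection = NULL) {
  topo <- trj$topology
  li <- resolve_selection(topo, ligand_selection)
  li <- li[topo$atoms$element[li] != "H"]
  ei <- if (is.null(environment_selection)) {
    setdiff(which(topo$atoms$element != "H"), li)
  } else {
    setdiff(resolve_selection(topo, environment_selection), li)
  }
  ei <- ei[topo$atoms$element[ei] != "H"]
  if (!length(li) || !length(ei)) stopf("empty ligand or environment selection")
  rid <- paste(topo$atoms$chain[ei], topo$atoms$resnum[ei], sep = ":")
  groups <- split(seq_along(ei), factor(rid, levels = unique(rid)))
  nf <- n_frames(trj)
  hits <- numeric(length(groups))
  for (t in seq_len(nf)) {
    x <- frame_coords(trj, t)
    d <- cross_dist(x[ei, , drop = FALSE], x[li, , drop = FALSE])
    dmin <- apply(d, 1, min)
    hits <- hits + vapply(groups, function(g) any(dmin[g] <= cutoff), TRUE)
  }
  first <- vapply(groups, `[`, 0L, 1)
  out <- data.frame(chain = topo$atoms$chain[ei[first]],
                    resnum = topo$atoms$resnum[ei[first]],
                    resname = topo$atoms$resname[ei[first]],
                    fraction = hits / nf)
  out$reported <- out$fraction > report_threshold
  attr(out, "cutoff") <- cutoff
  attr(out, "report_threshold") <- report_threshold
  class(out) <- c("contact_profile", "data.frame")
  out
}

#' @export
print.contact_profile <- function(x, ...) {
  cat(sprintf("contact_profile: cutoff %.1f A, reporting fractions > %.1f%%\n",
              attr(x, "cutoff"), 100 * attr(x, "report_threshold")))
  rep <- x[x$reported, c("chain", "resnum", "resname", "fraction")]
  if (nrow(rep)) print.data.frame(rep[order(-rep$fraction), ], row.names = FALSE)
  else cat("  (no residue above the report threshold)\n")
  invisible(x)
}

#' Average contact profiles across poses of one conformational class
#'
#' Pools the full (unthresholded) per-residue fractions of several profiles
#' -- e.g. all poses classified as extended -- and averages them; the
#' report threshold is applied after averaging, so residues that are
#' individually sub-threshold but consistently present are retained.
#'
#' @param profiles list of `contact_profile` over the same residue set.
#' @param report_threshold minimum reported average fraction (default: the
#'   first profile's threshold).
#' @return a `contact_profile` of the averaged fractions.
#' @export
average_contact_profiles <- function(profiles, report_threshold = NULL) {
  stopifnot(length(profiles) >= 1)
  base <- profiles[[1]]
  report_threshold <- report_threshold %||% attr(base, "report_threshold")
  key <- paste(base$chain, base$resnum)
  fr <- rowMeans(vapply(profiles, function(p) {
    if (!identical(paste(p$chain, p$resnum), key))
      stopf("profiles cover different residue sets")
    p$fraction
  }, numeric(nrow(base))))
  out <- data.frame(chain = base$chain, resnum = base$resnum,
                    resname = base$resname, fraction = fr)
  out$reported <- out$fraction > report_threshold
  attr(out, "cutoff") <- attr(base, "cutoff")
  attr(out, "report_threshold") <- report_threshold
  class(out) <- c("contact_profile", "data.frame")
  out
}

#' Classify a bound polymer conformation
#'
#' Labels a pose `extended` when exactly one terminus sits in the pocket
#' (within `pocket_cutoff` of an alpha-sphere center) and the other is at
#' the surface; `folded` when both termini are at the surface and the
#' ligand centroid lies within `heme_cutoff` of the heme center; otherwise
#' `extended_like`. A terminus is "at the surface" when its burial depth --
#' its inward distance from the protein convex hull -- is at most
#' `surface_probe`.
#'
#' @param frame n x 3 coordinates of the full complex, or a `mol_structure`.
#' @param ligand a `polymer_model`.
#' @param pocket a `pocket` detected on the same (or a reference) structure.
#' @param heme_center 3-vector (Angstrom).
#' @param topology `mol_structure` describing the frame's atoms (needed
#'   when `frame` is a bare matrix and defaults to it when a structure is given).
#' @param ligand_map indices of the ligand's atoms within the frame
#'   (default: atoms with residue name IPR, in order).
#' @param surface_probe burial-depth threshold (Angstrom, default 3).
#' @param pocket_cutoff terminus-to-sphere-center threshold (default 2.5).
#' @param heme_cutoff centroid-to-heme threshold for folded (default 12).
#' @return a `conformation_label`: list with `label` and the supporting
#'   measurements.
#' @export
classify_conformation <- function(frame, ligand, pocket, heme_center,
                                  topology = NULL, ligand_map = NULL,
                                  surface_probe = 3.0, pocket_cutoff = 2.5,
                                  heme_cutoff = 12.0) {
  if (inherits(frame, "mol_structure")) {
    topology <- frame
    frame <- coords(frame)
  }
  if (is.null(topology)) stopf("supply a topology describing the frame's atoms")
  frame <- as.matrix(frame)
  if (is.null(ligand_map)) ligand_map <- which(topology$atoms$resname == "IPR")
  if (length(ligand_map) != n_atoms(ligand$structure))
    stopf("ligand atoms not found in the frame (map %d atoms, model has %d)",
          length(ligand_map), n_atoms(ligand$structure))
  if (max(ligand_map) > nrow(frame)) stopf("ligand atom indices not found in frame")
  prot <- setdiff(which(topology$atoms$element != "H"), ligand_map)
  if (!length(prot)) stopf("no protein heavy atoms in the frame")
  hull_cloud <- frame[prot, , drop = FALSE]
  term <- frame[ligand_map[ligand$terminus_atoms], , drop = FALSE]
  dist_pocket <- apply(cross_dist(term, pocket$spheres$centers), 1, min)
  depth <- pmax(hull_depth(term, hull_cloud), 0)
  in_pocket <- dist_pocket <= pocket_cutoff
  at_surface <- depth <= surface_probe
  lig_centroid <- colMeans(frame[ligand_map, , drop = FALSE])
  heme_dist <- sqrt(sum((lig_centroid - heme_center)^2))
  label <- if (sum(in_pocket) == 1 && at_surface[!in_pocket]) "extended"
  else if (all(at_surface) && heme_dist <= heme_cutoff) "folded"
  else "extended_like"
  structure(list(label = label, terminus_pocket_distance = dist_pocket,
                 terminus_burial_depth = depth, in_pocket = in_pocket,
                 at_surface = at_surface, heme_distance = heme_dist,
                 ligand_span = max(stats::dist(term))),
            class = "conformation_label")
}

#' @export
print.conformation_label <- function(x, ...) {
  cat(sprintf("conformation: %s (pocket distances %.1f/%.1f A, burial %.1f/%.1f A, heme %.1f A)\n",
              x$label, x$terminus_pocket_distance[1], x$terminus_pocket_distance[2],
              x$terminus_burial_depth[1], x$terminus_burial_depth[2], x$heme_distance))
  invisible(x)
}

#' Double-bond to distal-oxygen distance
#'
#' @param frame n x 3 coordinates.
#' @param bond length-2 vector of the bond's carbon indices in the frame.
#' @param distal_oxygen index of the distal O2 oxygen in the frame.
#' @param mode `"min"` (default): smaller of the two carbon-oxygen
#'   distances; `"midpoint"`: distance from the bond midpoint.
#' @return distance (Angstrom).
#' @export
bond_o2_distance <- function(frame, bond, distal_oxygen, mode = c("min", "midpoint")) {
  mode <- match.arg(mode)
  frame <- as.matrix(frame)
  if (any(c(bond, distal_oxygen) < 1) || any(c(bond, distal_oxygen) > nrow(frame)))
    stopf("atom index out of range")
  o <- frame[distal_oxygen, ]
  if (mode == "min") {
    min(sqrt(sum((frame[bond[1], ] - o)^2)), sqrt(sum((frame[bond[2], ] - o)^2)))
  } else {
    mid <- (frame[bond[1], ] + frame[bond[2], ]) / 2
    sqrt(sum((mid - o)^2))
  }
}

#' Near-attack-conformation cleavage profile
#'
#' For every frame and double bond, the minimum carbon-to-distal-oxygen
#' distance is computed; the NAC count of bond k is the number of frames
#' with distance strictly below `threshold`, pooled over trajectories.
#'
#' @param trajectories a `mol_trajectory` or list of them (shared topology).
#' @param ligand a `polymer_model` (bond numbering from the dimethyl
#'   terminus).
#' @param distal_oxygen index of the distal oxygen in the topology.
#' @param ligand_map indices of the ligand's atoms within the topology
#'   (default: residue name IPR).
#' @param threshold NAC distance (Angstrom, default 4).
#' @param bin_width histogram bin (Angstrom, default 0.5).
#' @param mode distance convention, see [bond_o2_distance()].
#' @return a `cleavage_profile`: `counts` (per bond), `n_frames`,
#'   `threshold`, `histograms` (per bond), `distances` (bond x frame).
#' @export
nac_profile <- function(trajectories, ligand, distal_oxygen, ligand_map = NULL,
                        threshold = 4.0, bin_width = 0.5, mode = "min") {
  if (inherits(trajectories, "mol_trajectory")) trajectories <- list(trajectories)
  topo <- trajectories[[1]]$topology
  if (is.null(ligand_map)) ligand_map <- which(topo$atoms$resname == "IPR")
  nb <- nrow(ligand$double_bonds)
  if (nb < 1) stopf("ligand has no double bonds")
  bonds <- matrix(ligand_map[ligand$double_bonds], ncol = 2)
  dists <- NULL
  for (trj in trajectories) {
    for (t in seq_len(n_frames(trj))) {
      x <- frame_coords(trj, t)
      dists <- cbind(dists, vapply(seq_len(nb), function(k)
        bond_o2_distance(x, bonds[k, ], distal_oxygen, mode), 0))
    }
  }
  counts <- rowSums(dists < threshold)
  hmax <- ceiling(max(dists) / bin_width) * bin_width
  edges <- seq(0, hmax, by = bin_width)
  histograms <- lapply(seq_len(nb), function(k)
    graphics::hist(dists[k, ], breaks = edges, plot = FALSE)[c("breaks", "counts")])
  structure(list(counts = as.integer(counts), n_frames = ncol(dists),
                 threshold = threshold, histograms = histograms,
                 distances = dists), class = "cleavage_profile")
}

#' @export
print.cleavage_profile <- function(x, ...) {
  cat(sprintf("cleavage_profile: %d bonds, %d frames, NAC < %.1f A\n",
              length(x$counts), x$n_frames, x$threshold))
  print(stats::setNames(x$counts, paste0("bond", seq_along(x$counts))))
  invisible(x)
}

#' Fragment-size spectrum from a cleavage profile
#'
#' Each NAC event at bond k of an n-mer yields oligomers with k-1 and n-k
#' intact double bonds (see [cleavage_products()]); both contribute one
#' count to the spectrum, which is normalized to fractions.
#'
#' @param profile a `cleavage_profile`.
#' @param n monomer count (must equal the profile's bond count).
#' @return data.frame with `size` (0..n-1 intact units) and `weight`
#'   (fractions summing to 1; all zero for an empty profile), with raw
#'   counts in attribute `"events"`.
#' @export
fragment_spectrum <- function(profile, n) {
  if (length(profile$counts) != n)
    stopf("profile has %d bonds but n = %d", length(profile$counts), n)
  w <- numeric(n)  # sizes 0 .. n-1
  for (k in seq_len(n)) {
    pr <- cleavage_products(n, k)
    w[pr[1] + 1] <- w[pr[1] + 1] + profile$counts[k]
    w[pr[2] + 1] <- w[pr[2] + 1] + profile$counts[k]
  }
  out <- data.frame(size = 0:(n - 1),
                    weight = if (sum(w) > 0) w / sum(w) else w)
  attr(out, "events") <- sum(profile$counts)
  out
}

#' Assign per-atom charges and Lennard-Jones parameters
#'
#' @param structure a `mol_structure`.
#' @param table data.frame with columns `name` (atom name; `"*"` matches
#'   any), optional `resname`, and `charge` (e), `eps` (kcal/mol),
#'   `rmin_half` (Angstrom). The most specific matching row wins.
#' @return the structure with `charge`, `eps`, `rmin_half` columns filled.
#' @export
assign_lj_parameters <- function(structure, table) {
  a <- structure$atoms
  for (i in seq_len(nrow(a))) {
    cand <- table[table$name == a$name[i] | table$name == "*", , drop = FALSE]
    if ("resname" %in% names(table))
      cand <- cand[cand$resname == a$resname[i] | cand$resname == "*", , drop = FALSE]
    if (!nrow(cand)) next
    best <- cand[order(cand$name == "*"), ][1, ]
    a$charge[i] <- best$charge; a$eps[i] <- best$eps; a$rmin_half[i] <- best$rmin_half
  }
  structure$atoms <- a
  structure
}

#' Linear interaction energy decomposition
#'
#' Per-frame ligand-environment interaction energies over all cross pairs:
#' \deqn{E_{vdW} = \sum \epsilon_{ij}[(R_{min,ij}/r)^{12} - 2 (R_{min,ij}/r)^6]}
#' with \eqn{\epsilon_{ij} = \sqrt{\epsilon_i \epsilon_j}} and
#' \eqn{R_{min,ij} = R_{min,i}/2 + R_{min,j}/2}, and
#' \eqn{E_{ele} = k_e \sum q_i q_j / r} with
#' \eqn{k_e = 332.0636} kcal A mol^-1 e^-2. No cutoff, vacuum dielectric.
#' The percentage shares are of the absolute ensemble means,
#' \eqn{100 |\bar E_{vdW}| / (|\bar E_{vdW}| + |\bar E_{ele}|)}.
#'
#' @param trj a `mol_trajectory` whose topology carries `charge`, `eps`,
#'   `rmin_half` for all selected atoms (see [assign_lj_parameters()]).
#' @param ligand_selection selection string or indices.
#' @param environment_selection selection string or indices (disjoint).
#' @return an `energy_terms`: per-frame data.frame (`E_vdw`, `E_ele`,
#'   `E_tot`), `means`, `sds`, and `share_pct` (vdW/ele percentages).
#' @export
lie_energy <- function(trj, ligand_selection, environment_selection) {
  topo <- trj$topology
  li <- resolve_selection(topo, ligand_selection)
  ei <- resolve_selection(topo, environment_selection)
  if (!length(li) || !length(ei)) stopf("empty selection")
  if (length(intersect(li, ei))) stopf("ligand and environment selections overlap")
  a <- topo$atoms
  par_missing <- c(li, ei)[is.na(a$charge[c(li, ei)]) | is.na(a$eps[c(li, ei)]) |
                             is.na(a$rmin_half[c(li, ei)])]
  if (length(par_missing))
    stopf("missing charge/LJ parameters for atoms: %s",
          paste(utils::head(a$serial[par_missing], 10), collapse = ", "))
  qq <- COULOMB_K * outer(a$charge[li], a$charge[ei])
  epsij <- sqrt(outer(a$eps[li], a$eps[ei]))
  rmin <- outer(a$rmin_half[li], a$rmin_half[ei], "+")
  nf <- n_frames(trj)
  evdw <- eele <- numeric(nf)
  for (t in seq_len(nf)) {
    x <- frame_coords(trj, t)
    r <- cross_dist(x[li, , drop = FALSE], x[ei, , drop = FALSE])
    s6 <- (rmin / r)^6
    evdw[t] <- sum(epsij * (s6^2 - 2 * s6))
    eele[t] <- sum(qq / r)
  }
  etot <- evdw + eele
  mvdw <- mean(evdw); mele <- mean(eele)
  denom <- abs(mvdw) + abs(mele)
  share <- if (denom > 0) 100 * c(vdw = abs(mvdw), ele = abs(mele)) / denom
  else c(vdw = NA_real_, ele = NA_real_)
  structure(list(frames = data.frame(E_vdw = evdw, E_ele = eele, E_tot = etot),
                 means = c(E_vdw = mvdw, E_ele = mele, E_tot = mean(etot)),
                 sds = c(E_vdw = stats::sd(evdw), E_ele = stats::sd(eele),
                         E_tot = stats::sd(etot)),
                 share_pct = share), class = "energy_terms")
}

#' @export
print.energy_terms <- function(x, ...) {
  cat(sprintf("energy_terms over %d frames (kcal/mol):\n", nrow(x$frames)))
  cat(sprintf("  E_vdW %8.2f +/- %.2f  (%.0f%%)\n", x$means["E_vdw"],
              x$sds["E_vdw"], x$share_pct["vdw"]))
  cat(sprintf("  E_ele %8.2f +/- %.2f  (%.0f%%)\n", x$means["E_ele"],
              x$sds["E_ele"], x$share_pct["ele"]))
  cat(sprintf("  E_tot %8.2f +/- %.2f\n", x$means["E_tot"], x$sds["E_tot"]))
  invisible(x)
}
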