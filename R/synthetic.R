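## Seed-deterministic synthetic structures and trajectories with planted,
## analytically known properties. Every generator records its planted
## truths in a manifest (attribute "manifest", see manifest()), and tests
## read only the manifest, never generator internals.

#' Planted-truth manifest of a synthetic object
#' @param x an object returned by a `make_*` generator.
#' @return named list of planted parameters and truths.
#' @export
manifest <- function(x) attr(x, "manifest")

#' Write a manifest as JSON
#' @param x a synthetic object carrying a manifest.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
write_manifest <- function(x, path) {
  jsonlite::write_json(manifest(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## points on a sphere of radius r (Fibonacci lattice, ~`spacing` apart)
sphere_points <- function(r, spacing) {
  n <- max(8L, ceiling(4 * pi * r^2 / spacing^2))
  fibonacci_directions(n) * r
}

## points on an open cylinder wall of radius r along +z over [z0, z1];
## rings `spacing` apart, staggered half a step between rings
cylinder_points <- function(r, z0, z1, spacing) {
  zs <- seq(z0, z1, by = spacing)
  m <- max(6L, ceiling(2 * pi * r / spacing))
  out <- NULL
  for (k in seq_along(zs)) {
    th <- 2 * pi * (seq_len(m) - 1) / m + (k %% 2) * pi / m
    out <- rbind(out, cbind(r * cos(th), r * sin(th), zs[k]))
  }
  out
}

wall_structure <- function(xyz, wall_atom_radius, resname = "WAL") {
  s <- molecular_structure(data.frame(
    name = "C", element = "C", resname = resname,
    resnum = seq_len(nrow(xyz)), chain = "X",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
  s$atoms$radius <- wall_atom_radius
  s
}

#' Synthetic wall-atom channel structure
#'
#' A sealed spherical cavity with one (optionally two) straight cylindrical
#' exit channel(s) of analytic clearance radius, built from wall atoms on
#' double-layer shells. The free radius along a channel axis equals the
#' channel's `inner_radius` (to within the wall-atom discretization), so a
#' tunnel search from the cavity center must report that bottleneck.
#'
#' @param inner_radius analytic clearance radius of the +z channel (Angstrom).
#' @param length channel length (Angstrom).
#' @param wall_atom_radius radius assigned to wall atoms (Angstrom, default 1.4).
#' @param spacing wall-atom lattice spacing (Angstrom, default 0.8); must be
#'   < 1.5 x `wall_atom_radius` or the walls would leak.
#' @param cavity_radius clearance radius of the central cavity (default 4).
#' @param second_radius optional clearance radius of a second channel along
#'   -z (default none).
#' @param seed recorded in the manifest; the construction is deterministic.
#' @return `mol_structure` with radii set and a manifest of planted truths.
#' @export
make_channel <- function(inner_radius, length, wall_atom_radius = 1.4,
                         spacing = 0.8, cavity_radius = 4.0,
                         second_radius = NULL, seed = 1) {
  if (inner_radius <= 0) stopf("inner_radius must be positive")
  if (spacing >= 1.5 * wall_atom_radius)
    stopf("wall gaps would exceed the wall-atom radius (fixture would leak); reduce spacing")
  if (inner_radius + wall_atom_radius >= cavity_radius + wall_atom_radius)
    stopf("channel must be narrower than the cavity")
  wr <- wall_atom_radius
  layers <- function(build) rbind(build(0), build(1.4 * wr))
  tube_block <- function(ri, sgn) {
    z0 <- sqrt(max(0, (cavity_radius + wr)^2 - (ri + wr)^2)) - spacing
    pts <- layers(function(off) cylinder_points(ri + wr + off, z0, z0 + length, spacing))
    pts[, 3] <- sgn * pts[, 3]
    pts
  }
  keep_shell <- function(pts) {
    axdist <- sqrt(pts[, 1]^2 + pts[, 2]^2)
    drop <- (pts[, 3] > 0 & axdist < inner_radius + wr + spacing)
    if (!is.null(second_radius))
      drop <- drop | (pts[, 3] < 0 & axdist < second_radius + wr + spacing)
    pts[!drop, , drop = FALSE]
  }
  shell <- keep_shell(layers(function(off) sphere_points(cavity_radius + wr + off, spacing)))
  xyz <- rbind(shell, tube_block(inner_radius, 1))
  if (!is.null(second_radius)) xyz <- rbind(xyz, tube_block(second_radius, -1))
  s <- wall_structure(xyz, wr)
  attr(s, "manifest") <- list(
    kind = "channel", seed = seed, inner_radius = inner_radius,
    second_radius = second_radius, channel_length = length,
    cavity_radius = cavity_radius, wall_atom_radius = wr, spacing = spacing,
    start_point = c(0, 0, 0),
    n_exits = if (is.null(second_radius)) 1L else 2L)
  s
}

#' Synthetic hollow cavity shell
#'
#' Wall atoms jittered on a sphere enclose an interior void; Voronoi-vertex
#' alpha spheres near the center have radius close to `cavity_radius`
#' (atom-center convention). The manifest records the analytic inscribed
#' void volume, 4/3 pi (cavity_radius - atom_radius)^3.
#'
#' @param cavity_radius distance of wall-atom centers from the center
#'   (Angstrom); choose within [3.4, 6.2] to yield alpha spheres that survive
#'   the radius filter.
#' @param shell_atoms number of wall atoms (default 80; at least 30 to
#'   close the shell).
#' @param atom_radius wall-atom radius (default 1.8).
#' @param jitter uniform radial/tangential jitter amplitude (default 0.25).
#' @param center cavity center (default origin).
#' @param seed RNG seed for the jitter.
#' @return `mol_structure` with radii set and a manifest.
#' @export
make_cavity <- function(cavity_radius = 4.5, shell_atoms = 80L,
                        atom_radius = 1.8, jitter = 0.25,
                        center = c(0, 0, 0), seed = 1) {
  if (shell_atoms < 30) stopf("too few shell atoms to close the cavity")
  xyz <- with_seed(seed, {
    dirs <- fibonacci_directions(shell_atoms)
    r <- cavity_radius + stats::runif(shell_atoms, -jitter, jitter)
    p <- dirs * r + matrix(stats::rnorm(3 * shell_atoms, 0, jitter / 2), ncol = 3)
    sweep(p, 2, center, "+")
  })
  s <- wall_structure(xyz, atom_radius)
  attr(s, "manifest") <- list(
    kind = "cavity", seed = seed, cavity_radius = cavity_radius,
    shell_atoms = shell_atoms, atom_radius = atom_radius, jitter = jitter,
    center = center,
    inscribed_void_volume = 4 / 3 * pi * max(0, cavity_radius - atom_radius)^3)
  s
}

## deterministic evenly spread frame schedule realizing `count` of `n`
schedule_frames <- function(count, n) {
  if (count == 0) return(integer(0))
  unique(as.integer(round((seq_len(count)) * n / count)))
}

#' Synthetic protein-ligand binding trajectory with planted truths
#'
#' Builds a complex of a polyisoprene ligand, single-atom probe residues,
#' and a fixed distal-O2 pseudo-atom, then animates it so that each probe
#' residue's ligand-contact indicator follows a deterministic schedule
#' realizing its target fraction exactly, and each planned double bond's
#' minimum carbon-O2 distance dips below the NAC threshold in exactly its
#' planned fraction of frames. Scheduled residues, planned bond carbons and
#' the O2 atom are jitter-free so the planted counts are exact; all other
#' atoms receive isotropic Gaussian jitter of `jitter_sigma` per axis.
#'
#' Geometric zones keep the analyses independent: the ligand body sits at
#' the origin, probe residues approach its first atom from the -x
#' hemisphere, and planned bond carbons orbit the O2 atom 60 A away.
#'
#' @param n_frames frame count.
#' @param ligand a `polymer_model` (default `build_polyisoprene(10)`).
#' @param contact_schedule named numeric vector: residue number -> target
#'   contact fraction (each fraction x n_frames must be a whole number).
#' @param distance_plan data.frame with columns `bond`, `baseline`, `dip`,
#'   `dip_fraction` (Angstrom / fraction); `dip_fraction * n_frames` must be
#'   whole.
#' @param n_background extra always-far probe residues (default 3).
#' @param contact_distance in-contact ligand-residue distance (default 4).
#' @param far_distance out-of-contact distance (default 20).
#' @param jitter_sigma per-axis Gaussian jitter (Angstrom, default 0).
#' @param seed RNG seed for the jitter.
#' @return `mol_trajectory` whose manifest records all planted truths plus
#'   `ligand_map` (ligand atom indices) and `o2_index`.
#' @export
make_binding_trajectory <- function(n_frames, ligand = build_polyisoprene(10),
                                    contact_schedule = NULL,
                                    distance_plan = NULL,
                                    n_background = 3L,
                                    contact_distance = 4.0, far_distance = 20.0,
                                    jitter_sigma = 0, seed = 1) {
  n <- as.integer(n_frames)
  sched <- list()
  if (!is.null(contact_schedule)) {
    for (rn in names(contact_schedule)) {
      f <- contact_schedule[[rn]]
      cnt <- f * n
      if (abs(cnt - round(cnt)) > 1e-9)
        stopf("contact fraction %g x %d frames is not a whole number", f, n)
      sched[[rn]] <- schedule_frames(as.integer(round(cnt)), n)
    }
  }
  plans <- list()
  if (!is.null(distance_plan)) {
    for (r in seq_len(nrow(distance_plan))) {
      p <- distance_plan[r, ]
      cnt <- p$dip_fraction * n
      if (abs(cnt - round(cnt)) > 1e-9)
        stopf("dip fraction %g x %d frames is not a whole number", p$dip_fraction, n)
      if (p$dip >= p$baseline)
        stopf("dip distance must be below the baseline for bond %d", p$bond)
      plans[[as.character(p$bond)]] <-
        list(baseline = p$baseline, dip = p$dip,
             frames = schedule_frames(as.integer(round(cnt)), n))
    }
  }

  lig_atoms <- ligand$structure$atoms
  n_lig <- nrow(lig_atoms)
  res_names <- names(sched)
  n_res <- length(res_names) + n_background
  res_nums <- c(as.integer(res_names),
                if (n_background > 0) 900L + seq_len(n_background))
  ## probe-residue rest directions: -x hemisphere around ligand atom 1
  dirs <- fibonacci_directions(max(4L * n_res, 32L))
  dirs <- dirs[dirs[, 1] < -0.3, , drop = FALSE][seq_len(max(n_res, 1L)), , drop = FALSE]

  prot <- data.frame(
    name = "CA", element = "C", resname = "GLY", resnum = res_nums, chain = "A",
    x = far_distance * dirs[, 1], y = far_distance * dirs[, 2],
    z = far_distance * dirs[, 3], stringsAsFactors = FALSE)
  lig <- data.frame(name = lig_atoms$name, element = lig_atoms$element,
                    resname = "IPR", resnum = lig_atoms$resnum, chain = "L",
                    x = lig_atoms$x, y = lig_atoms$y, z = lig_atoms$z,
                    stringsAsFactors = FALSE)
  o2_pos <- c(-60, 0, 0)
  o2 <- data.frame(name = "O2", element = "O", resname = "OXY", resnum = 999L,
                   chain = "O", x = o2_pos[1], y = o2_pos[2], z = o2_pos[3],
                   stringsAsFactors = FALSE)
  topo <- molecular_structure(rbind(prot, lig, o2))
  topo$atoms$type[nrow(topo$atoms)] <- "HETATM"
  ligand_map <- nrow(prot) + seq_len(n_lig)
  o2_index <- nrow(prot) + n_lig + 1L
  base <- coords(topo)
  lig1 <- base[ligand_map[1], ]

  ## planned-bond carbons orbit O2 on distinct directions in the y-z plane
  bond_dirs <- list()
  for (k in seq_along(plans)) {
    th <- 2 * pi * (k - 1) / max(1, length(plans))
    bond_dirs[[names(plans)[k]]] <- c(0, cos(th), sin(th))
  }

  frames <- with_seed(seed, {
    arr <- array(NA_real_, c(nrow(base), 3, n))
    fixed <- rep(FALSE, nrow(base))
    fixed[o2_index] <- TRUE
    for (rn in res_names) fixed[which(topo$atoms$resnum == as.integer(rn))] <- TRUE
    for (bk in names(plans))
      fixed[ligand_map[ligand$double_bonds[as.integer(bk), ]]] <- TRUE
    for (t in seq_len(n)) {
      x <- base
      for (j in seq_along(res_names)) {
        rn <- res_names[j]
        ri <- which(topo$atoms$resnum == as.integer(rn))
        d <- if (t %in% sched[[rn]]) contact_distance else far_distance
        x[ri, ] <- lig1 + d * dirs[j, ]
      }
      for (bk in names(plans)) {
        p <- plans[[bk]]
        r <- if (t %in% p$frames) p$dip else p$baseline
        ci <- ligand_map[ligand$double_bonds[as.integer(bk), ]]
        u <- bond_dirs[[bk]]
        x[ci[1], ] <- o2_pos + r * u
        x[ci[2], ] <- o2_pos + r * u + c(1.34, 0, 0)  # second carbon farther
      }
      if (jitter_sigma > 0) {
        jit <- matrix(stats::rnorm(3 * nrow(base), 0, jitter_sigma), ncol = 3)
        jit[fixed, ] <- 0
        x <- x + jit
      }
      arr[, , t] <- x
    }
    arr
  })
  trj <- trajectory(topo, frames)
  attr(trj, "manifest") <- list(
    kind = "binding", seed = seed, n_frames = n,
    contact_fractions = as.list(contact_schedule %||% list()),
    contact_frames = lapply(sched, identity),
    distance_plan = plans, jitter_sigma = jitter_sigma,
    contact_distance = contact_distance, far_distance = far_distance,
    ligand_map = ligand_map, o2_index = o2_index,
    monomer_count = ligand$monomer_count)
  trj
}

#' Remove rigid-body components from a planted displacement
#'
#' Projects a per-atom displacement field onto the subspace orthogonal to
#' the six rigid-body modes (net translations and infinitesimal rotations
#' about the centroid) of the reference. Superposition-based analyses are
#' blind to rigid-body motion, so a planted two-state displacement should
#' be orthogonalized this way for its direction to be recoverable by PCA.
#'
#' @param reference `mol_structure` (or n x 3 coordinates).
#' @param displacement n x 3 matrix (Angstrom).
#' @return n x 3 matrix with rigid-body components removed.
#' @export
orthogonalize_displacement <- function(reference, displacement) {
  xyz <- if (inherits(reference, "mol_structure")) coords(reference) else as.matrix(reference)
  n <- nrow(xyz)
  ctr <- sweep(xyz, 2, colMeans(xyz))
  basis <- matrix(0, 3 * n, 6)
  for (k in 1:3) basis[seq(k, 3 * n, by = 3), k] <- 1       # translations
  for (k in 1:3) {                                          # rotations e_k x r
    e <- c(0, 0, 0); e[k] <- 1
    rot <- t(apply(ctr, 1, function(r) pracma_cross(e, r)))
    basis[, 3 + k] <- as.vector(t(rot))
  }
  q <- qr.Q(qr(basis))
  v <- as.vector(t(displacement))
  v <- v - q %*% (t(q) %*% v)
  matrix(v, ncol = 3, byrow = TRUE)
}

#' Synthetic two-state trajectory
#'
#' Frames are drawn from state A (the reference coordinates) or state B
#' (reference + displacement) with probability `occupancy` for B, plus
#' isotropic Gaussian noise. The manifest records the per-frame state
#' assignments and the planted displacement, so two-state separation by
#' PCA can be checked exactly.
#'
#' @param reference `mol_structure`.
#' @param displacement n_atoms x 3 matrix (Angstrom), state B minus state A.
#' @param occupancy probability of state B, in (0, 1).
#' @param n_frames frame count.
#' @param noise_sigma per-axis Gaussian noise (Angstrom).
#' @param seed RNG seed.
#' @return `mol_trajectory` with manifest fields `states` (1 = A, 2 = B)
#'   and `displacement`.
#' @export
make_two_state_trajectory <- function(reference, displacement, occupancy,
                                      n_frames, noise_sigma, seed = 1) {
  if (occupancy <= 0 || occupancy >= 1) stopf("occupancy must be in (0, 1)")
  displacement <- as.matrix(displacement)
  if (!all(dim(displacement) == c(n_atoms(reference), 3)))
    stopf("displacement must be n_atoms x 3")
  if (all(displacement == 0))
    warning("zero displacement: the two states are indistinguishable")
  base <- coords(reference)
  out <- with_seed(seed, {
    states <- 1L + stats::rbinom(n_frames, 1L, occupancy)
    arr <- array(NA_real_, c(nrow(base), 3, n_frames))
    for (t in seq_len(n_frames)) {
      x <- base + if (states[t] == 2L) displacement else 0
      arr[, , t] <- x + matrix(stats::rnorm(3 * nrow(base), 0, noise_sigma), ncol = 3)
    }
    list(states = states, arr = arr)
  })
  trj <- trajectory(reference, out$arr)
  attr(trj, "manifest") <- list(
    kind = "two_state", seed = seed, occupancy = occupancy,
    n_frames = n_frames, noise_sigma = noise_sigma,
    states = out$states, displacement = displacement)
  trj
}

#' Uniform ideal-gas trajectory
#'
#' Independent uniform positions in a periodic box each frame; the radial
#' distribution function of such a gas is identically 1.
#'
#' @param n_atoms_gas number of gas atoms (>= 2).
#' @param box length-3 box dimensions (Angstrom).
#' @param n_frames frame count.
#' @param seed RNG seed.
#' @return periodic `mol_trajectory` with a manifest.
#' @export
make_uniform_gas <- function(n_atoms_gas, box, n_frames, seed = 1) {
  if (n_atoms_gas < 2) stopf("need at least 2 gas atoms")
  topo <- molecular_structure(data.frame(
    name = "AR", element = "AR", resname = "GAS",
    resnum = seq_len(n_atoms_gas), chain = "G",
    x = 0, y = 0, z = 0, stringsAsFactors = FALSE))
  arr <- with_seed(seed, {
    a <- array(stats::runif(n_atoms_gas * 3 * n_frames), c(n_atoms_gas, 3, n_frames))
    for (k in 1:3) a[, k, ] <- a[, k, ] * box[k]
    a
  })
  trj <- trajectory(topo, arr, box = box)
  attr(trj, "manifest") <- list(kind = "gas", seed = seed,
                                n_atoms = n_atoms_gas, box = box,
                                n_frames = n_frames,
                                density = n_atoms_gas / prod(box))
  trj
}
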