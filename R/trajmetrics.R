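## Superposition-based trajectory metrics: Kabsch fitting, RMSD series,
## per-residue RMSF, cartesian PCA of backbone atoms with porcupine mode
## export, radial distribution functions, and sliding-window smoothing.

#' Kabsch superposition
#'
#' Least-squares rigid-body fit of `mobile` onto `reference` (proper
#' rotation, determinant +1), optionally weighted.
#'
#' @param mobile n x 3 coordinate matrix.
#' @param reference n x 3 coordinate matrix.
#' @param weights optional non-negative per-point weights.
#' @return list with `rotation` (3 x 3), `translation` (length 3) such that
#'   `mobile %*% rotation + translation` best fits `reference`, and `rmsd`.
#' @export
kabsch <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || nrow(mobile) < 3)
    stopf("kabsch needs two equal n x 3 sets with n >= 3")
  w <- weights %||% rep(1, nrow(mobile))
  w <- w / sum(w)
  mc <- colSums(mobile * w); rc <- colSums(reference * w)
  a <- sweep(mobile, 2, mc); b <- sweep(reference, 2, rc)
  h <- t(a * w) %*% b
  sv <- svd(h)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1e-30))
    stopf("degenerate geometry: points are (nearly) collinear")
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- a %*% rot
  rmsd <- sqrt(sum(w * rowSums((fitted - b)^2)))
  list(rotation = rot, translation = rc - mc %*% rot, rmsd = rmsd)
}

apply_fit <- function(xyz, fit) sweep(xyz %*% fit$rotation, 2, as.vector(fit$translation), "+")

resolve_selection <- function(structure, selection) {
  if (is.character(selection)) select_atoms(structure, selection)
  else as.integer(selection)
}

#' Per-frame RMSD from a reference structure
#'
#' Each frame is superposed on the reference over `fit_selection`, then the
#' RMSD is computed over `calc_selection`.
#'
#' @param trj a `mol_trajectory`.
#' @param reference `mol_structure` (defaults to the trajectory topology).
#' @param fit_selection selection string or indices for the superposition
#'   (default `"name CA"`).
#' @param calc_selection selection for the RMSD (default: same as fit).
#' @return numeric vector of per-frame RMSD (Angstrom).
#' @export
rmsd_series <- function(trj, reference = trj$topology,
                        fit_selection = "name CA", calc_selection = fit_selection) {
  fit_idx <- resolve_selection(reference, fit_selection)
  calc_idx <- resolve_selection(reference, calc_selection)
  if (!length(fit_idx) || !length(calc_idx)) stopf("empty selection")
  ref <- coords(reference)
  vapply(seq_len(n_frames(trj)), function(t) {
    x <- frame_coords(trj, t)
    f <- kabsch(x[fit_idx, , drop = FALSE], ref[fit_idx, , drop = FALSE])
    xf <- apply_fit(x, f)
    sqrt(mean(rowSums((xf[calc_idx, , drop = FALSE] -
                         ref[calc_idx, , drop = FALSE])^2)))
  }, 0)
}

## superpose all frames onto the ensemble mean of `fit_idx` atoms,
## iterating the mean twice (standard essential-dynamics practice)
superpose_to_mean <- function(arr, fit_idx, iterations = 2) {
  nf <- dim(arr)[3]
  ref <- arr[fit_idx, , 1]
  for (it in seq_len(iterations)) {
    for (t in seq_len(nf)) {
      f <- kabsch(arr[fit_idx, , t], ref)
      arr[, , t] <- apply_fit(arr[, , t], f)
    }
    ref <- apply(arr[fit_idx, , , drop = FALSE], c(1, 2), mean)
  }
  arr
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed on the ensemble mean (iterated twice); per-atom
#' RMSF is the RMS deviation from the time-mean position; residues are
#' reported by their C-alpha atom when selected, else by the mean over the
#' residue's selected atoms.
#'
#' @param trj a `mol_trajectory` with >= 2 frames.
#' @param selection atoms to report (default `"name CA"`).
#' @param fit_selection atoms used for superposition (default: the selection).
#' @return data.frame with `chain`, `resnum`, `resname`, `rmsf` (Angstrom).
#' @export
rmsf <- function(trj, selection = "name CA", fit_selection = selection) {
  if (n_frames(trj) < 2) stopf("RMSF needs at least 2 frames")
  idx <- resolve_selection(trj$topology, selection)
  fit_idx <- resolve_selection(trj$topology, fit_selection)
  if (!length(idx) || !length(fit_idx)) stopf("empty selection")
  arr <- superpose_to_mean(trj$coords, fit_idx)
  mu <- apply(arr[idx, , , drop = FALSE], c(1, 2), mean)
  dev2 <- vapply(seq_len(n_frames(trj)),
                 function(t) rowSums((arr[idx, , t] - mu)^2), numeric(length(idx)))
  atom_rmsf <- sqrt(rowMeans(matrix(dev2, nrow = length(idx))))
  at <- trj$topology$atoms[idx, ]
  agg <- data.frame(chain = at$chain, resnum = at$resnum, resname = at$resname,
                    ca = at$name == "CA", rmsf = atom_rmsf)
  out <- do.call(rbind, lapply(split(agg, paste(agg$chain, agg$resnum)), function(g) {
    val <- if (any(g$ca)) g$rmsf[g$ca][1] else mean(g$rmsf)
    data.frame(chain = g$chain[1], resnum = g$resnum[1],
               resname = g$resname[1], rmsf = val)
  }))
  out <- out[order(out$chain, out$resnum), ]
  rownames(out) <- NULL
  out
}

#' Cartesian principal component analysis of trajectories
#'
#' Pools the frames of one or more trajectories (tagged per trajectory),
#' superposes them on the overall mean (iterated twice), and
#' eigen-decomposes the positional covariance of the selected atoms
#' (typically backbone N, CA, C, O). Mode signs are fixed so each mode's
#' largest-magnitude component is positive.
#'
#' @param trajectories a `mol_trajectory` or list of them (same topology).
#' @param selection atoms to analyse (default `"backbone"`).
#' @return a `pca_result`: `mean_coordinates` (m x 3), `eigenvalues`
#'   (A^2, descending), `modes` (3m x k orthonormal columns),
#'   `projections` (frames x k, Angstrom), `tags` (source trajectory per frame),
#'   `atom_indices`.
#' @export
pca_trajectory <- function(trajectories, selection = "backbone") {
  if (inherits(trajectories, "mol_trajectory")) trajectories <- list(trajectories)
  topo <- trajectories[[1]]$topology
  idx <- resolve_selection(topo, selection)
  if (!length(idx)) stopf("empty selection")
  arrs <- lapply(trajectories, function(trj) trj$coords[idx, , , drop = FALSE])
  tags <- rep(seq_along(arrs), vapply(arrs, function(a) dim(a)[3], 0L))
  arr <- array(unlist(arrs), c(length(idx), 3, length(tags)))
  if (dim(arr)[3] < 2) stopf("PCA needs more than one frame")
  if (dim(arr)[3] <= 3 * length(idx))
    warning(sprintf("only %d frames for %d coordinates; eigenvalues will be noisy",
                    dim(arr)[3], 3 * length(idx)))
  arr <- superpose_to_mean(arr, seq_along(idx))
  x <- t(apply(arr, 3, as.vector))            # frames x 3m (atom-major per axis)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sv <- svd(xc)
  lambda <- sv$d^2 / (nrow(x) - 1)
  modes <- sv$v
  flip <- apply(modes, 2, function(v) sign(v[which.max(abs(v))]))
  modes <- sweep(modes, 2, flip, "*")
  proj <- xc %*% modes
  structure(list(mean_coordinates = matrix(mu, ncol = 3),
                 eigenvalues = lambda, modes = modes, projections = proj,
                 tags = tags, atom_indices = idx), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  cat(sprintf("pca_result: %d frames, %d atoms; PC1-3 variance %.1f%% %.1f%% %.1f%%\n",
              nrow(x$projections), length(x$atom_indices),
              100 * x$eigenvalues[1] / tot, 100 * x$eigenvalues[2] / tot,
              100 * x$eigenvalues[3] / tot))
  invisible(x)
}

#' Porcupine displacement vectors for a principal component
#'
#' Per-atom vectors `scale * sqrt(eigenvalue) * mode`; vectors shorter than
#' `min_length` are zeroed so only substantial motions are drawn.
#'
#' @param result a `pca_result`.
#' @param component mode index (default 1).
#' @param scale multiplier (default 1).
#' @param min_length suppression threshold (Angstrom, default 2).
#' @return m x 3 matrix of displacement vectors.
#' @export
porcupine <- function(result, component = 1, scale = 1, min_length = 2.0) {
  if (component < 1 || component > length(result$eigenvalues))
    stopf("component out of range")
  v <- matrix(result$modes[, component], ncol = 3)
  v <- v * scale * sqrt(result$eigenvalues[component])
  len <- sqrt(rowSums(v^2))
  v[len < min_length, ] <- 0
  v
}

#' Radial distribution function
#'
#' Pair-distance histogram between two selections, normalized by the ideal
#' shell volume and bulk target density. With a periodic box, distances use
#' the minimum-image convention and the density defaults to the mean box
#' density of the target selection; without a box a `density` override is
#' required.
#'
#' @param trj a `mol_trajectory`.
#' @param reference_selection selection string or indices.
#' @param target_selection selection string or indices.
#' @param bin_width histogram bin (Angstrom, default 0.1).
#' @param r_max maximum distance (Angstrom, default 10).
#' @param density bulk number density override (atoms / A^3).
#' @return data.frame with `r` (bin centers) and `g` (dimensionless).
#' @export
rdf <- function(trj, reference_selection, target_selection,
                bin_width = 0.1, r_max = 10, density = NULL) {
  ri <- resolve_selection(trj$topology, reference_selection)
  ti <- resolve_selection(trj$topology, target_selection)
  if (!length(ri) || !length(ti)) stopf("empty selection")
  if (is.null(trj$box) && is.null(density))
    stopf("no periodic box: supply a bulk density override")
  edges <- seq(0, r_max, by = bin_width)
  counts <- numeric(length(edges) - 1)
  nf <- n_frames(trj)
  for (t in seq_len(nf)) {
    x <- frame_coords(trj, t)
    dd <- 0
    for (k in 1:3) {
      dk <- outer(x[ri, k], x[ti, k], "-")
      if (!is.null(trj$box)) {
        L <- trj$box[t, k]
        dk <- dk - L * round(dk / L)
      }
      dd <- dd + dk^2
    }
    d <- sqrt(dd)
    if (identical(ri, ti)) d[cbind(seq_along(ri), seq_along(ti))] <- NA
    d <- d[!is.na(d) & d > 0 & d < r_max]
    counts <- counts + graphics::hist(d, breaks = edges, plot = FALSE)$counts
  }
  rho <- density %||% (length(ti) / mean(apply(trj$box, 1, prod)))
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  g <- counts / (nf * length(ri) * shell * rho)
  data.frame(r = (edges[-1] + edges[-length(edges)]) / 2, g = g)
}

#' Sliding-window trajectory smoothing
#'
#' Centered moving average of the coordinates over `window` frames; the
#' window shrinks symmetrically at the ends, so the frame count is
#' unchanged.
#'
#' @param trj a `mol_trajectory`.
#' @param window odd window size (default 5).
#' @return smoothed `mol_trajectory`.
#' @export
smooth_trajectory <- function(trj, window = 5) {
  if (window %% 2 == 0) stopf("smoothing window must be odd")
  nf <- n_frames(trj)
  if (window < 1 || window > nf) stopf("window must be in 1..n_frames")
  h <- (window - 1) %/% 2
  out <- trj$coords
  for (t in seq_len(nf)) {
    hh <- min(h, t - 1, nf - t)   # symmetric shrink at the ends
    w <- (t - hh):(t + hh)
    out[, , t] <- apply(trj$coords[, , w, drop = FALSE], c(1, 2), mean)
  }
  trajectory(trj$topology, out, box = trj$box)
}
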