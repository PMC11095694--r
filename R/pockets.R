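## Alpha-sphere pocket detection.
##
## An alpha sphere is tangent to four atoms and empty of all others -- a
## Voronoi vertex of the atom centers (radius measured to atom centers,
## the convention implied by the 3.4-6.2 A default bounds). Vertices are
## found as circumcenters of candidate atom quadruples drawn from k-nearest
## neighbourhoods and validated by the exact empty-circumsphere (Delaunay)
## condition against every atom, so each reported sphere is exact; the
## neighbourhood size bounds the enumeration, not the geometry.

#' Detect alpha spheres
#'
#' @param structure `mol_structure` with >= 5 non-coplanar heavy atoms.
#' @param rmin,rmax radius filter bounds (Angstrom; defaults 3.4 and 6.2).
#' @param k_neighbours neighbourhood size for candidate enumeration
#'   (default 16).
#' @param interior_only discard spheres whose center falls outside the
#'   convex hull of the atoms (default TRUE).
#' @return an `alpha_spheres` object: list with `centers` (m x 3),
#'   `radius` (length m), `atoms` (m x 4 defining-atom indices).
#' @export
alpha_spheres <- function(structure, rmin = 3.4, rmax = 6.2,
                          k_neighbours = 16L, interior_only = TRUE) {
  heavy <- which(structure$atoms$element != "H")
  xyz <- coords(structure)[heavy, , drop = FALSE]
  n <- nrow(xyz)
  if (n < 5) stopf("alpha-sphere detection needs at least 5 heavy atoms")
  k <- min(k_neighbours, n - 1L)
  dm <- as.matrix(stats::dist(xyz))
  diag(dm) <- Inf

  ## candidate quadruples: each atom with 3 of its k nearest neighbours
  quads <- NULL
  for (i in seq_len(n)) {
    nb <- order(dm[i, ])[seq_len(k)]
    tri <- utils::combn(nb, 3)
    quads <- rbind(quads, cbind(i, t(tri)))
  }
  quads <- t(apply(quads, 1, sort))
  quads <- unique(quads)

  ## vectorized circumcenters: solve 2 (p_j - p_1) . x = |p_j|^2 - |p_1|^2
  p1 <- xyz[quads[, 1], , drop = FALSE]
  a <- xyz[quads[, 2], , drop = FALSE] - p1
  b <- xyz[quads[, 3], , drop = FALSE] - p1
  cc <- xyz[quads[, 4], , drop = FALSE] - p1
  ka <- rowSums(a^2) / 2; kb <- rowSums(b^2) / 2; kc <- rowSums(cc^2) / 2
  cross_rows <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                                     u[, 3] * v[, 1] - u[, 1] * v[, 3],
                                     u[, 1] * v[, 2] - u[, 2] * v[, 1])
  bxc <- cross_rows(b, cc); cxa <- cross_rows(cc, a); axb <- cross_rows(a, b)
  det <- rowSums(a * bxc)
  ok <- abs(det) > 1e-9
  ctr <- (bxc * ka + cxa * kb + axb * kc) / det
  rad <- sqrt(rowSums(ctr^2))
  ctr <- ctr + p1
  keep <- ok & rad >= rmin & rad <= rmax
  if (!any(keep)) {
    if (all(!ok)) stopf("degenerate (coplanar) atom arrangement: no circumspheres")
    return(empty_alpha_spheres())
  }
  ctr <- ctr[keep, , drop = FALSE]; rad <- rad[keep]
  quads <- quads[keep, , drop = FALSE]

  ## exact empty-circumsphere condition: no atom strictly inside
  inside <- logical(nrow(ctr))
  chunk <- 2000L
  for (s in seq(1, nrow(ctr), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(ctr))
    dmin <- apply(cross_dist(ctr[s:e, , drop = FALSE], xyz), 1, min)
    inside[s:e] <- dmin >= rad[s:e] - 1e-6
  }
  ctr <- ctr[inside, , drop = FALSE]; rad <- rad[inside]
  quads <- quads[inside, , drop = FALSE]

  if (interior_only && nrow(ctr)) {
    dep <- hull_depth(ctr, xyz)
    keep <- dep >= 0
    ctr <- ctr[keep, , drop = FALSE]; rad <- rad[keep]
    quads <- quads[keep, , drop = FALSE]
  }
  structure(list(centers = ctr, radius = rad,
                 atoms = matrix(heavy[quads], ncol = 4)),
            class = "alpha_spheres")
}

empty_alpha_spheres <- function() {
  structure(list(centers = matrix(0, 0, 3), radius = numeric(0),
                 atoms = matrix(0L, 0, 4)), class = "alpha_spheres")
}

#' @export
print.alpha_spheres <- function(x, ...) {
  cat(sprintf("alpha_spheres: %d spheres, radii %.2f-%.2f A\n",
              length(x$radius),
              if (length(x$radius)) min(x$radius) else NA,
              if (length(x$radius)) max(x$radius) else NA))
  invisible(x)
}

subset_spheres <- function(sp, idx) {
  structure(list(centers = sp$centers[idx, , drop = FALSE],
                 radius = sp$radius[idx],
                 atoms = sp$atoms[idx, , drop = FALSE]), class = "alpha_spheres")
}

#' Cluster alpha spheres into pockets
#'
#' Single-linkage clustering of sphere centers at `link_cutoff`
#' (equivalently, connected components of the contact graph at that
#' distance); components with fewer than `min_spheres` members are
#' discarded. Pockets are ordered by sphere count.
#'
#' @param spheres an `alpha_spheres` object.
#' @param link_cutoff single-linkage cut distance (Angstrom, default 1.8).
#' @param min_spheres minimum spheres per pocket (default 15).
#' @return list of `pocket` objects (possibly empty), each with `spheres`,
#'   `n_spheres`, `centroid`; `volume`, `volume_se`, `hydrophobicity` are
#'   filled by [pocket_volume()] / [pocket_hydrophobicity()].
#' @export
cluster_spheres <- function(spheres, link_cutoff = 1.8, min_spheres = 15L) {
  m <- length(spheres$radius)
  if (m == 0) return(list())
  membership <- if (m == 1) 1L else {
    hc <- stats::hclust(stats::dist(spheres$centers), method = "single")
    stats::cutree(hc, h = link_cutoff)
  }
  pockets <- lapply(seq_len(max(membership)), function(kk) {
    idx <- which(membership == kk)
    if (length(idx) < min_spheres) return(NULL)
    sp <- subset_spheres(spheres, idx)
    structure(list(spheres = sp, n_spheres = length(idx),
                   centroid = colMeans(sp$centers),
                   volume = NA_real_, volume_se = NA_real_,
                   hydrophobicity = NA_real_, lining_atoms = NULL),
              class = "pocket")
  })
  pockets <- Filter(Negate(is.null), pockets)
  pockets[order(-vapply(pockets, `[[`, 0L, "n_spheres"))]
}

#' @export
print.pocket <- function(x, ...) {
  cat(sprintf("pocket: %d alpha spheres, centroid (%.1f, %.1f, %.1f)%s\n",
              x$n_spheres, x$centroid[1], x$centroid[2], x$centroid[3],
              if (!is.na(x$volume))
                sprintf(", volume %.1f +/- %.1f A^3", x$volume, x$volume_se)
              else ""))
  invisible(x)
}

#' Monte-Carlo pocket volume
#'
#' Uniform samples over the bounding box of the pocket's sphere union; a
#' sample counts when inside at least one alpha sphere and outside every
#' atom sphere, so the estimate is the solvent-accessible void volume of
#' the union. A fixed seed makes the estimate bit-reproducible.
#'
#' @param pocket a `pocket` (or `alpha_spheres`) object.
#' @param structure `mol_structure` with radii (atoms excluded from the
#'   volume); pass `NULL` to measure the bare sphere union.
#' @param n_samples sample count (>= 1e4; default 1e5).
#' @param seed RNG seed.
#' @return the pocket with `volume` (A^3) and `volume_se` (binomial
#'   standard error) set; for `alpha_spheres` input, a named vector.
#' @export
pocket_volume <- function(pocket, structure = NULL, n_samples = 1e5, seed = 1) {
  if (n_samples < 1e4) stopf("use at least 1e4 Monte-Carlo samples")
  sp <- if (inherits(pocket, "pocket")) pocket$spheres else pocket
  m <- length(sp$radius)
  if (m == 0) stopf("no alpha spheres to measure")
  lo <- apply(sp$centers - sp$radius, 2, min)
  hi <- apply(sp$centers + sp$radius, 2, max)
  if (any(hi - lo <= 0)) stopf("zero-extent bounding box")
  vbox <- prod(hi - lo)
  axyz <- NULL; ar <- NULL
  if (!is.null(structure)) {
    r <- structure$atoms$radius
    if (anyNA(r)) stopf("assign radii to the structure first")
    xyz <- coords(structure)
    near <- rowSums(sweep(xyz, 2, (lo + hi) / 2)^2) <=
      (sqrt(sum((hi - lo)^2)) / 2 + max(r))^2
    axyz <- xyz[near, , drop = FALSE]; ar <- r[near]
  }
  hits <- 0L
  n_samples <- as.integer(n_samples)
  with_seed(seed, {
    chunk <- 100000L
    done <- 0L
    while (done < n_samples) {
      nb <- min(chunk, n_samples - done)
      pts <- cbind(stats::runif(nb, lo[1], hi[1]),
                   stats::runif(nb, lo[2], hi[2]),
                   stats::runif(nb, lo[3], hi[3]))
      inside <- rep(FALSE, nb)
      for (j in seq_len(m)) {
        dj2 <- (pts[, 1] - sp$centers[j, 1])^2 + (pts[, 2] - sp$centers[j, 2])^2 +
          (pts[, 3] - sp$centers[j, 3])^2
        inside <- inside | dj2 <= sp$radius[j]^2
      }
      if (!is.null(axyz) && nrow(axyz)) {
        cand <- which(inside)
        for (j in seq_len(nrow(axyz))) {
          if (!length(cand)) break
          dj2 <- (pts[cand, 1] - axyz[j, 1])^2 + (pts[cand, 2] - axyz[j, 2])^2 +
            (pts[cand, 3] - axyz[j, 3])^2
          cand <- cand[dj2 > ar[j]^2]
        }
        inside[] <- FALSE; inside[cand] <- TRUE
      }
      hits <- hits + sum(inside)
      done <- done + nb
    }
  })
  p <- hits / n_samples
  vol <- p * vbox
  se <- vbox * sqrt(p * (1 - p) / n_samples)
  if (inherits(pocket, "pocket")) {
    pocket$volume <- vol; pocket$volume_se <- se
    pocket
  } else c(volume = vol, se = se)
}

#' Pocket hydrophobicity
#'
#' Fraction of apolar lining atoms. Lining atoms lie within
#' `contact_cutoff` of any alpha-sphere surface; apolar means element C
#' or S (an element-only rule; bond topology is typically absent).
#' Reported as a proxy score, not comparable to external tools' scales.
#'
#' @param pocket a `pocket`.
#' @param structure `mol_structure` with element data.
#' @param contact_cutoff lining distance to the sphere surface (Angstrom,
#'   default 2.2).
#' @return the pocket with `hydrophobicity` and `lining_atoms` set.
#' @export
pocket_hydrophobicity <- function(pocket, structure, contact_cutoff = 2.2) {
  heavy <- which(structure$atoms$element != "H")
  xyz <- coords(structure)[heavy, , drop = FALSE]
  sp <- pocket$spheres
  d <- cross_dist(xyz, sp$centers)
  surf <- abs(sweep(d, 2, sp$radius))
  lining <- heavy[apply(surf, 1, min) <= contact_cutoff]
  if (!length(lining)) stopf("no lining atoms within %.1f A", contact_cutoff)
  elem <- structure$atoms$element[lining]
  pocket$hydrophobicity <- mean(elem %in% c("C", "S"))
  pocket$lining_atoms <- lining
  pocket
}

#' Pockets near a point
#'
#' @param pockets list of `pocket`.
#' @param point 3-vector (Angstrom), e.g. the heme iron.
#' @param cutoff centroid-to-point distance bound (inclusive; Angstrom).
#' @return the pockets whose centroid lies within `cutoff`, order preserved.
#' @export
pockets_near <- function(pockets, point, cutoff) {
  keep <- vapply(pockets, function(p) sqrt(sum((p$centroid - point)^2)) <= cutoff,
                 TRUE)
  pockets[keep]
}

#' Track pockets across trajectory frames
#'
#' Detects pockets independently on each frame and matches them across
#' frames by centroid proximity, reporting per-track occupancy and average
#' volume.
#'
#' @param trj a `mol_trajectory` with radii on the topology.
#' @param match_cutoff centroid match distance between frames (default 3).
#' @param n_samples Monte-Carlo samples per volume (default 2e4).
#' @param seed RNG seed.
#' @param ... passed to [alpha_spheres()] and [cluster_spheres()].
#' @return data.frame: track id, frames seen, mean centroid, mean volume.
#' @export
track_pockets <- function(trj, match_cutoff = 3.0, n_samples = 2e4, seed = 1, ...) {
  dots <- list(...)
  tracks <- list()
  for (t in seq_len(n_frames(trj))) {
    s <- frame_structure(trj, t)
    sp <- alpha_spheres(s, rmin = dots$rmin %||% 3.4, rmax = dots$rmax %||% 6.2)
    pk <- cluster_spheres(sp, link_cutoff = dots$link_cutoff %||% 1.8,
                          min_spheres = dots$min_spheres %||% 15L)
    for (p in pk) {
      p <- pocket_volume(p, s, n_samples = n_samples, seed = seed + t)
      hit <- NULL
      for (i in seq_along(tracks)) {
        if (sqrt(sum((tracks[[i]]$centroid - p$centroid)^2)) < match_cutoff) {
          hit <- i; break
        }
      }
      if (is.null(hit)) {
        tracks[[length(tracks) + 1L]] <-
          list(centroid = p$centroid, volumes = p$volume, frames = t)
      } else {
        tr <- tracks[[hit]]
        tr$volumes <- c(tr$volumes, p$volume)
        tr$frames <- c(tr$frames, t)
        tr$centroid <- (tr$centroid * (length(tr$frames) - 1) + p$centroid) /
          length(tr$frames)
        tracks[[hit]] <- tr
      }
    }
  }
  if (!length(tracks)) return(data.frame())
  do.call(rbind, lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    data.frame(track = i, n_frames = length(tr$frames),
               x = tr$centroid[1], y = tr$centroid[2], z = tr$centroid[3],
               volume_mean = mean(tr$volumes))
  }))
}
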