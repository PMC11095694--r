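## Grid-based tunnel detection from a buried start point to bulk solvent.
##
## The search discretizes the free space on a regular grid, defines the
## bulk region by rolling a shell-radius probe in from the grid boundary
## and eroding it shell-depth deep, and finds minimum-cost paths from the
## start voxel to each distinct bulk-contact patch with Dijkstra on the
## 26-connected voxel graph. The per-step cost is ds / max(r, eps)^2, so
## wide tunnels are cheap; throughput = exp(-cost * r_ref^2 / L_straight)
## (r_ref = 1 A) lies in (0, 1], increases with width and decreases with
## length and curvature. Absolute values are this package's own ranking
## score and are not comparable across tunnel-detection tools.

TUNNEL_EPS <- 0.05  # A; cost-denominator floor near the prune boundary

## 13 lexicographically-positive neighbour shifts of the 26-neighbourhood
neighbour_shifts <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d[d[, 3] > 0 | (d[, 3] == 0 & d[, 2] > 0) |
      (d[, 3] == 0 & d[, 2] == 0 & d[, 1] > 0), , drop = FALSE]
}

## linear-index pairs (a, b = a + shift) where mask is TRUE at both ends
shift_pairs <- function(mask, d, dims) {
  rng <- function(n, s) if (s >= 0) seq_len(n - s) else (1 - s):n
  ax <- rng(dims[1], d[1]); ay <- rng(dims[2], d[2]); az <- rng(dims[3], d[3])
  sub <- mask[ax, ay, az, drop = FALSE] & mask[ax + d[1], ay + d[2], az + d[3], drop = FALSE]
  w <- which(sub)
  if (!length(w)) return(NULL)
  ijk <- arrayInd(w, dim(sub))
  ia <- cbind(ax[ijk[, 1]], ay[ijk[, 2]], az[ijk[, 3]])
  a <- (ia[, 3] - 1L) * dims[1] * dims[2] + (ia[, 2] - 1L) * dims[1] + ia[, 1]
  b <- a + d[1] + d[2] * dims[1] + d[3] * dims[1] * dims[2]
  cbind(a, b)
}

## one 26-connected dilation step of `set` constrained to `domain`
dilate_once <- function(set, domain, dims) {
  out <- set
  for (s in seq_len(13)) {
    d <- neighbour_shifts()[s, ]
    for (sgn in c(1L, -1L)) {
      dd <- sgn * d
      rng <- function(n, sh) if (sh >= 0) seq_len(n - sh) else (1 - sh):n
      ax <- rng(dims[1], dd[1]); ay <- rng(dims[2], dd[2]); az <- rng(dims[3], dd[3])
      out[ax + dd[1], ay + dd[2], az + dd[3]] <-
        out[ax + dd[1], ay + dd[2], az + dd[3]] | set[ax, ay, az]
    }
  }
  out & domain
}

## flood fill within `domain` from `seeds` (logical arrays), 6-connectivity
flood_fill <- function(seeds, domain, dims) {
  vis <- seeds & domain
  repeat {
    new <- vis
    for (ax in 1:3) {
      d <- c(0L, 0L, 0L); d[ax] <- 1L
      rng <- function(n, sh) seq_len(n - sh)
      ix <- seq_len(dims[1] - d[1]); iy <- seq_len(dims[2] - d[2]); iz <- seq_len(dims[3] - d[3])
      new[ix + d[1], iy + d[2], iz + d[3]] <-
        new[ix + d[1], iy + d[2], iz + d[3]] | vis[ix, iy, iz]
      new[ix, iy, iz] <- new[ix, iy, iz] | vis[ix + d[1], iy + d[2], iz + d[3]]
    }
    new <- new & domain
    if (identical(new, vis)) break
    vis <- new
  }
  vis
}

make_tunnel_path <- function(centerline, radii, cost_raw, snapshot = NA) {
  segs <- sqrt(rowSums((centerline[-1, , drop = FALSE] -
                          centerline[-nrow(centerline), , drop = FALSE])^2))
  len <- sum(segs)
  straight <- sqrt(sum((centerline[nrow(centerline), ] - centerline[1, ])^2))
  cost <- cost_raw / max(straight, 1e-9)           # r_ref = 1 A
  structure(list(centerline = centerline, radii = radii,
                 bottleneck_radius = min(radii), length = len,
                 curvature = len / max(straight, 1e-9),
                 cost = cost, throughput = exp(-cost),
                 snapshot = snapshot), class = "tunnel_path")
}

#' @export
print.tunnel_path <- function(x, ...) {
  cat(sprintf("tunnel_path: bottleneck %.2f A, length %.1f A, curvature %.2f, throughput %.3f\n",
              x$bottleneck_radius, x$length, x$curvature, x$throughput))
  invisible(x)
}

#' Find tunnels from a buried start point to the surface
#'
#' @param structure `mol_structure` with radii assigned.
#' @param start_point 3-vector (Angstrom), e.g. the heme iron position. Snapped
#'   to the highest-free-radius voxel within `snap_radius`.
#' @param min_probe minimum bottleneck radius (Angstrom); narrower paths are
#'   discarded (default 0.9).
#' @param shell_radius probe radius defining bulk solvent (Angstrom, default 3).
#' @param shell_depth erosion depth of the bulk region (Angstrom, default 4).
#' @param spacing grid spacing (Angstrom, default 0.4).
#' @param max_tunnels return at most this many tunnels (default all).
#' @param snap_radius start-point snap radius (Angstrom, default 3).
#' @param max_free_radius cap on the free-radius field (Angstrom, default 6);
#'   must exceed `shell_radius`.
#' @param snapshot optional snapshot tag attached to every returned path.
#' @return list of `tunnel_path`, sorted by decreasing throughput; empty
#'   list when no path reaches bulk with bottleneck >= `min_probe`.
#' @export
find_tunnels <- function(structure, start_point, min_probe = 0.9,
                         shell_radius = 3.0, shell_depth = 4.0, spacing = 0.4,
                         max_tunnels = Inf, snap_radius = 3.0,
                         max_free_radius = 6.0, snapshot = NA) {
  if (max_free_radius <= shell_radius)
    stopf("max_free_radius must exceed shell_radius")
  grid <- free_radius_map(structure, spacing = spacing,
                          padding = shell_radius + 2 * spacing + 0.5,
                          max_radius = max_free_radius)
  dims <- grid$dims
  fieldv <- as.vector(grid$field)
  accessible <- grid$field > 0

  ## start voxel: best free radius within snap_radius of the start point
  s0 <- grid_snap(grid, start_point)
  rr <- as.integer(ceiling(snap_radius / spacing))
  ix <- max(1, s0[1] - rr):min(dims[1], s0[1] + rr)
  iy <- max(1, s0[2] - rr):min(dims[2], s0[2] + rr)
  iz <- max(1, s0[3] - rr):min(dims[3], s0[3] + rr)
  sub <- grid$field[ix, iy, iz, drop = FALSE]
  ctr <- grid_center(grid, as.matrix(expand.grid(ix, iy, iz)))
  ok <- sqrt(colSums((t(ctr) - start_point)^2)) <= snap_radius
  sub_v <- as.vector(sub); sub_v[!ok] <- -Inf
  if (max(sub_v) <= 0) stopf("start point lies inside an atom (free radius <= 0)")
  best <- arrayInd(which.max(sub_v), dim(sub))
  start_ijk <- c(ix[best[1]], iy[best[2]], iz[best[3]])
  start_lin <- grid_index(grid, start_ijk)

  ## bulk: shell_radius-probe region connected to the boundary, dilated
  ## shell_depth inward (Chebyshev steps)
  open_enough <- grid$field >= shell_radius
  boundary <- array(FALSE, dims)
  boundary[c(1, dims[1]), , ] <- TRUE
  boundary[, c(1, dims[2]), ] <- TRUE
  boundary[, , c(1, dims[3])] <- TRUE
  outer_region <- flood_fill(boundary, open_enough, dims)
  bulk <- outer_region
  for (step in seq_len(max(1L, as.integer(round(shell_depth / spacing)))))
    bulk <- dilate_once(bulk, array(TRUE, dims), dims)
  bulk <- bulk & accessible

  interior <- accessible & !bulk
  if (!interior[start_ijk[1], start_ijk[2], start_ijk[3]])
    return(list())  # start already in bulk: nothing buried to escape from

  ## terminal layer: bulk voxels 26-adjacent to interior
  terminal <- dilate_once(interior, bulk, dims) & !interior

  ## voxel graph: interior-interior and interior-terminal edges
  node_ok <- interior | terminal
  shifts <- neighbour_shifts()
  eps <- TUNNEL_EPS
  edges <- vector("list", 13); wts <- vector("list", 13)
  term_v <- as.vector(terminal)
  for (s in seq_len(13)) {
    p <- shift_pairs(node_ok, shifts[s, ], dims)
    if (is.null(p)) next
    keep <- !(term_v[p[, 1]] & term_v[p[, 2]])  # paths end at first bulk voxel
    p <- p[keep, , drop = FALSE]
    if (!nrow(p)) next
    len <- spacing * sqrt(sum(shifts[s, ]^2))
    ra <- pmax(fieldv[p[, 1]], eps); rb <- pmax(fieldv[p[, 2]], eps)
    edges[[s]] <- p
    wts[[s]] <- len * 0.5 * (1 / ra^2 + 1 / rb^2)
  }
  ep <- do.call(rbind, edges)
  if (is.null(ep)) return(list())
  g <- igraph::make_empty_graph(n = prod(dims), directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(ep)), weight = unlist(wts))

  term_lin <- which(term_v)
  if (!length(term_lin)) return(list())
  dvec <- suppressWarnings(igraph::distances(g, v = start_lin, to = term_lin,
                                             weights = igraph::E(g)$weight))[1, ]
  reach <- which(is.finite(dvec))
  if (!length(reach)) return(list())
  term_lin <- term_lin[reach]; dvec <- dvec[reach]

  ## exit regions: connected components of the terminal layer, merged when
  ## their best voxels are within shell_radius (keep the cheaper path)
  tg <- igraph::make_empty_graph(n = length(term_lin), directed = FALSE)
  tpos <- grid_center(grid, grid_ijk(grid, term_lin))
  if (length(term_lin) > 1) {
    remap <- integer(prod(dims)); remap[term_lin] <- seq_along(term_lin)
    tmask <- array(FALSE, dims); tmask[term_lin] <- TRUE
    tedges <- NULL
    for (s in seq_len(13)) {
      p <- shift_pairs(tmask, shifts[s, ], dims)
      if (!is.null(p)) tedges <- rbind(tedges, cbind(remap[p[, 1]], remap[p[, 2]]))
    }
    if (!is.null(tedges)) tg <- igraph::add_edges(tg, as.vector(t(tedges)))
  }
  comp <- igraph::components(tg)$membership
  reps <- vapply(seq_len(max(comp)), function(k) {
    members <- which(comp == k); members[which.min(dvec[members])]
  }, 0L)
  ## merge exit representatives closer than shell_radius
  ord <- order(dvec[reps])
  kept <- integer(0)
  for (r in reps[ord]) {
    if (!length(kept) ||
        min(sqrt(colSums((t(tpos[kept, , drop = FALSE]) - tpos[r, ])^2))) > shell_radius)
      kept <- c(kept, r)
  }

  paths <- list()
  for (r in kept) {
    vp <- suppressWarnings(igraph::shortest_paths(
      g, from = start_lin, to = term_lin[r], weights = igraph::E(g)$weight,
      output = "vpath"))$vpath[[1]]
    lin <- as.integer(vp)
    if (length(lin) < 2) next
    centerline <- grid_center(grid, grid_ijk(grid, lin))
    radii <- fieldv[lin]
    tp <- make_tunnel_path(centerline, radii, dvec[r], snapshot)
    if (tp$bottleneck_radius >= min_probe) paths[[length(paths) + 1L]] <- tp
  }
  paths <- paths[order(-vapply(paths, `[[`, 0, "throughput"))]
  if (is.finite(max_tunnels) && length(paths) > max_tunnels)
    paths <- paths[seq_len(max_tunnels)]
  paths
}

#' Resampled radius-vs-arclength profile of a tunnel
#'
#' @param path a `tunnel_path`.
#' @param resample number of equally spaced arclength samples (>= 2).
#' @return data.frame with columns `arclength`, `radius` (Angstrom).
#' @export
tunnel_profile <- function(path, resample = 50) {
  if (resample < 2) stopf("resample must be >= 2")
  cl <- path$centerline
  segs <- sqrt(rowSums((cl[-1, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE])^2))
  s <- c(0, cumsum(segs))
  grid_s <- seq(0, s[length(s)], length.out = resample)
  data.frame(arclength = grid_s,
             radius = stats::approx(s, path$radii, xout = grid_s, rule = 2)$y)
}

## equal-arclength resampling of a centerline to m 3-d points
resample_centerline <- function(cl, m) {
  segs <- sqrt(rowSums((cl[-1, , drop = FALSE] - cl[-nrow(cl), , drop = FALSE])^2))
  s <- c(0, cumsum(segs))
  grid_s <- seq(0, s[length(s)], length.out = m)
  vapply(1:3, function(k) stats::approx(s, cl[, k], xout = grid_s, rule = 2)$y,
         numeric(m))
}

#' Cluster tunnels into pathway families
#'
#' Pairwise tunnel distance is the mean Euclidean distance between
#' corresponding equal-arclength resampled centerline points; the
#' average-linkage dendrogram (Murtagh algorithm, `hclust`) is cut at the
#' threshold. Clusters are ranked by priority: the sum of member
#' throughputs divided by the snapshot count, so snapshots without a member
#' contribute zero.
#'
#' @param paths list of `tunnel_path`, tagged by snapshot via their
#'   `snapshot` field.
#' @param threshold dendrogram cut height (default 3.5).
#' @param resample centerline resampling points for the distance (default 20).
#' @param n_snapshots snapshot count for priorities; default is the number
#'   of distinct snapshot tags present (untagged input counts as 1).
#' @return list of `tunnel_cluster`, ordered by decreasing priority.
#' @export
cluster_tunnels <- function(paths, threshold = 3.5, resample = 20,
                            n_snapshots = NULL) {
  if (!length(paths)) stopf("no tunnels to cluster")
  tags <- vapply(paths, function(p) as.character(p$snapshot %||% NA), "")
  if (is.null(n_snapshots)) n_snapshots <- max(1L, length(unique(tags[!is.na(tags)])))
  rs <- lapply(paths, function(p) resample_centerline(p$centerline, resample))
  np <- length(paths)
  if (np == 1) {
    membership <- 1L
  } else {
    dm <- matrix(0, np, np)
    for (i in seq_len(np - 1)) for (j in (i + 1):np)
      dm[i, j] <- dm[j, i] <- mean(sqrt(rowSums((rs[[i]] - rs[[j]])^2)))
    hc <- stats::hclust(stats::as.dist(dm), method = "average")
    membership <- stats::cutree(hc, h = threshold)
  }
  clusters <- lapply(seq_len(max(membership)), function(k) {
    members <- paths[membership == k]
    structure(list(members = members,
                   priority = sum(vapply(members, `[[`, 0, "throughput")) / n_snapshots,
                   n_snapshots = n_snapshots), class = "tunnel_cluster")
  })
  clusters[order(-vapply(clusters, `[[`, 0, "priority"))]
}

#' @export
print.tunnel_cluster <- function(x, ...) {
  cat(sprintf("tunnel_cluster: %d members, priority %.3f\n",
              length(x$members), x$priority))
  invisible(x)
}

#' Summary statistics of a tunnel cluster
#'
#' @param cluster a `tunnel_cluster`.
#' @param n_snapshots total snapshot count (>= distinct member tags);
#'   default the value stored on the cluster.
#' @return one-row data.frame: average/sd/max bottleneck radius,
#'   average/sd length, curvature and throughput, priority (sum of member
#'   throughputs / n_snapshots) and occurrence (fraction of snapshots with
#'   at least one member).
#' @export
cluster_statistics <- function(cluster, n_snapshots = cluster$n_snapshots) {
  m <- cluster$members
  if (!length(m)) stopf("empty tunnel cluster")
  tags <- vapply(m, function(p) as.character(p$snapshot %||% NA), "")
  n_tagged <- length(unique(tags[!is.na(tags)]))
  if (n_snapshots < max(1L, n_tagged))
    stopf("n_snapshots is smaller than the number of distinct snapshot tags")
  get <- function(f) vapply(m, `[[`, 0, f)
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  data.frame(
    n_tunnels = length(m),
    bottleneck_avg = mean(get("bottleneck_radius")),
    bottleneck_sd = sd0(get("bottleneck_radius")),
    bottleneck_max = max(get("bottleneck_radius")),
    length_avg = mean(get("length")), length_sd = sd0(get("length")),
    curvature_avg = mean(get("curvature")), curvature_sd = sd0(get("curvature")),
    throughput_avg = mean(get("throughput")), throughput_sd = sd0(get("throughput")),
    priority = sum(get("throughput")) / n_snapshots,
    occurrence = max(1L, n_tagged) / n_snapshots)
}
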