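# Tunnel detection on analytic wall-atom fixtures. The channel generator
# plants a known clearance radius; all expectations read the manifest.

channel_fixture <- function(...) make_channel(inner_radius = 1.5, length = 10,
                                              spacing = 0.8, ...)

test_that("free-radius map is exact against a brute-force oracle", {
  set.seed(7)
  s <- toy_structure(matrix(runif(150, 0, 12), ncol = 3), radius = runif(50, 1, 2))
  g <- free_radius_map(s, spacing = 0.9, padding = 2)
  pts <- as.matrix(expand.grid(g$gx[c(2, 7)], g$gy[c(3, 9)], g$gz[c(1, 8)]))
  idx <- as.matrix(expand.grid(c(2L, 7L), c(3L, 9L), c(1L, 8L)))
  got <- g$field[idx]
  expect_equal(got, brute_free_radius(pts, s), tolerance = 1e-9)
  ## analytic single atom: field = |p| - r everywhere, negative at center
  one <- toy_structure(c(0, 0, 0), radius = 1.7)
  g1 <- free_radius_map(one, spacing = 0.5, padding = 4)
  ctr <- lcpaccess:::grid_center(g1, lcpaccess:::grid_snap(g1, c(0, 0, 0)))[1, ]
  expect_equal(g1$field[matrix(lcpaccess:::grid_snap(g1, c(0, 0, 0)), 1)],
               sqrt(sum(ctr^2)) - 1.7, tolerance = 1e-9)
  expect_lt(min(g1$field), 0)
  expect_error(free_radius_map(s, spacing = 1.5), "spacing")
})

test_that("a single analytic channel yields one tunnel at the planted bottleneck", {
  ch <- channel_fixture()
  mf <- manifest(ch)
  spacing <- 0.5
  paths <- find_tunnels(ch, mf$start_point, spacing = spacing)
  expect_length(paths, mf$n_exits)
  p <- paths[[1]]
  expect_equal(p$bottleneck_radius, mf$inner_radius, tolerance = spacing)
  ## reported bottleneck equals the min of the free-radius field sampled
  ## along the centerline (brute-force oracle), within one grid spacing
  fr <- brute_free_radius(p$centerline, ch)
  expect_equal(p$bottleneck_radius, min(fr), tolerance = spacing)
  ## structural invariants
  expect_equal(p$bottleneck_radius, min(p$radii))
  expect_gte(p$curvature, 1)
  expect_equal(p$throughput, exp(-p$cost), tolerance = 1e-12)
  expect_gt(p$throughput, 0); expect_lte(p$throughput, 1)
})

test_that("channels narrower than the probe are pruned", {
  sealed <- make_channel(inner_radius = 0.5, length = 10, spacing = 0.8)
  expect_length(find_tunnels(sealed, manifest(sealed)$start_point, spacing = 0.5), 0)
  ## a channel just under the default probe is pruned at 0.9 but found
  ## when the probe is lowered (0.8 A still spans two voxels of clearance)
  narrow <- make_channel(inner_radius = 0.8, length = 10, spacing = 0.8)
  expect_length(find_tunnels(narrow, manifest(narrow)$start_point, spacing = 0.5), 0)
  expect_length(find_tunnels(narrow, manifest(narrow)$start_point,
                             spacing = 0.5, min_probe = 0.3), 1)
})

test_that("wider channels have higher throughput (monotonicity)", {
  two <- make_channel(inner_radius = 1.2, length = 10, spacing = 0.8,
                      second_radius = 2.0)
  paths <- find_tunnels(two, manifest(two)$start_point, spacing = 0.5)
  expect_length(paths, 2)
  ## sorted by throughput; the wide channel must rank first
  expect_gt(paths[[1]]$bottleneck_radius, paths[[2]]$bottleneck_radius)
  expect_gt(paths[[1]]$throughput, paths[[2]]$throughput)
})

test_that("Dijkstra path cost is optimal against random monotone paths", {
  ch <- make_channel(inner_radius = 1.5, length = 6, cavity_radius = 3,
                     spacing = 0.8)
  spacing <- 0.5
  paths <- find_tunnels(ch, manifest(ch)$start_point, spacing = spacing)
  p <- paths[[1]]
  ## rebuild the capped field the search used and its cost convention
  g <- free_radius_map(ch, spacing = spacing, padding = 3 + 2 * spacing + 0.5,
                       max_radius = 6)
  eps <- lcpaccess:::TUNNEL_EPS
  seg_cost <- function(a, b) {
    ra <- max(g$field[matrix(a, 1)], eps); rb <- max(g$field[matrix(b, 1)], eps)
    spacing * sqrt(sum((a - b)^2)) * 0.5 * (1 / ra^2 + 1 / rb^2)
  }
  path_cost <- function(ijks) {
    sum(vapply(seq_len(nrow(ijks) - 1),
               function(i) seg_cost(ijks[i, ], ijks[i + 1, ]), 0))
  }
  from <- lcpaccess:::grid_snap(g, p$centerline[1, ])
  to <- lcpaccess:::grid_snap(g, p$centerline[nrow(p$centerline), ])
  returned_raw <- p$cost * (p$length / p$curvature)
  set.seed(5)
  for (trial in 1:40) {
    ## random monotone lattice path: shuffle the needed axis steps
    steps <- unlist(lapply(1:3, function(k) rep(k, abs(to[k] - from[k]))))
    steps <- sample(steps)
    cur <- from; walk <- matrix(from, 1)
    for (st in steps) {
      cur[st] <- cur[st] + sign(to[st] - from[st])
      walk <- rbind(walk, cur)
    }
    if (any(g$field[cbind(walk[, 1], walk[, 2], walk[, 3])] <= 0)) next
    expect_gte(path_cost(walk) + 1e-9, returned_raw)
  }
})

test_that("bottleneck converges as the grid is refined", {
  ch <- make_channel(inner_radius = 1.5, length = 6, cavity_radius = 3,
                     spacing = 0.8)
  b <- vapply(c(0.5, 0.25), function(sp)
    find_tunnels(ch, manifest(ch)$start_point, spacing = sp)[[1]]$bottleneck_radius, 0)
  expect_lt(abs(b[1] - b[2]), 0.5)
  expect_lt(abs(b[2] - 1.5), 0.25 * sqrt(3))
})

test_that("start point inside an atom is rejected", {
  ch <- channel_fixture()
  wall_atom <- coords(ch)[1, ]
  expect_error(find_tunnels(ch, wall_atom, snap_radius = 0.2, spacing = 0.5),
               "inside an atom")
})

test_that("tunnel profiles resample the radius along arclength", {
  ch <- channel_fixture()
  p <- find_tunnels(ch, manifest(ch)$start_point, spacing = 0.5)[[1]]
  prof <- tunnel_profile(p, resample = 40)
  expect_equal(nrow(prof), 40)
  ## arclength axis spans the path length exactly
  expect_equal(max(prof$arclength), p$length, tolerance = 1e-6)
  expect_equal(sum(diff(prof$arclength)), p$length, tolerance = 1e-6)
  ## resampled minimum cannot dip below bottleneck minus one spacing
  expect_gte(min(prof$radius), p$bottleneck_radius - 0.5)
  expect_error(tunnel_profile(p, resample = 1), "resample")
  ## straight synthetic path with constant radius: flat profile
  flat <- lcpaccess:::make_tunnel_path(cbind(0:10, 0, 0), rep(1.3, 11), 1)
  expect_equal(tunnel_profile(flat, 7)$radius, rep(1.3, 7))
})

test_that("tunnel clustering matches a brute-force average-link oracle", {
  mk <- function(offset, through = 0.5, tag = 1) {
    cl <- cbind(seq(0, 10, length.out = 21), offset, 0)
    p <- lcpaccess:::make_tunnel_path(cl, rep(1.5, 21), -log(through) * 10)
    p$snapshot <- tag
    p
  }
  ## identical paths collapse into one cluster
  expect_length(cluster_tunnels(list(mk(0), mk(0))), 1)
  ## parallel paths 10 A apart split at threshold 3.5
  expect_length(cluster_tunnels(list(mk(0), mk(10)), threshold = 3.5), 2)
  ## merge heights match brute-force average-linkage on 6 paths
  offsets <- c(0, 0.5, 1.2, 6, 6.3, 20)
  paths <- lapply(offsets, mk)
  dm <- outer(offsets, offsets, function(a, b) abs(a - b))
  heights <- brute_average_link_heights(dm)
  hc <- hclust(as.dist(dm), method = "average")
  expect_equal(sort(hc$height), sort(heights), tolerance = 1e-9)
  ## the package cut at 3.5 equals components of the oracle dendrogram
  cl <- cluster_tunnels(paths, threshold = 3.5)
  sizes <- sort(vapply(cl, function(x) length(x$members), 0L))
  expect_equal(sizes, c(1L, 2L, 3L))
})

test_that("cluster statistics and priority are recomputable from members", {
  mk <- function(through, bottleneck, tag) {
    p <- lcpaccess:::make_tunnel_path(cbind(seq(0, 10, length.out = 5), 0, 0),
                                      rep(bottleneck, 5), -log(through) * 10)
    p$snapshot <- tag
    p
  }
  ## single member, throughput 0.8, 2 snapshots -> priority 0.4
  cl <- cluster_tunnels(list(mk(0.8, 1.0, 1)), n_snapshots = 2)
  st <- cluster_statistics(cl[[1]])
  expect_equal(st$priority, 0.4, tolerance = 1e-9)
  expect_equal(st$occurrence, 0.5)
  ## bottlenecks {1.0, 1.2}: avg 1.1, max 1.2
  cl2 <- cluster_tunnels(list(mk(0.5, 1.0, 1), mk(0.5, 1.2, 2)), n_snapshots = 2)
  st2 <- cluster_statistics(cl2[[1]])
  expect_equal(st2$bottleneck_avg, 1.1)
  expect_equal(st2$bottleneck_max, 1.2)
  expect_equal(st2$priority, sum(0.5, 0.5) / 2, tolerance = 1e-9)
  ## random members: statistics equal direct recomputation
  set.seed(3)
  th <- runif(5, 0.2, 0.9); bn <- runif(5, 1, 2)
  cl3 <- cluster_tunnels(mapply(mk, th, bn, 1:5, SIMPLIFY = FALSE),
                         threshold = 100, n_snapshots = 5)
  st3 <- cluster_statistics(cl3[[1]])
  expect_equal(st3$throughput_avg, mean(th), tolerance = 1e-9)
  expect_equal(st3$throughput_sd, sd(th), tolerance = 1e-9)
  expect_equal(st3$length_avg, 10, tolerance = 1e-9)
  expect_equal(st3$priority, sum(th) / 5, tolerance = 1e-9)
  expect_error(cluster_statistics(cl3[[1]], n_snapshots = 2), "n_snapshots")
})
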