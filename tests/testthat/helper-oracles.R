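# Independent brute-force oracles and small fixture builders shared by the
# test files. Oracles deliberately use naive enumeration, not the package's
# own code paths.

# simple structure from a coordinate matrix
toy_structure <- function(xyz, element = "C", name = element, resnum = NULL,
                          chain = "A", resname = "TOY", radius = NULL) {
  xyz <- rbind(xyz)
  n <- nrow(xyz)
  s <- molecular_structure(data.frame(
    name = rep_len(name, n), element = rep_len(element, n),
    resname = rep_len(resname, n), resnum = resnum %||% seq_len(n),
    chain = rep_len(chain, n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE))
  if (!is.null(radius)) s$atoms$radius <- rep_len(radius, n)
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a 3-residue toy protein with backbone + waters + a HEM iron
toy_protein <- function() {
  df <- data.frame(
    name = c(rep(c("N", "CA", "C", "O"), 3), "O", "O", "FE"),
    element = c(rep(c("N", "C", "C", "O"), 3), "O", "O", "FE"),
    resname = c(rep(c("ALA", "GLY", "LEU"), each = 4), "HOH", "HOH", "HEM"),
    resnum = c(rep(1:3, each = 4), 101L, 102L, 200L),
    chain = c(rep("A", 12), "A", "B", "A"),
    x = seq(0, by = 1.5, length.out = 15), y = 0, z = 0,
    stringsAsFactors = FALSE)
  s <- molecular_structure(df)
  s$atoms$type[13:15] <- "HETATM"
  s
}

# brute-force free radius at arbitrary points
brute_free_radius <- function(points, structure) {
  xyz <- coords(structure)
  r <- structure$atoms$radius
  apply(rbind(points), 1, function(p)
    min(sqrt(colSums((t(xyz) - p)^2)) - r))
}

# brute-force single-linkage components at a cutoff (union-find)
brute_components <- function(pts, cutoff) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  d <- as.matrix(dist(pts))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (d[i, j] <= cutoff) parent[find(i)] <- find(j)
  vapply(seq_len(n), find, 0L)
}

# naive double-loop LIE oracle on one frame
brute_lie <- function(x, li, ei, charge, eps, rmin_half) {
  evdw <- 0; eele <- 0
  for (i in li) for (j in ei) {
    r <- sqrt(sum((x[i, ] - x[j, ])^2))
    rm <- rmin_half[i] + rmin_half[j]
    e <- sqrt(eps[i] * eps[j])
    evdw <- evdw + e * ((rm / r)^12 - 2 * (rm / r)^6)
    eele <- eele + 332.0636 * charge[i] * charge[j] / r
  }
  c(vdw = evdw, ele = eele)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# brute-force average-linkage agglomeration returning merge heights
brute_average_link_heights <- function(dm) {
  groups <- as.list(seq_len(nrow(dm)))
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_len(length(groups) - 1)) for (j in (i + 1):length(groups)) {
      h <- mean(dm[groups[[i]], groups[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  heights
}
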