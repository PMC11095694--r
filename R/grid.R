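## Regular-grid discretization of the void space around a structure.
## The free-radius field stores, per voxel center, the distance to the
## nearest atom surface (negative inside an atom) -- the radius of the
## largest probe centered there.

#' Free-radius grid map
#'
#' @param structure a `mol_structure` with radii assigned.
#' @param spacing voxel edge length (Angstrom), in (0.2, 1.0].
#' @param padding margin added around the atom bounding box (Angstrom).
#' @param max_radius optional cap: field values are clamped to this value,
#'   allowing the per-atom updates to stay local (used internally by the
#'   tunnel search). `Inf` (default) computes the exact field everywhere.
#' @return a `grid_map`: list with `origin`, `spacing`, `dims`, axes `gx`,
#'   `gy`, `gz` and the 3-d `field` array.
#' @export
free_radius_map <- function(structure, spacing = 0.4, padding = 6,
                            max_radius = Inf) {
  if (n_atoms(structure) == 0) stopf("empty structure")
  if (spacing <= 0.2 || spacing > 1.0) stopf("spacing must be in (0.2, 1.0]")
  r <- structure$atoms$radius
  if (anyNA(r)) stopf("assign radii before building a grid (assign_radii)")
  xyz <- coords(structure)
  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  dims <- pmax(2L, as.integer(ceiling((hi - lo) / spacing)) + 1L)
  gx <- lo[1] + spacing * (seq_len(dims[1]) - 1L)
  gy <- lo[2] + spacing * (seq_len(dims[2]) - 1L)
  gz <- lo[3] + spacing * (seq_len(dims[3]) - 1L)
  field <- array(max_radius, dims)
  ## per-atom local update: only voxels with dist - r_i < current cap matter
  for (i in seq_len(nrow(xyz))) {
    reach <- if (is.finite(max_radius)) max_radius + r[i] else Inf
    ix <- if (is.finite(reach)) which(abs(gx - xyz[i, 1]) <= reach) else seq_along(gx)
    iy <- if (is.finite(reach)) which(abs(gy - xyz[i, 2]) <= reach) else seq_along(gy)
    iz <- if (is.finite(reach)) which(abs(gz - xyz[i, 3]) <= reach) else seq_along(gz)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - xyz[i, 1])^2
    dy2 <- (gy[iy] - xyz[i, 2])^2
    dz2 <- (gz[iz] - xyz[i, 3])^2
    d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+")) - r[i]
    field[ix, iy, iz] <- pmin(field[ix, iy, iz], d)
  }
  structure(list(origin = lo, spacing = spacing, dims = dims,
                 gx = gx, gy = gy, gz = gz, field = field),
            class = "grid_map")
}

## voxel linear index <-> integer (i,j,k) <-> cartesian center
grid_index <- function(grid, ijk) {
  ijk <- rbind(ijk)
  (ijk[, 3] - 1L) * grid$dims[1] * grid$dims[2] + (ijk[, 2] - 1L) * grid$dims[1] + ijk[, 1]
}

grid_ijk <- function(grid, lin) {
  lin <- lin - 1L
  nx <- grid$dims[1]; ny <- grid$dims[2]
  cbind(lin %% nx + 1L, (lin %/% nx) %% ny + 1L, lin %/% (nx * ny) + 1L)
}

grid_center <- function(grid, ijk) {
  ijk <- rbind(ijk)
  cbind(grid$gx[ijk[, 1]], grid$gy[ijk[, 2]], grid$gz[ijk[, 3]])
}

## nearest voxel to a cartesian point
grid_snap <- function(grid, point) {
  ijk <- pmin(pmax(1L, as.integer(round((point - grid$origin) / grid$spacing)) + 1L),
              grid$dims)
  ijk
}

#' @export
print.grid_map <- function(x, ...) {
  cat(sprintf("grid_map: %d x %d x %d voxels, spacing %.2f A\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing))
  invisible(x)
}
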