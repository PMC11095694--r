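## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Evaluate expr with a temporarily seeded RNG, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

## Quasi-uniform unit vectors on the sphere (Fibonacci lattice).
fibonacci_directions <- function(n = 256L) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## Approximate depth of points inside the convex hull of `cloud`, via the
## support function h(d) = max_i <d, x_i> sampled over unit directions:
##   depth(p) = min_d (h(d) - <d, p>)
## Non-negative inside the hull (distance to the boundary in the sampled
## directions), negative outside. Exact in the limit of dense directions.
hull_depth <- function(points, cloud, n_directions = 256L) {
  points <- rbind(points)
  dirs <- fibonacci_directions(n_directions)
  support <- apply(dirs %*% t(cloud), 1, max)   # h(d) per direction
  proj <- dirs %*% t(points)                    # <d, p>
  apply(support - proj, 2, min)
}

## Pairwise Euclidean distances between the rows of two matrices.
cross_dist <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

vec_norm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vec_norm(v)
  if (n < 1e-12) stopf("cannot normalize a zero vector")
  v / n
}
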