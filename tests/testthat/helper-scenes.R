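# Shared fixtures and independent oracles. Scenes are memoised so several
# test files can reuse the same geometry without regenerating it.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  got <- .fixture_cache[[key]]
  if (!is.null(got)) return(got)
  val <- force(expr)
  .fixture_cache[[key]] <- val
  val
}

pc <- function(p) as.matrix(p[, c("x", "y", "z")])

# plain membrane scenes
scene_plain <- function(level = 4L, spacing = 135, seed = 1L)
  cached(sprintf("plain_%d_%g_%d", level, spacing, seed),
         make_mitochondrion(3000, spacing = spacing, level = level,
                            seed = seed))

# independent O(n*m) nearest-centroid oracle
brute_nearest <- function(points, centroids) {
  idx <- integer(nrow(points))
  dst <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    d <- sqrt(colSums((t(centroids) - points[i, ])^2))
    idx[i] <- which.min(d) # which.min takes the lowest index on ties
    dst[i] <- d[idx[i]]
  }
  list(index = idx, distance = dst)
}

# independent O(n^2) Ripley pair-count oracle
brute_ripley <- function(points, r_grid, volume) {
  n <- nrow(points)
  out <- numeric(length(r_grid))
  for (k in seq_along(r_grid)) {
    cnt <- 0L
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (sqrt(sum((points[i, ] - points[j, ])^2)) <= r_grid[k])
        cnt <- cnt + 1L
    }
    out[k] <- volume / (n * (n - 1)) * cnt
  }
  out
}

# a small flat rectangular grid mesh in the z = 0 plane (for patch and
# classification tests); nx x ny cells, each split into two triangles
flat_grid_mesh <- function(nx = 20, ny = 20, pitch = 50, z = 0) {
  xs <- (0:nx) * pitch
  ys <- (0:ny) * pitch
  V <- as.matrix(expand.grid(x = xs, y = ys))
  V <- cbind(V, z)
  vid <- function(i, j) (j - 1L) * (nx + 1L) + i
  F <- matrix(0L, 0, 3)
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    a <- vid(i, j); b <- vid(i + 1L, j)
    c0 <- vid(i, j + 1L); d <- vid(i + 1L, j + 1L)
    F <- rbind(F, c(a, b, d), c(a, d, c0))
  }
  triangle_surface(V, F, surface_id = "OMM")
}

# Monte-Carlo oracle for the chance that a randomly oriented particle
# passes the exit-distance rule: places exit points geometrically and
# measures distances by brute-force (chunked) matrix arithmetic, not via
# the package's spatial-index path.
chance_pass_rate <- function(omm, n_draws, exit_len, standoff, cutoff,
                             seed) {
  set.seed(seed)
  sp <- sample_surface_points(omm, n_draws)
  ctr <- sp$points + standoff * sp$normals
  u <- matrix(rnorm(3 * n_draws), n_draws, 3)
  u <- u / sqrt(rowSums(u^2))
  exitp <- ctr + exit_len * u
  cen <- omm$centroids
  pass <- logical(n_draws)
  step <- 500L
  for (s in seq(1L, n_draws, by = step)) {
    idx <- s:min(s + step - 1L, n_draws)
    blk <- exitp[idx, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rep(1, nrow(cen))) +
      outer(rep(1, length(idx)), rowSums(cen^2)) -
      2 * blk %*% t(cen)
    pass[idx] <- sqrt(pmax(apply(d2, 1, min), 0)) <= cutoff
  }
  mean(pass)
}
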