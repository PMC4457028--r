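# Internal helpers: seeded evaluation, truncated normals, array smoothing.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-item substream seeds (kept below 2^31).
derive_seed <- function(seed, i) {
  s <- (as.numeric(seed) %% 2147483629 + 999331 * as.numeric(i)) %% 2147483629
  as.integer(s) + 1L
}

# Truncated normal sampling by inverse CDF; degenerate sd collapses to the mean.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Closed-form moments of the truncated normal (used by tests and docs).
truncnorm_moments <- function(mean, sd, lower = -Inf, upper = Inf) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  pa <- stats::dnorm(a); pb <- stats::dnorm(b)
  apa <- if (is.finite(a)) a * pa else 0
  bpb <- if (is.finite(b)) b * pb else 0
  m <- mean + sd * (pa - pb) / Z
  v <- sd^2 * (1 + (apa - bpb) / Z - ((pa - pb) / Z)^2)
  list(mean = m, sd = sqrt(v))
}

# Edge-renormalized 1D Gaussian smoothing matrix (n x n).
smoothing_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  h <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq(-h, h), sd = sigma)
  K <- matrix(0, n, n)
  for (d in seq(-h, h)) {
    idx <- seq_len(n)
    j <- idx + d
    ok <- j >= 1 & j <= n
    K[cbind(idx[ok], j[ok])] <- k[d + h + 1]
  }
  K / rowSums(K)
}

# Separable Gaussian smoothing of a 3D array; sigma given per dimension
# (in voxel units, order matching dim(a)).
smooth_3d <- function(a, sigma) {
  d <- dim(a)
  stopifnot(length(d) == 3, length(sigma) == 3)
  for (ax in 1:3) {
    if (sigma[ax] > 0) {
      K <- smoothing_matrix(d[1], sigma[ax])
      a <- array(K %*% matrix(a, d[1]), d)
    }
    # rotate axes: dim order (1,2,3) -> (2,3,1)
    a <- aperm(a, c(2, 3, 1))
    d <- dim(a)
    sigma <- sigma[c(2, 3, 1)]
  }
  a
}

smooth_2d <- function(m, sigma) {
  a <- smooth_3d(array(m, c(dim(m), 1)), c(sigma, sigma, 0))
  a[, , 1]
}

# Strict local maxima over the 26-neighborhood of a 3D array.
local_maxima_3d <- function(a) {
  d <- dim(a)
  res <- array(TRUE, d)
  pad_shift <- function(a, s) {
    # shift a by s (length 3), filling with -Inf
    out <- array(-Inf, d)
    src <- dst <- vector("list", 3)
    for (k in 1:3) {
      if (s[k] >= 0) {
        src[[k]] <- seq_len(d[k] - s[k])
        dst[[k]] <- src[[k]] + s[k]
      } else {
        src[[k]] <- seq_len(d[k] + s[k]) - s[k]
        dst[[k]] <- seq_len(d[k] + s[k])
      }
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    res <- res & (a > pad_shift(a, c(dy, dx, dz)))
    if (!any(res)) return(res)
  }
  res
}

# 3D flood fill (6-connectivity) from a set of seed linear indices within
# `mask`; returns logical array of reached voxels. Vectorized frontier BFS.
flood_3d <- function(mask, seeds) {
  d <- dim(mask)
  n1 <- d[1]; n12 <- d[1] * d[2]
  visited <- array(FALSE, d)
  if (length(seeds) == 0) return(visited)
  seeds <- seeds[mask[seeds]]
  visited[seeds] <- TRUE
  frontier <- seeds
  # precompute coordinates helpers for border checks
  while (length(frontier) > 0) {
    i1 <- ((frontier - 1) %% n1) + 1
    i2 <- ((frontier - 1) %/% n1) %% d[2] + 1
    i3 <- ((frontier - 1) %/% n12) + 1
    nb <- c(frontier[i1 > 1] - 1L,
            frontier[i1 < d[1]] + 1L,
            frontier[i2 > 1] - n1,
            frontier[i2 < d[2]] + n1,
            frontier[i3 > 1] - n12,
            frontier[i3 < d[3]] + n12)
    nb <- unique(nb)
    nb <- nb[mask[nb] & !visited[nb]]
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

# Largest 6-connected component of a logical 3D array.
largest_component_3d <- function(mask) {
  remaining <- mask
  best <- NULL
  best_n <- 0L
  while (any(remaining)) {
    seed <- which(remaining)[1]
    comp <- flood_3d(remaining, seed)
    n <- sum(comp)
    if (n > best_n) { best <- comp; best_n <- n }
    remaining <- remaining & !comp
  }
  if (is.null(best)) array(FALSE, dim(mask)) else best
}

# Fill interior holes: background voxels not reachable from the array border.
fill_holes_3d <- function(mask) {
  d <- dim(mask)
  bg <- !mask
  idx <- array(seq_len(prod(d)), d)
  border <- unique(c(idx[c(1, d[1]), , ], idx[, c(1, d[2]), ], idx[, , c(1, d[3])]))
  outside <- flood_3d(bg, border)
  mask | (bg & !outside)
}

border_fraction_3d <- function(mask) {
  d <- dim(mask)
  n <- sum(mask)
  if (n == 0) return(0)
  on_border <- sum(mask[c(1, d[1]), , ]) + sum(mask[-c(1, d[1]), c(1, d[2]), ]) +
    sum(mask[-c(1, d[1]), -c(1, d[2]), c(1, d[3])])
  on_border / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a
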