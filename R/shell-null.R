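# Monte Carlo null model: distances between two uniform random points in
# the nucleoplasm shell (nucleus interior minus the nucleolus).

#' Nucleoplasm shell geometry
#'
#' The sampling domain of the geometric null: a spherical shell with outer
#' radius `r` (the nucleus) and inner radius `r_prime` (the nucleolus);
#' sampled radial coordinates r_x satisfy r' < r_x <= r. The nucleolus must
#' be strictly smaller than the nucleus, otherwise the shell constraint is
#' unsatisfiable.
#'
#' @param r nucleus radius (um), > 0.
#' @param r_prime nucleolus radius (um), in [0, r).
#' @return object of class `shell_geometry`.
#' @export
shell_geometry <- function(r = 2.3, r_prime = 1.17) {
  stopifnot(is.numeric(r), is.numeric(r_prime), r > 0)
  if (r_prime < 0 || r_prime >= r)
    stop("need 0 <= r_prime < r: the nucleolus radius must be strictly ",
         "smaller than the nucleus radius for the shell constraint ",
         "r' < r_x <= r to be satisfiable")
  structure(list(r = r, r_prime = r_prime), class = "shell_geometry")
}

#' @export
print.shell_geometry <- function(x, ...) {
  cat(sprintf("<shell_geometry> nucleus r = %.3g um, nucleolus r' = %.3g um\n",
              x$r, x$r_prime))
  invisible(x)
}

#' Sample points uniformly in the nucleoplasm shell
#'
#' Exact, branch-free sampling: directions uniform on the unit sphere
#' (normalized Gaussian triples) and radii from the inverse CDF of the
#' volume (r^3) law restricted to (r'^3, r^3].
#'
#' @param geometry a [shell_geometry()].
#' @param n number of points.
#' @return n x 3 matrix of coordinates with the radial coordinate of each
#'   point in attribute `"radius"`.
#' @export
sample_shell_points <- function(geometry, n) {
  stopifnot(inherits(geometry, "shell_geometry"), n >= 1)
  u <- stats::runif(n)
  radius <- (geometry$r_prime^3 + u * (geometry$r^3 - geometry$r_prime^3))^(1 / 3)
  dirs <- random_directions(n)
  pts <- dirs * radius
  attr(pts, "radius") <- radius
  pts
}

#' Monte Carlo null distribution of inter-point distances in the shell
#'
#' Draws `n_pairs` independent pairs of uniform points in the nucleoplasm
#' shell and records their Euclidean distances — the null model for the
#' inter-allelic distance if the two loci were placed at random in the
#' nucleoplasm.
#'
#' @param geometry a [shell_geometry()].
#' @param n_pairs number of point pairs (default 1e6).
#' @param seed integer seed (recorded in the result).
#' @return object of class `shell_null`: `geometry`, `n_pairs`, `distances`,
#'   `mean`, `sd` (0 by convention for a single pair), `seed`.
#' @export
simulate_shell_null <- function(geometry, n_pairs = 1e6, seed = NULL) {
  stopifnot(inherits(geometry, "shell_geometry"), n_pairs >= 1)
  with_seed(seed, {
    p1 <- sample_shell_points(geometry, n_pairs)
    p2 <- sample_shell_points(geometry, n_pairs)
    d <- sqrt(rowSums((p1 - p2)^2))
    structure(list(geometry = geometry, n_pairs = as.integer(n_pairs),
                   distances = d, mean = mean(d),
                   sd = if (n_pairs >= 2) stats::sd(d) else 0,
                   seed = seed),
              class = "shell_null")
  })
}

#' @export
print.shell_null <- function(x, ...) {
  cat(sprintf("<shell_null> r = %.3g, r' = %.3g um: mean distance %.4f +/- %.4f um (n = %d pairs)\n",
              x$geometry$r, x$geometry$r_prime, x$mean, x$sd, x$n_pairs))
  invisible(x)
}

#' Compare a measured distance sample with the shell null
#'
#' Reports the measured mean, the null mean, and a one-sided resampling
#' p-value for the hypothesis that the measured mean exceeds the null mean:
#' samples of the measured size are repeatedly drawn from the null
#' distances, and p = (1 + #\{resampled mean >= measured mean\}) /
#' (n_resamples + 1). A Welch t-test of the measured sample against the
#' null sample is available by flag.
#'
#' @param measured numeric vector of measured distances (um), n >= 2.
#' @param geometry a [shell_geometry()].
#' @param n_null_pairs null sample size.
#' @param n_resamples number of resampled means.
#' @param seed integer seed.
#' @param method `"resampling"` (default) or `"welch"`.
#' @return object of class `null_comparison`: `measured_mean`, `measured_n`,
#'   `null_mean`, `null_n`, `p`, `direction` (`"longer"`/`"shorter"`),
#'   `method`, `geometry`, `seed`.
#' @export
compare_to_null <- function(measured, geometry, n_null_pairs = 1e5,
                            n_resamples = 1999, seed = NULL,
                            method = c("resampling", "welch")) {
  method <- match.arg(method)
  measured <- measured[is.finite(measured)]
  if (length(measured) < 2) stop("need at least 2 measured distances")
  null <- simulate_shell_null(geometry, n_null_pairs, seed = seed)
  mm <- mean(measured)
  if (method == "resampling") {
    p <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, 1L), {
      res <- matrix(sample(null$distances, length(measured) * n_resamples,
                           replace = TRUE), nrow = n_resamples)
      (1 + sum(rowMeans(res) >= mm)) / (n_resamples + 1)
    })
  } else {
    p <- stats::t.test(measured, null$distances,
                       alternative = "greater")$p.value
  }
  structure(list(measured_mean = mm, measured_n = length(measured),
                 null_mean = null$mean, null_n = null$n_pairs,
                 p = p,
                 direction = if (mm > null$mean) "longer" else "shorter",
                 method = method, geometry = geometry, seed = seed),
            class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat(sprintf("<null_comparison> measured mean %.3f um (n = %d) vs null mean %.3f um (n = %d pairs)\n",
              x$measured_mean, x$measured_n, x$null_mean, x$null_n))
  cat(sprintf("  measured %s than null; one-sided p = %.4g (%s)\n",
              x$direction, x$p, x$method))
  invisible(x)
}
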