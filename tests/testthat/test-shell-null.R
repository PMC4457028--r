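# Monte Carlo shell null: sampling law, closed-form limits, comparison test.

test_that("the constructor rejects a nucleolus at least as large as the nucleus", {
  expect_error(shell_geometry(1.17, 2.3), "strictly")
  expect_error(shell_geometry(2.3, 2.3), "strictly")
  expect_s3_class(shell_geometry(2.3, 1.17), "shell_geometry")
  expect_s3_class(shell_geometry(1, 0), "shell_geometry")
})

test_that("sampled radii obey the restricted r^3 law", {
  geoms <- list(c(1, 0), c(2.3, 1.17), c(2, 1.8))
  for (g in geoms) {
    geo <- shell_geometry(g[1], g[2])
    set.seed(71)
    pts <- sample_shell_points(geo, 1e5)
    rad <- attr(pts, "radius")
    expect_true(all(rad > g[2] & rad <= g[1]))
    ks <- suppressWarnings(ks.test(rad, shell_radius_cdf(g[1], g[2])))
    expect_gt(ks$p.value, 0.01)
  }
  # full ball: mean radius 3r/4
  geo <- shell_geometry(2, 0)
  set.seed(72)
  rad <- attr(sample_shell_points(geo, 2e5), "radius")
  expect_equal(mean(rad), 3 * 2 / 4, tolerance = 0.005)
})

test_that("inverse-CDF sampling matches the brute-force rejection oracle", {
  geo <- shell_geometry(2.3, 1.17)
  set.seed(73)
  r_pkg <- attr(sample_shell_points(geo, 4e4), "radius")
  r_orc <- sqrt(rowSums(sample_shell_rejection(2.3, 1.17, 4e4)^2))
  expect_gt(suppressWarnings(ks.test(r_pkg, r_orc))$p.value, 0.01)
  expect_equal(mean(r_pkg), mean(r_orc), tolerance = 0.01)
})

with_seed_pts <- function(geo, n, seed) {
  set.seed(seed)
  sample_shell_points(geo, n)
}

test_that("null mean matches the closed forms in both limits", {
  # full ball: mean pairwise distance 36 r / 35
  n1 <- simulate_shell_null(shell_geometry(1, 0), 1e6, seed = 74)
  expect_equal(n1$mean, 36 / 35, tolerance = 0.002)
  n23 <- simulate_shell_null(shell_geometry(2.3, 0), 4e5, seed = 75)
  expect_equal(n23$mean, 36 * 2.3 / 35, tolerance = 0.005)
  # thin-shell limit: mean distance between points on a sphere -> 4r/3
  thin <- simulate_shell_null(shell_geometry(1, 0.999), 4e5, seed = 76)
  expect_equal(thin$mean, 4 / 3, tolerance = 0.005)
  rad <- attr(with_seed_pts(shell_geometry(1, 0.999), 1e4, 77), "radius")
  expect_true(all(rad >= 0.999 & rad <= 1))
})

test_that("null mean is non-decreasing in the nucleolus radius", {
  r <- 2.3
  means <- vapply(c(0, 0.5, 1, 1.5, 2), function(rp)
    simulate_shell_null(shell_geometry(r, rp), 1e5, seed = 78)$mean,
    numeric(1))
  expect_true(all(diff(means) >= 0))
})

test_that("null simulation is deterministic under a seed and handles n = 1", {
  g <- shell_geometry(2.3, 1.17)
  a <- simulate_shell_null(g, 1e4, seed = 79)
  b <- simulate_shell_null(g, 1e4, seed = 79)
  expect_identical(a$distances, b$distances)
  expect_true(all(a$distances > 0 & a$distances <= 2 * 2.3))
  one <- simulate_shell_null(g, 1, seed = 80)
  expect_equal(one$sd, 0)
  expect_length(one$distances, 1)
})

test_that("comparison against the null is calibrated and detects excess", {
  g <- shell_geometry(2.3, 1.17)
  # a sample at the maximum distance cannot be exceeded by resampling
  cmp_max <- compare_to_null(rep(2 * 2.3, 20), g, n_null_pairs = 2e4,
                             n_resamples = 199, seed = 81)
  expect_lte(cmp_max$p, 1 / 200)
  # measured ~ meristematic scale is longer than the null, p < 0.01
  set.seed(82)
  meas <- rnorm(105, 3.5, 0.8)
  cmp <- compare_to_null(meas, g, n_null_pairs = 5e4, seed = 83)
  expect_equal(cmp$direction, "longer")
  expect_lt(cmp$p, 0.01)
  expect_equal(cmp$measured_n, 105)
  # calibration: measured drawn from the null itself -> uniform p
  ref <- simulate_shell_null(g, 2e5, seed = 84)
  set.seed(85)
  ps <- vapply(1:200, function(i) {
    meas_i <- sample(ref$distances, 20)
    res <- matrix(sample(ref$distances, 20 * 199, replace = TRUE), 199)
    (1 + sum(rowMeans(res) >= mean(meas_i))) / 200
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)
  expect_error(compare_to_null(numeric(0), g), "at least 2")
})
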