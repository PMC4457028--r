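# Nucleus segmentation, volumetry, and the distance-volume statistics.

test_that("sphere and ellipsoid volumes are recovered within 5%", {
  m <- nucleus_model(size_jitter_sd = 0)
  seg <- segment_nucleus(simulate_nucleus_stack(m, separation = 3.5,
                                                seed = 51)$stack)
  va <- 4 / 3 * pi * 2.3^3
  expect_lt(abs(seg$measurement$volume_um3 - va) / va, 0.05)
  expect_false(seg$measurement$clipped)

  me <- nucleus_model("elongation", size_jitter_sd = 0)
  sege <- segment_nucleus(simulate_nucleus_stack(me, separation = 5,
                                                 seed = 52)$stack)
  vae <- 4 / 3 * pi * 4.6 * 3.25 * 3.25
  expect_lt(abs(sege$measurement$volume_um3 - vae) / vae, 0.05)
})

test_that("volume error shrinks at least twofold with half-size voxels", {
  va <- 4 / 3 * pi * 2.3^3
  mc <- nucleus_model(size_jitter_sd = 0, noise = FALSE)
  mf <- nucleus_model(size_jitter_sd = 0, noise = FALSE,
                      voxel_size = c(x = 0.05, y = 0.05, z = 0.25))
  ec <- abs(segment_nucleus(simulate_nucleus_stack(mc, separation = 3.5,
                                                   seed = 53)$stack)$measurement$volume_um3 - va)
  ef <- abs(segment_nucleus(simulate_nucleus_stack(mf, separation = 3.5,
                                                   seed = 53)$stack)$measurement$volume_um3 - va)
  expect_lt(ef, ec / 2)
})

test_that("segmentation errors on structureless input and flags clipping", {
  st <- image_stack(array(7, c(20, 20, 6)), c(x = 0.1, y = 0.1, z = 0.5),
                    channels = "nucleus")
  expect_error(segment_nucleus(st), "no contrast")
  # zero margin: the nucleus touches the border and is flagged clipped
  m0 <- nucleus_model(size_jitter_sd = 0, margin = 0, noise = FALSE)
  seg <- segment_nucleus(simulate_nucleus_stack(m0, separation = 2,
                                                seed = 54)$stack)
  expect_true(seg$measurement$clipped)
})

test_that("distance-volume correlation behaves as expected", {
  set.seed(61)
  vol <- runif(100, 30, 250)
  dist_linear <- 0.01 * vol + rnorm(100, 0, 1e-6)
  r <- correlate_distance_volume(dist_linear, vol)
  expect_gt(r$r, 0.99)
  expect_equal(r$n, 100)
  # affine invariance
  r2 <- correlate_distance_volume(3 * dist_linear + 2, 0.5 * vol - 7)
  expect_equal(r2$r, r$r, tolerance = 1e-9)
  expect_true(abs(r$r) <= 1)
  # shuffled distances: |r| < 0.3 at n = 100 in >= 95% of replicates
  ok <- vapply(1:100, function(i) {
    abs(correlate_distance_volume(sample(dist_linear), vol)$r) < 0.3
  }, logical(1))
  expect_gte(mean(ok), 0.95)
  expect_error(correlate_distance_volume(rep(1, 10), vol[1:10]),
               "zero variance")
  expect_error(correlate_distance_volume(1:2, 1:2), "at least 3")
})

test_that("volume comparison has correct size and power", {
  set.seed(62)
  # type I error at n = 100 per group
  p_null <- vapply(1:200, function(i)
    compare_volumes(list(a = rnorm(100, 50, 8), b = rnorm(100, 50, 8)))$p,
    numeric(1))
  expect_gte(mean(p_null > 0.05), 0.90)
  # power: 3-SD mean shift at n = 50 per group
  p_alt <- vapply(1:100, function(i)
    compare_volumes(list(a = rnorm(50, 50, 8), b = rnorm(50, 74, 8)))$p,
    numeric(1))
  expect_gte(mean(p_alt < 0.01), 0.95)
  # degenerate identical constant groups
  expect_equal(compare_volumes(list(a = rep(5, 4), b = rep(5, 4)))$p, 1)
  expect_error(compare_volumes(list(a = 1, b = 1:3)), "at least 2")
  # Mann-Whitney flag
  expect_lt(compare_volumes(list(a = rnorm(50, 50, 8), b = rnorm(50, 74, 8)),
                            method = "wilcoxon")$p, 0.01)
})
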