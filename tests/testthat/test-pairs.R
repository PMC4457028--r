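# Pairing, distance summaries, pairing frequency, series tracking.

test_that("pair distance is the physical Euclidean norm, symmetric and non-negative", {
  p <- fake_pair(c(0, 0, 0), c(0, 0, 3.5))
  expect_equal(p$distance_um, 3.5)
  expect_false(p$paired)
  q <- fake_pair(c(0, 0, 3.5), c(0, 0, 0))
  expect_equal(q$distance_um, p$distance_um)
  r <- fake_pair(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$distance_um, 0)
  expect_true(r$paired)
  s <- fake_pair(c(0, 0, 0), c(0, 0.3, 0))
  expect_equal(s$distance_um, 0.3)
  expect_true(s$paired)
})

test_that("a single high-score detection counts as a fully overlapped pair", {
  det <- data.frame(x_um = 1, y_um = 1, z_um = 1, peak = 100, score = 30,
                    amplitude = 2000, residual = 1, converged = TRUE)
  p <- measure_pair(det, pairing_threshold = 0.4)
  expect_equal(p$distance_um, 0)
  expect_true(p$paired)
  expect_equal(p$n_candidates, 1L)
})

test_that("summaries exclude paired loci from the distance sample", {
  pairs <- c(lapply(c(3, 4, 5), pair_with_distance),
             list(pair_with_distance(0.1)))
  s <- summarize_distances(pairs)
  expect_equal(s$n, 3)
  expect_equal(s$mean, 4)
  expect_equal(s$sd, 1)
  expect_equal(s$n_paired, 1)
  expect_equal(s$n_total, 4)
  s_all <- summarize_distances(pairs, exclude_paired = FALSE)
  expect_equal(s_all$n, 4)
  # ten pairs, one paired
  pairs10 <- c(lapply(seq(1, 4.6, length.out = 9), pair_with_distance),
               list(pair_with_distance(0)))
  expect_equal(summarize_distances(pairs10)$n, 9)
  # all paired -> empty distance sample
  expect_error(summarize_distances(list(pair_with_distance(0.1),
                                        pair_with_distance(0.2))),
               "empty distance sample")
  expect_error(summarize_distances(list(NULL, NULL)), "no measurable")
})

test_that("pairing frequency uses the root as replication unit", {
  mk_root <- function(n, n_paired)
    c(lapply(seq_len(n - n_paired), function(i) pair_with_distance(3)),
      lapply(seq_len(n_paired), function(i) pair_with_distance(0.1)))
  pf <- pairing_frequency(list(r1 = mk_root(30, 2)))
  expect_equal(pf$per_root$frequency, 2 / 30)
  pf0 <- pairing_frequency(list(r1 = mk_root(30, 0), r2 = mk_root(30, 0)))
  expect_equal(pf0$mean, 0)
  pf1 <- pairing_frequency(list(r1 = mk_root(30, 30)))
  expect_equal(pf1$mean, 1)
  expect_warning(pairing_frequency(list(r1 = mk_root(10, 1))), "only 10")
  expect_error(pairing_frequency(list()), "no roots")
  # partition: paired + distance sample = measurable nuclei
  pairs <- mk_root(30, 4)
  s <- summarize_distances(pairs)
  expect_equal(s$n + s$n_paired, s$n_total)
})

test_that("series tracking reports constant distances and flags missing frames", {
  m <- small_model()
  ser <- simulate_time_series(m, n_timepoints = 4, drift = 0.1,
                              separation = 1.6, seed = 41)
  tr <- track_series(ser)
  expect_equal(nrow(tr$trace), 4)
  expect_true(all(tr$trace$measurable))
  expect_lt(tr$cv, 0.10)
  # replace one frame with pure background -> recorded missing
  blank <- image_stack(array(10, dim(ser[[1]]$stack$data)[1:3]),
                       ser[[1]]$stack$voxel_size)
  stacks <- lapply(ser, `[[`, "stack")
  stacks[[2]] <- blank
  tr2 <- track_series(stacks)
  expect_false(tr2$trace$measurable[2])
  expect_true(is.na(tr2$trace$distance_um[2]))
  expect_true(all(tr2$trace$measurable[-2]))
})
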