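# Generator: geometry, intensity conservation, separation distribution,
# dose response, time series, reproducibility.

test_that("separation override places foci at the exact requested distance", {
  m <- nucleus_model(size_jitter_sd = 0)
  sim <- simulate_nucleus_stack(m, separation = 3.5, seed = 11)
  expect_equal(sim$truth$separation, 3.5)
  d <- sqrt(sum((sim$truth$coords[1, ] - sim$truth$coords[2, ])^2))
  expect_equal(d, 3.5, tolerance = 1e-12)

  sim0 <- simulate_nucleus_stack(m, separation = 0, seed = 12)
  expect_identical(sim0$truth$coords[1, ], sim0$truth$coords[2, ])
  expect_equal(sim0$truth$separation, 0)
})

test_that("noiseless foci channel integrates to twice the amplitude", {
  m <- small_model(noise = FALSE)
  sim <- simulate_nucleus_stack(m, separation = 1.5, seed = 3)
  f <- stack_channel(sim$stack, "foci")
  total <- sum(f - m$background)
  expect_equal(total, 2 * m$amplitude, tolerance = 0.01)
})

test_that("truth coordinates always satisfy the nucleoplasm constraints", {
  m <- small_model(noise = FALSE)
  for (i in 1:40) {
    sim <- simulate_nucleus_stack(m, seed = 300 + i)
    rel <- sweep(sim$truth$coords, 2,
                 c(sim$truth$center[["x"]], sim$truth$center[["y"]],
                   sim$truth$center[["z"]]))
    ok <- locipair:::in_nucleoplasm(rel, sim$truth$semi_axes,
                                    sim$truth$nucleolus_radius)
    expect_true(all(ok), info = paste("nucleus", i))
  }
})

test_that("impossible separations error out", {
  m <- small_model()
  expect_error(simulate_nucleus_stack(m, separation = 10, seed = 1),
               "cannot be placed")
  expect_error(simulate_nucleus_stack(m, separation = -1), "non-negative")
})

test_that("truth separations follow the truncated-normal model", {
  # parameters chosen so the geometric upper bound is rarely active and
  # the placement step does not distort the draw
  m <- nucleus_model(semi_axes = c(x = 2.3, y = 2.3, z = 2.3),
                     nucleolus_radius = 1.17, separation_mean = 2,
                     separation_sd = 0.5, size_jitter_sd = 0, noise = FALSE)
  n <- 600
  seps <- vapply(seq_len(n), function(i)
    simulate_nucleus_stack(m, seed = 10000 + i)$truth$separation, numeric(1))
  mo <- locipair:::truncnorm_moments(2, 0.5, 0, 2 * 2.3)
  se_mean <- mo$sd / sqrt(n)
  expect_lt(abs(mean(seps) - mo$mean), 3 * se_mean)
  se_sd <- mo$sd / sqrt(2 * (n - 1))
  expect_lt(abs(sd(seps) - mo$sd), 3 * se_sd)
})

test_that("identical seed and model give bit-identical stacks", {
  m <- small_model()
  a <- simulate_nucleus_stack(m, seed = 77)
  b <- simulate_nucleus_stack(m, seed = 77)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$coords, b$truth$coords)
  c <- simulate_nucleus_stack(m, seed = 78)
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("elongation nuclei are larger than meristematic under defaults", {
  vm <- locipair:::nucleus_volume(nucleus_model("meristematic")$semi_axes)
  ve <- locipair:::nucleus_volume(nucleus_model("elongation")$semi_axes)
  expect_gt(ve, vm)
  expect_gt(nucleus_model("elongation")$separation_mean,
            nucleus_model("meristematic")$separation_mean)
})

test_that("dose-response prediction is monotone in dose and recovers by 24 h", {
  dr <- dose_response_model()
  doses <- seq(0, 300, by = 25)
  pred <- predict_separation(dr, doses, time_h = 0)
  expect_true(all(diff(pred) <= 0))
  expect_equal(predict_separation(dr, 0), dr$baseline)
  # 24-h recovery within 2% of baseline
  expect_lt(abs(predict_separation(dr, 150, time_h = 24) - dr$baseline),
            0.02 * dr$baseline)
  # shortening switch disables the effect entirely
  expect_equal(predict_separation(dr, 150, shortening = FALSE), dr$baseline)
  expect_equal(predict_pairing(dr, 150, pairing = FALSE), 0)
})

test_that("dose panels shorten truth separations but not volumes", {
  m <- small_model(separation_mean = 3.5)
  m$semi_axes <- c(x = 2.3, y = 2.3, z = 2.3)
  m$nucleolus_radius <- 1.17
  m$size_jitter_sd <- 0.08
  dr <- dose_response_model()
  panel <- simulate_dose_panel(m, dr, doses = c(0, 150), n_per_dose = 30,
                               time_h = 0, seed = 5, noise = FALSE)
  man <- panel$manifest
  s0 <- man$truth_separation_um[man$dose_gy == 0]
  s1 <- man$truth_separation_um[man$dose_gy == 150]
  expect_lt(mean(s1), mean(s0))
  # volume distribution must not depend on dose
  v0 <- man$truth_volume_um3[man$dose_gy == 0]
  v1 <- man$truth_volume_um3[man$dose_gy == 150]
  expect_gt(t.test(v0, v1)$p.value, 0.01)
  # 24-h panel returns near baseline
  p24 <- simulate_dose_panel(m, dr, 150, 30, time_h = 24, seed = 6,
                             noise = FALSE)
  expect_lt(abs(mean(p24$manifest$truth_separation_um) - mean(s0)), 0.35)
})

test_that("time series hold the separation constant and span the interval", {
  m <- small_model(noise = FALSE)
  ser <- simulate_time_series(m, n_timepoints = 7, interval_min = 10,
                              drift = 0.15, separation = 1.5, seed = 9)
  expect_length(ser, 7)
  seps <- vapply(ser, function(s) s$truth$separation, numeric(1))
  expect_true(all(seps == seps[1]))
  times <- vapply(ser, function(s) s$truth$time_min, numeric(1))
  expect_equal(times, seq(0, 60, by = 10))
  # drift-free series: truth coordinates identical at every frame
  ser0 <- simulate_time_series(m, n_timepoints = 3, drift = 0,
                               separation = 1.5, seed = 10)
  expect_identical(ser0[[1]]$truth$coords, ser0[[3]]$truth$coords)
  # error mode when the walk leaves the margin
  expect_error(simulate_time_series(m, n_timepoints = 30, drift = 1.5,
                                    separation = 1, seed = 11,
                                    on_exit = "error"),
               "walked outside")
})

test_that("nucleus model rejects invalid geometry", {
  expect_error(nucleus_model(nucleolus_radius = 3), "inside the nucleus")
  expect_error(nucleus_model(separation_mean = -1))
})
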