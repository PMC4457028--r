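# Comet generator and DSB metrics.

test_that("rendered intensity is conserved between head and tail", {
  for (f in c(0, 0.25, 0.5, 0.75, 1)) {
    cm <- comet_model(tail_fraction = f, noise = FALSE)
    sim <- simulate_comet_image(cm, seed = 1)
    expect_equal(sim$truth$head_sum + sim$truth$tail_sum, cm$intensity,
                 tolerance = 1e-8, info = paste("fraction", f))
    expect_equal(sim$truth$tail_sum / cm$intensity, f, tolerance = 1e-8)
  }
  # tail fraction 1: the head region carries only background
  sim1 <- simulate_comet_image(comet_model(tail_fraction = 1, noise = FALSE),
                               seed = 2)
  expect_equal(sim1$truth$head_sum, 0)
})

test_that("tail-free comets yield an empty tail mask and zero metrics", {
  cm <- comet_model(tail_fraction = 0, noise = FALSE)
  sim <- simulate_comet_image(cm, seed = 3)
  seg <- segment_comet(sim$stack)
  expect_equal(sum(seg$tail_mask), 0)
  meas <- tail_metrics(seg$subtracted, seg$head_mask, seg$tail_mask)
  expect_equal(meas$tail_percent, 0)
  expect_equal(meas$olive_moment, 0)
  expect_equal(meas$tail_length_px, 0)
})

test_that("tail DNA percent recovers the generated fraction within 1 point", {
  cm <- comet_model(tail_fraction = 0.5, noise = FALSE)
  sim <- simulate_comet_image(cm, seed = 4)
  # direct pixel-summation oracle from the truth record
  oracle <- 100 * sim$truth$tail_sum / (sim$truth$head_sum + sim$truth$tail_sum)
  meas <- measure_comet(sim$stack)
  expect_equal(oracle, 50)
  expect_lt(abs(meas$tail_percent - oracle), 2.5)
  expect_gt(meas$olive_moment, 0)
})

test_that("measured tail extent tracks the generated tail length", {
  cm <- comet_model(tail_fraction = 0.5, tail_length = 96, noise = FALSE)
  sim <- simulate_comet_image(cm, seed = 5)
  meas <- measure_comet(sim$stack)
  expect_lt(abs(meas$tail_length_px - sim$truth$tail_length_px) /
            sim$truth$tail_length_px, 0.10)
})

test_that("tail percent is monotone in the generated fraction and scale-free", {
  m02 <- measure_comet(simulate_comet_image(
    comet_model(tail_fraction = 0.2, noise = FALSE), seed = 6)$stack)
  m06 <- measure_comet(simulate_comet_image(
    comet_model(tail_fraction = 0.6, noise = FALSE), seed = 6)$stack)
  expect_lt(m02$tail_percent, m06$tail_percent)
  # invariance under multiplication by a positive constant
  sim <- simulate_comet_image(comet_model(tail_fraction = 0.4, noise = FALSE),
                              seed = 7)
  scaled <- image_stack(sim$stack$data * 7.3, sim$stack$voxel_size, "comet")
  expect_equal(measure_comet(scaled)$tail_percent,
               measure_comet(sim$stack)$tail_percent, tolerance = 1e-6)
})

test_that("blank images and disjointness violations error", {
  blank <- image_stack(array(5, c(96, 256, 1, 1)), c(x = 1, y = 1, z = 1),
                       "comet")
  expect_error(segment_comet(blank), "no signal")
  img <- matrix(1, 10, 10)
  m <- matrix(TRUE, 10, 10)
  expect_error(tail_metrics(img, m, m), "disjoint")
})

test_that("the DSB time course verdict follows its truth table", {
  expect_equal(locipair:::recovery_verdict(FALSE, FALSE), "no induction")
  expect_equal(locipair:::recovery_verdict(FALSE, TRUE), "no induction")
  expect_equal(locipair:::recovery_verdict(TRUE, TRUE), "not recovered")
  expect_equal(locipair:::recovery_verdict(TRUE, FALSE), "recovered")

  set.seed(91)
  ctrl <- rnorm(30, 5, 2)
  induced <- rnorm(30, 50, 8)
  recovered <- rnorm(30, 6, 2)
  tc <- dsb_timecourse(list(control = ctrl, "0" = induced, "24" = recovered))
  expect_equal(tc$verdict, "recovered")
  tc2 <- dsb_timecourse(list(control = ctrl, "0" = induced,
                             "24" = induced + rnorm(30, 0, 1)))
  expect_equal(tc2$verdict, "not recovered")
  flat <- rep(5, 20)
  tc3 <- dsb_timecourse(list(control = flat, "0" = flat, "24" = flat))
  expect_equal(tc3$verdict, "no induction")
  expect_error(dsb_timecourse(list("0" = induced)), "control")
})

test_that("a synthetic comet panel reproduces induction and recovery", {
  cm <- comet_model()
  panel <- simulate_comet_panel(cm, c(control = 0.05, "0" = 0.5, "24" = 0.08),
                                n_per_group = 12, seed = 92)
  groups <- lapply(panel, function(sims)
    vapply(sims, function(s) measure_comet(s$stack)$tail_percent, numeric(1)))
  tc <- dsb_timecourse(groups)
  expect_equal(tc$verdict, "recovered")
  expect_gt(tc$summary$mean[tc$summary$group == "0"],
            tc$summary$mean[tc$summary$group == "control"])
})
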