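# Grouped statistics, configuration round-trip, end-to-end study runs.

test_that("grouped distance tests: identity, calibration, power", {
  set.seed(111)
  # identical groups: p ~ 1-ish, never starred
  x <- rnorm(40, 3.5, 1)
  tab <- grouped_distance_test(c(x, x), rep(c("a", "b"), each = 40),
                               control = "a")
  expect_gt(tab$p_raw[2], 0.99)
  expect_identical(tab$stars[2], "")
  # type-I error near nominal alpha
  hits <- vapply(1:200, function(i) {
    v <- rnorm(60, 3.5, 1)
    g <- rep(c("a", "b"), each = 30)
    grouped_distance_test(v, g, control = "a")$p_raw[2] < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.03)
  # power: 1-SD shift at n = 90 is detected at the 0.01 level
  power <- vapply(1:100, function(i) {
    v <- c(rnorm(90, 3.5, 1), rnorm(90, 2.5, 1))
    g <- rep(c("a", "b"), each = 90)
    grouped_distance_test(v, g, control = "a")$p_adj[2] < 0.01
  }, logical(1))
  expect_gte(mean(power), 0.95)
  expect_error(grouped_distance_test(1:4, rep("a", 4), control = "zz"),
               "control")
  expect_error(
    grouped_distance_test(1:4, rep(c("a", "b"), 2), method = "anova"))
})

test_that("study configuration round-trips through YAML", {
  cfg <- study_config(seed = 9, n_per_zone = 4, alpha = 0.01)
  path <- file.path(withr::local_tempdir(), "study.yaml")
  write_study_config(cfg, path)
  back <- read_study_config(path)
  expect_equal(back$seed, cfg$seed)
  expect_equal(back$alpha, cfg$alpha)
  expect_equal(back$meristematic_model$semi_axes,
               cfg$meristematic_model$semi_axes)
  expect_equal(back$dose_response$baseline, cfg$dose_response$baseline)
  expect_equal(back$shell$r, cfg$shell$r)
  expect_equal(back$comet_fractions, cfg$comet_fractions)
  expect_s3_class(back$meristematic_model, "nucleus_model")
})

tiny_config <- function(seed = 5) {
  study_config(seed = seed, n_per_zone = 6, n_per_dose = 6, n_recovery = 5,
               n_roots = 2, nuclei_per_root = 4, n_null_pairs = 2e4,
               n_resamples = 499, n_per_comet_group = 5)
}

test_that("identical config and seed give byte-identical study reports", {
  a <- run_study(tiny_config())
  b <- run_study(tiny_config())
  expect_identical(as.character(study_report_json(a)),
                   as.character(study_report_json(b)))
})

test_that("zeroing the generator effects removes the induced differences", {
  cfg <- tiny_config(seed = 6)
  cfg$n_per_dose <- 8
  # no dose effect, no pairing boost, identical zones, flat comet panel
  cfg$dose_response <- dose_response_model(amplitude = 0, pairing_max = 0)
  cfg$elongation_model <- cfg$meristematic_model
  cfg$comet_fractions <- c(control = 0.2, "0" = 0.2, "24" = 0.2)
  st <- run_study(cfg)
  expect_false(st$verdicts[["dose_shortening"]])
  expect_false(st$verdicts[["elongation_longer"]])
  expect_false(st$verdicts[["wt_pairing_increase"]])
  expect_equal(st$comet$verdict, "no induction")
  expect_true(st$verdicts[["volume_dose_invariant"]])
})
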