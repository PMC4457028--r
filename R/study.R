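# Study orchestration: simulate -> measure -> morphometry -> null
# comparison -> comet stages, with the grouped statistics and a
# reproducible report.

#' Configuration of a full synthetic study
#'
#' Bundles the generator models, detector settings, shell-null geometry,
#' statistical choices and per-stage sample sizes. All randomness in
#' [run_study()] derives deterministically from `seed`.
#'
#' @param seed master integer seed.
#' @param meristematic_model,elongation_model [nucleus_model()] objects.
#' @param dose_response a [dose_response_model()].
#' @param n_per_zone nuclei per zone for the zone comparison and the
#'   distance-volume correlation.
#' @param doses doses (Gy) of the dose-response stage (first entry is the
#'   unirradiated control).
#' @param n_per_dose nuclei per dose.
#' @param recovery_time_h post-dose time (h) of the recovery stage.
#' @param n_recovery nuclei in the recovery group.
#' @param genotypes named list of genotype switch lists (`label`,
#'   `shortening`, `pairing`).
#' @param n_roots,nuclei_per_root pairing-frequency design (root is the
#'   replication unit).
#' @param pairing_threshold pairing threshold (um).
#' @param spot_sigma detector spot sigmas `c(lateral=, axial=)` (um).
#' @param shell a [shell_geometry()] for the Monte Carlo null.
#' @param n_null_pairs,n_resamples Monte Carlo sizes of the null
#'   comparison.
#' @param comet_model a [comet_model()]; `comet_fractions` names the
#'   conditions (control plus hours) with their tail DNA fractions;
#'   `n_per_comet_group` comets per condition.
#' @param comet_fractions named numeric vector of tail fractions.
#' @param n_per_comet_group comets per condition.
#' @param test `"welch"` or `"wilcoxon"` for grouped comparisons.
#' @param alpha significance level in (0, 1).
#' @return object of class `study_config`.
#' @export
study_config <- function(seed = 1,
                         meristematic_model = nucleus_model("meristematic"),
                         elongation_model = nucleus_model("elongation"),
                         dose_response = dose_response_model(),
                         n_per_zone = 25,
                         doses = c(0, 150),
                         n_per_dose = 25,
                         recovery_time_h = 24,
                         n_recovery = 25,
                         genotypes = list(
                           wild_type = list(label = "wild_type",
                                            shortening = TRUE, pairing = TRUE),
                           rad54_like = list(label = "rad54_like",
                                             shortening = FALSE,
                                             pairing = FALSE)),
                         n_roots = 5,
                         nuclei_per_root = 8,
                         pairing_threshold = 0.4,
                         spot_sigma = c(lateral = 0.125, axial = 0.3),
                         shell = shell_geometry(2.3, 1.17),
                         n_null_pairs = 2e5,
                         n_resamples = 1999,
                         comet_model = NULL,
                         comet_fractions = c(control = 0.05, "0" = 0.5,
                                             "24" = 0.05),
                         n_per_comet_group = 20,
                         test = c("welch", "wilcoxon"),
                         alpha = 0.05) {
  test <- match.arg(test)
  stopifnot(alpha > 0, alpha < 1, n_per_zone >= 2, n_per_dose >= 2,
            length(doses) >= 2, all(doses >= 0))
  # (function lookup skips the like-named argument binding)
  if (is.null(comet_model)) comet_model <- comet_model()
  structure(list(seed = as.integer(seed),
                 meristematic_model = meristematic_model,
                 elongation_model = elongation_model,
                 dose_response = dose_response,
                 n_per_zone = n_per_zone, doses = doses,
                 n_per_dose = n_per_dose,
                 recovery_time_h = recovery_time_h, n_recovery = n_recovery,
                 genotypes = genotypes, n_roots = n_roots,
                 nuclei_per_root = nuclei_per_root,
                 pairing_threshold = pairing_threshold,
                 spot_sigma = spot_sigma, shell = shell,
                 n_null_pairs = n_null_pairs, n_resamples = n_resamples,
                 comet_model = comet_model,
                 comet_fractions = comet_fractions,
                 n_per_comet_group = n_per_comet_group,
                 test = test, alpha = alpha),
            class = "study_config")
}

#' Write / read a study configuration as YAML
#'
#' The configuration round-trips losslessly (up to floating-point
#' precision of the YAML encoding, 12 significant digits).
#'
#' @param config a [study_config()].
#' @param path YAML file path.
#' @return `write_study_config`: `path` invisibly; `read_study_config`: a
#'   `study_config`.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  # named atomic vectors become named lists (yaml drops vector names)
  to_plain <- function(x) {
    x <- unclass(x)
    if (is.list(x)) lapply(x, to_plain)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  writeLines(yaml::as.yaml(to_plain(config), precision = 12), path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_named <- function(x) {
    if (is.list(x) && all(vapply(x, is.numeric, logical(1))))
      unlist(x) else x
  }
  restore_model <- function(m) {
    structure(lapply(m, as_named), class = "nucleus_model")
  }
  cfg <- raw
  cfg$meristematic_model <- restore_model(raw$meristematic_model)
  cfg$elongation_model <- restore_model(raw$elongation_model)
  cfg$dose_response <- structure(raw$dose_response,
                                 class = "dose_response_model")
  cfg$shell <- structure(raw$shell, class = "shell_geometry")
  cfg$comet_model <- structure(lapply(raw$comet_model, as_named),
                               class = "comet_model")
  cfg$spot_sigma <- unlist(raw$spot_sigma)
  cfg$comet_fractions <- unlist(raw$comet_fractions)
  cfg$doses <- unlist(raw$doses)
  structure(cfg, class = "study_config")
}

#' Pairwise grouped distance tests against a control group
#'
#' Each non-control group is compared with the designated control by the
#' configured two-sample test; p-values are Holm-corrected across the
#' comparisons (raw p-values are also reported) and stars echo the usual
#' convention (* adjusted p < 0.05, ** < 0.01).
#'
#' @param values numeric vector of measurements.
#' @param group grouping factor/vector (same length).
#' @param control control group label (default: first level).
#' @param method `"welch"` or `"wilcoxon"`.
#' @param alpha significance level.
#' @param p_adjust correction method (see [stats::p.adjust()]).
#' @return data.frame of class `grouped_test`: group, n, mean, sd, shift
#'   (mean - control mean), p_raw, p_adj, stars, significant.
#' @export
grouped_distance_test <- function(values, group, control = NULL,
                                  method = c("welch", "wilcoxon"),
                                  alpha = 0.05, p_adjust = "holm") {
  method <- match.arg(method)
  group <- as.character(group)
  stopifnot(length(values) == length(group))
  levels <- unique(group)
  control <- control %||% levels[1]
  if (!control %in% levels) stop("control group not present")
  if (any(table(group) < 2)) stop("each group needs n >= 2")
  ctrl <- values[group == control]
  others <- setdiff(levels, control)
  test_one <- function(x) {
    if (stats::sd(x) == 0 && stats::sd(ctrl) == 0)
      return(if (isTRUE(all.equal(mean(x), mean(ctrl)))) 1 else 0)
    if (method == "welch") stats::t.test(x, ctrl)$p.value
    else stats::wilcox.test(x, ctrl, exact = FALSE)$p.value
  }
  p_raw <- vapply(others, function(g) test_one(values[group == g]), numeric(1))
  p_adj <- stats::p.adjust(p_raw, method = p_adjust)
  rows <- data.frame(
    group = c(control, others),
    n = vapply(c(control, others), function(g) sum(group == g), integer(1)),
    mean = vapply(c(control, others), function(g) mean(values[group == g]),
                  numeric(1)),
    sd = vapply(c(control, others), function(g) stats::sd(values[group == g]),
                numeric(1)))
  rows$shift <- rows$mean - rows$mean[1]
  rows$p_raw <- c(NA, p_raw)
  rows$p_adj <- c(NA, p_adj)
  rows$stars <- c("", ifelse(p_adj < 0.01, "**",
                             ifelse(p_adj < 0.05, "*", "")))
  rows$significant <- c(NA, p_adj < alpha)
  rownames(rows) <- NULL
  class(rows) <- c("grouped_test", "data.frame")
  rows
}

measure_sims <- function(sims, config) {
  lapply(sims, function(s)
    measure_stack(s$stack, spot_sigma = config$spot_sigma,
                  pairing_threshold = config$pairing_threshold))
}

pair_distances <- function(pairs, exclude_paired = TRUE) {
  pairs <- Filter(Negate(is.null), pairs)
  paired <- vapply(pairs, function(p) p$paired, logical(1))
  d <- vapply(pairs, function(p) p$distance_um, numeric(1))
  if (exclude_paired) d[!paired] else d
}

welch_p <- function(x, y) {
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  stats::t.test(x, y)$p.value
}

#' Run the full synthetic study
#'
#' Executes every stage on freshly generated data: zone comparison
#' (meristematic vs elongation distances), distance-volume correlation,
#' measured-vs-null Monte Carlo comparison, dose response with volume
#' invariance and 24-h recovery, genotype comparison (distance shortening
#' and per-root pairing frequencies, wild type vs a recombination-deficient
#' "rad54-like" configuration), and the comet-assay DSB time course. Every
#' verdict is a seeded significance assertion at the configured alpha.
#'
#' @param config a [study_config()].
#' @return object of class `locipair_study`: per-stage results plus a named
#'   `verdicts` character vector and the resolved `config`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  s <- config$seed
  alpha <- config$alpha
  notes <- character(0)
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    notes <<- c(notes, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  # --- zones -----------------------------------------------------------
  mer_sims <- lapply(seq_len(config$n_per_zone), function(i)
    simulate_nucleus_stack(config$meristematic_model,
                           seed = derive_seed(s, 100 + i)))
  elo_sims <- lapply(seq_len(config$n_per_zone), function(i)
    simulate_nucleus_stack(config$elongation_model,
                           seed = derive_seed(s, 200 + i)))
  mer_pairs <- measure_sims(mer_sims, config)
  elo_pairs <- measure_sims(elo_sims, config)
  mer_d <- pair_distances(mer_pairs)
  elo_d <- pair_distances(elo_pairs)
  p_zone <- welch_p(mer_d, elo_d)
  zones <- list(
    meristematic = summarize_distances(mer_pairs),
    elongation = summarize_distances(elo_pairs),
    p = p_zone,
    elongation_longer = mean(elo_d) > mean(mer_d) && p_zone < alpha)

  # --- distance-volume correlation (pooled zones) ----------------------
  all_sims <- c(mer_sims, elo_sims)
  all_pairs <- c(mer_pairs, elo_pairs)
  keep <- which(vapply(all_pairs, function(p)
    !is.null(p) && !p$paired, logical(1)))
  vols <- vapply(all_sims[keep], function(sim) {
    seg <- tryCatch(segment_nucleus(sim$stack), error = function(e) NULL)
    if (is.null(seg) || seg$measurement$clipped) NA_real_
    else seg$measurement$volume_um3
  }, numeric(1))
  dists <- vapply(all_pairs[keep], function(p) p$distance_um, numeric(1))
  dv <- correlate_distance_volume(dists[!is.na(vols)], vols[!is.na(vols)])

  # --- measured vs Monte Carlo null ------------------------------------
  null_cmp <- compare_to_null(mer_d, config$shell,
                              n_null_pairs = config$n_null_pairs,
                              n_resamples = config$n_resamples,
                              seed = derive_seed(s, 3))

  # --- dose response (wild type, t = 0) --------------------------------
  wt <- config$genotypes[[1]]
  dose_panel <- simulate_dose_panel(config$meristematic_model,
                                    config$dose_response,
                                    config$doses, config$n_per_dose,
                                    time_h = 0, seed = derive_seed(s, 4),
                                    genotype = wt)
  dp_pairs <- measure_sims(dose_panel$sims, config)
  dp_dose <- dose_panel$manifest$dose_gy
  dp_ok <- which(vapply(dp_pairs, function(p)
    !is.null(p) && !p$paired, logical(1)))
  dose_table <- grouped_distance_test(
    vapply(dp_pairs[dp_ok], function(p) p$distance_um, numeric(1)),
    dp_dose[dp_ok], control = as.character(config$doses[1]),
    method = config$test, alpha = alpha)
  max_dose <- max(config$doses)
  ctrl_d <- vapply(dp_pairs[dp_ok][dp_dose[dp_ok] == config$doses[1]],
                   function(p) p$distance_um, numeric(1))
  high_d <- vapply(dp_pairs[dp_ok][dp_dose[dp_ok] == max_dose],
                   function(p) p$distance_um, numeric(1))
  shortened <- mean(high_d) < mean(ctrl_d) &&
    dose_table$significant[dose_table$group == as.character(max_dose)]

  # volume invariance between control and highest dose
  vol_of <- function(idx) {
    v <- vapply(dose_panel$sims[idx], function(sim) {
      seg <- tryCatch(segment_nucleus(sim$stack), error = function(e) NULL)
      if (is.null(seg)) NA_real_ else seg$measurement$volume_um3
    }, numeric(1))
    v[!is.na(v)]
  }
  vol_cmp <- compare_volumes(
    stats::setNames(list(vol_of(which(dp_dose == config$doses[1])),
                         vol_of(which(dp_dose == max_dose))),
                    c("control", paste0(max_dose, "Gy"))),
    method = if (config$test == "welch") "welch" else "wilcoxon")

  # recovery at 24 h after the highest dose
  rec_panel <- simulate_dose_panel(config$meristematic_model,
                                   config$dose_response,
                                   max_dose, config$n_recovery,
                                   time_h = config$recovery_time_h,
                                   seed = derive_seed(s, 5), genotype = wt)
  rec_d <- pair_distances(measure_sims(rec_panel$sims, config))
  p_rec <- welch_p(rec_d, ctrl_d)
  recovery <- list(p_vs_control = p_rec,
                   mean_recovered = mean(rec_d),
                   mean_control = mean(ctrl_d),
                   recovered = p_rec >= alpha && shortened)

  # --- genotypes: shortening and pairing frequency ---------------------
  genotype_res <- list()
  gi <- 0L
  for (g in config$genotypes) {
    gi <- gi + 1L
    per_dose <- list()
    for (di in seq_along(c(config$doses[1], max_dose))) {
      d <- c(config$doses[1], max_dose)[di]
      roots <- list()
      for (r in seq_len(config$n_roots)) {
        panel <- simulate_dose_panel(
          config$meristematic_model, config$dose_response, d,
          config$nuclei_per_root, time_h = 0,
          seed = derive_seed(s, 1000 * gi + 100 * di + r), genotype = g)
        roots[[paste0("root", r)]] <- measure_sims(panel$sims, config)
      }
      per_dose[[as.character(d)]] <- roots
    }
    all0 <- unlist(per_dose[[1]], recursive = FALSE)
    all1 <- unlist(per_dose[[2]], recursive = FALSE)
    d0 <- pair_distances(all0)
    d1 <- pair_distances(all1)
    p_short <- welch_p(d0, d1)
    pf0 <- collect(pairing_frequency(per_dose[[1]]))
    pf1 <- collect(pairing_frequency(per_dose[[2]]))
    p_pairing <- welch_p(pf0$per_root$frequency, pf1$per_root$frequency)
    genotype_res[[g$label]] <- list(
      mean_0 = mean(d0), mean_high = mean(d1), p_shortening = p_short,
      shortened = mean(d1) < mean(d0) && p_short < alpha,
      pairing_0 = pf0, pairing_high = pf1, p_pairing = p_pairing,
      pairing_increased = pf1$mean > pf0$mean && p_pairing < alpha)
  }

  # --- comet time course -----------------------------------------------
  comet_panel <- simulate_comet_panel(config$comet_model,
                                      config$comet_fractions,
                                      config$n_per_comet_group,
                                      seed = derive_seed(s, 6))
  comet_groups <- lapply(comet_panel, function(sims)
    vapply(sims, function(cs) measure_comet(cs$stack)$tail_percent,
           numeric(1)))
  comet <- dsb_timecourse(comet_groups, alpha = alpha)

  wt_label <- config$genotypes[[1]]$label
  mut_label <- if (length(config$genotypes) >= 2)
    config$genotypes[[2]]$label else NULL
  verdicts <- c(
    elongation_longer = zones$elongation_longer,
    distance_volume_correlated = dv$r > 0 && dv$p < alpha,
    measured_exceeds_null = null_cmp$direction == "longer" &&
      null_cmp$p < alpha,
    dose_shortening = shortened,
    volume_dose_invariant = vol_cmp$p >= alpha,
    recovery_24h = recovery$recovered,
    wt_pairing_increase = genotype_res[[wt_label]]$pairing_increased,
    comet_recovered = comet$verdict == "recovered")
  if (!is.null(mut_label)) {
    verdicts <- c(verdicts,
      mutant_no_shortening = !genotype_res[[mut_label]]$shortened,
      mutant_no_pairing_increase =
        !genotype_res[[mut_label]]$pairing_increased)
  }
  structure(list(config = config, zones = zones, distance_volume = dv,
                 null_comparison = null_cmp, dose_table = dose_table,
                 volume_comparison = vol_cmp, recovery = recovery,
                 genotypes = genotype_res, comet = comet,
                 verdicts = verdicts, notes = unique(notes)),
            class = "locipair_study")
}

#' @export
print.locipair_study <- function(x, ...) {
  cat("<locipair_study>\n")
  cat(sprintf("  zones: meristematic %.2f um (n=%d) vs elongation %.2f um (n=%d), p=%.3g\n",
              x$zones$meristematic$mean, x$zones$meristematic$n,
              x$zones$elongation$mean, x$zones$elongation$n, x$zones$p))
  cat(sprintf("  distance-volume: r=%.2f (n=%d, p=%.3g)\n",
              x$distance_volume$r, x$distance_volume$n, x$distance_volume$p))
  cat(sprintf("  null: measured %.2f vs null %.2f um, p=%.3g\n",
              x$null_comparison$measured_mean, x$null_comparison$null_mean,
              x$null_comparison$p))
  cat(sprintf("  recovery: %.2f um at 24 h vs control %.2f um (p=%.3g)\n",
              x$recovery$mean_recovered, x$recovery$mean_control,
              x$recovery$p_vs_control))
  cat("  verdicts:\n")
  for (v in names(x$verdicts))
    cat(sprintf("    %-28s %s\n", v, x$verdicts[[v]]))
  invisible(x)
}

#' Serialize a study report to deterministic JSON
#'
#' Numbers only; no timestamps, so identical config + seed gives
#' byte-identical output.
#'
#' @param study a `locipair_study`.
#' @param path optional output path.
#' @return JSON string (invisibly if `path` given).
#' @export
study_report_json <- function(study, path = NULL) {
  stopifnot(inherits(study, "locipair_study"))
  strip <- function(x) {
    if (inherits(x, "distance_summary"))
      return(list(n = x$n, mean = x$mean, sd = x$sd, n_paired = x$n_paired,
                  n_total = x$n_total))
    if (inherits(x, "pairing_frequencies"))
      return(list(per_root = x$per_root, mean = x$mean, sd = x$sd))
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    x
  }
  rep <- list(seed = study$config$seed,
              alpha = study$config$alpha,
              zones = strip(study$zones),
              distance_volume = unclass(study$distance_volume),
              null_comparison = strip(unclass(study$null_comparison))[
                c("measured_mean", "measured_n", "null_mean", "null_n", "p")],
              dose_table = as.data.frame(study$dose_table),
              volume_comparison = unclass(study$volume_comparison),
              recovery = study$recovery,
              genotypes = strip(study$genotypes),
              comet = list(summary = study$comet$summary,
                           tests = study$comet$tests,
                           verdict = study$comet$verdict),
              verdicts = as.list(study$verdicts),
              notes = study$notes)
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = 10, null = "null",
                         dataframe = "rows")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
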