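# Pairing of detected foci into an inter-allelic distance measurement, and
# the distance / pairing-frequency summaries built on it.

#' Pair the two strongest detections and measure the inter-allelic distance
#'
#' Takes the detection table of one nucleus (sorted by descending score, as
#' returned by [detect_foci()]) and forms the locus pair: with two or more
#' detections the top two give the physical Euclidean distance; a single
#' detection is interpreted as two fully overlapped loci appearing as one
#' dot (distance 0, paired); zero detections give `NULL` (unmeasurable
#' nucleus). The pair is flagged `paired` when the distance falls below the
#' pairing threshold — the separation below which two EGFP dots merge
#' visually.
#'
#' @param detections a `focus_detections` data.frame.
#' @param pairing_threshold pairing (overlap) threshold in um.
#' @return object of class `locus_pair` (or `NULL`): list with `foci` (the
#'   one or two detections used), `distance_um`, `paired`, `threshold_um`,
#'   `n_candidates`.
#' @export
measure_pair <- function(detections, pairing_threshold = 0.4) {
  stopifnot(is.data.frame(detections), pairing_threshold >= 0)
  n <- nrow(detections)
  if (n == 0) return(NULL)
  if (n == 1) {
    pair <- structure(list(foci = detections, distance_um = 0, paired = TRUE,
                           threshold_um = pairing_threshold, n_candidates = 1L),
                      class = "locus_pair")
    return(pair)
  }
  top <- detections[1:2, ]
  d <- sqrt((top$x_um[1] - top$x_um[2])^2 + (top$y_um[1] - top$y_um[2])^2 +
            (top$z_um[1] - top$z_um[2])^2)
  structure(list(foci = top, distance_um = d,
                 paired = d < pairing_threshold,
                 threshold_um = pairing_threshold, n_candidates = as.integer(n)),
            class = "locus_pair")
}

#' @export
print.locus_pair <- function(x, ...) {
  cat(sprintf("<locus_pair> distance %.3f um, %s (threshold %.2f um, %d candidate(s))\n",
              x$distance_um, if (x$paired) "paired" else "not paired",
              x$threshold_um, x$n_candidates))
  invisible(x)
}

#' Convenience: detect foci in a stack and measure its locus pair
#'
#' @inheritParams detect_foci
#' @param pairing_threshold pairing threshold in um.
#' @return a `locus_pair` or `NULL`; see [measure_pair()].
#' @export
measure_stack <- function(stack, spot_sigma = c(lateral = 0.125, axial = 0.3),
                          pairing_threshold = 0.4, ...) {
  measure_pair(detect_foci(stack, spot_sigma = spot_sigma, ...),
               pairing_threshold = pairing_threshold)
}

#' Summarize inter-allelic distances over a set of nuclei
#'
#' Paired (overlapping) loci are excluded from the distance sample by
#' default — they contribute to the pairing frequency but not to the
#' distance statistics. Unmeasurable nuclei (`NULL` pairs) are dropped.
#'
#' @param pairs list of `locus_pair` objects (may contain `NULL`s).
#' @param exclude_paired logical; exclude paired loci from the distance
#'   sample (default `TRUE`).
#' @return list of class `distance_summary`: `n` (sample size after
#'   exclusion), `mean`, `sd` (sample SD, `NA` for n < 2), `values`,
#'   `n_paired`, `n_total` (measurable nuclei).
#' @export
summarize_distances <- function(pairs, exclude_paired = TRUE) {
  pairs <- Filter(Negate(is.null), pairs)
  if (length(pairs) == 0) stop("no measurable nuclei")
  paired <- vapply(pairs, function(p) p$paired, logical(1))
  dist <- vapply(pairs, function(p) p$distance_um, numeric(1))
  values <- if (exclude_paired) dist[!paired] else dist
  if (length(values) == 0)
    stop("empty distance sample: all measurable nuclei have paired loci")
  structure(list(n = length(values), mean = mean(values),
                 sd = if (length(values) >= 2) stats::sd(values) else NA_real_,
                 values = values, n_paired = sum(paired),
                 n_total = length(pairs)),
            class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("<distance_summary> n=%d, mean %.3f um, SD %.3f um (%d/%d paired excluded)\n",
              x$n, x$mean, x$sd, x$n_paired, x$n_total))
  invisible(x)
}

#' Pairing frequency per root and group summary
#'
#' The root (not the nucleus) is the replication unit: the fraction of
#' nuclei with paired loci is computed per root, and the group summary is
#' the mean and SD over roots. Roots with fewer than 30 nuclei trigger a
#' warning (the study design counts at least 30 nuclei per root).
#'
#' @param pairs_by_root named list: root id -> list of `locus_pair` objects.
#' @param min_nuclei per-root minimum before warning (default 30).
#' @return list of class `pairing_frequencies`: `per_root` data.frame
#'   (root, n, n_paired, frequency), `mean`, `sd` (over roots).
#' @export
pairing_frequency <- function(pairs_by_root, min_nuclei = 30) {
  if (length(pairs_by_root) == 0) stop("no roots supplied")
  rows <- lapply(names(pairs_by_root), function(root) {
    pl <- Filter(Negate(is.null), pairs_by_root[[root]])
    if (length(pl) == 0) stop(sprintf("root '%s' has no measurable nuclei", root))
    if (length(pl) < min_nuclei)
      warning(sprintf("root '%s' has only %d nuclei (< %d)", root,
                      length(pl), min_nuclei))
    np <- sum(vapply(pl, function(p) p$paired, logical(1)))
    data.frame(root = root, n = length(pl), n_paired = np,
               frequency = np / length(pl))
  })
  per_root <- do.call(rbind, rows)
  structure(list(per_root = per_root, mean = mean(per_root$frequency),
                 sd = if (nrow(per_root) >= 2) stats::sd(per_root$frequency)
                      else NA_real_),
            class = "pairing_frequencies")
}

#' @export
print.pairing_frequencies <- function(x, ...) {
  cat(sprintf("<pairing_frequencies> %d root(s), mean %.1f%% +/- %.1f%%\n",
              nrow(x$per_root), 100 * x$mean, 100 * x$sd))
  invisible(x)
}

#' Measure the inter-allelic distance across a time-lapse series
#'
#' Detection runs independently per timepoint; no inter-frame identity
#' assignment is needed because the distance is symmetric in the two foci.
#' Timepoints with no measurable pair are recorded as missing, never
#' interpolated. The coefficient of variation is computed over the
#' non-missing, non-paired distances.
#'
#' @param series list of [image_stack()] objects or `nucleus_sim` objects
#'   (e.g. from [simulate_time_series()]); >= 2 timepoints.
#' @inheritParams measure_stack
#' @return list of class `distance_trace`: `trace` data.frame (timepoint,
#'   distance_um, paired, measurable), `cv` (SD/mean of the measured
#'   distances), `pairs` (the underlying `locus_pair` list).
#' @export
track_series <- function(series, spot_sigma = c(lateral = 0.125, axial = 0.3),
                         pairing_threshold = 0.4, ...) {
  stopifnot(length(series) >= 2)
  stacks <- lapply(series, function(s)
    if (inherits(s, "nucleus_sim")) s$stack else s)
  pairs <- lapply(stacks, measure_stack, spot_sigma = spot_sigma,
                  pairing_threshold = pairing_threshold, ...)
  dist <- vapply(pairs, function(p) if (is.null(p)) NA_real_ else p$distance_um,
                 numeric(1))
  paired <- vapply(pairs, function(p) if (is.null(p)) NA else p$paired,
                   logical(1))
  trace <- data.frame(timepoint = seq_along(pairs), distance_um = dist,
                      paired = paired, measurable = !is.na(dist))
  vals <- dist[!is.na(dist) & !paired]
  cv <- if (length(vals) >= 2 && mean(vals) > 0) stats::sd(vals) / mean(vals)
        else NA_real_
  structure(list(trace = trace, cv = cv, pairs = pairs),
            class = "distance_trace")
}

#' @export
print.distance_trace <- function(x, ...) {
  cat(sprintf("<distance_trace> %d timepoints, %d measurable, CV %.1f%%\n",
              nrow(x$trace), sum(x$trace$measurable), 100 * x$cv))
  invisible(x)
}
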