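# Comet-assay quantification: head/tail segmentation and DSB metrics.

# Rolling-percentile background: a low percentile of each column (the
# comet occupies a minority of any column, so the percentile sees clean
# background), smoothed by a rolling median along the migration axis to
# track slow illumination gradients.
rolling_background <- function(img, q = 0.5, width = 25) {
  nx <- ncol(img)
  width <- min(width, nx)
  if (width %% 2 == 0) width <- width - 1
  colq <- apply(img, 2, stats::quantile, probs = q, names = FALSE)
  prof <- zoo::rollapply(colq, width = width, FUN = stats::median,
                         partial = TRUE)
  matrix(prof, nrow(img), nx, byrow = TRUE)
}

#' Segment a comet image into head and tail masks
#'
#' Background is removed by a rolling-percentile estimate along the
#' migration axis (+x by convention; real images must be pre-rotated).
#' The head is the brightest circular region: its centre is the mode of the
#' smoothed image and its radius the largest radius at which the radial
#' intensity profile stays above half its central value. The tail is all
#' signal above `k_mad` robust SDs of background beyond the head edge
#' along +x.
#'
#' @param stack an [image_stack()] with a `"comet"` channel (or a plain
#'   matrix).
#' @param k_mad tail/signal threshold in MAD units above background.
#' @param smooth_sigma Gaussian sigma (px) used when locating the head.
#' @param guard guard band (px) added beyond the half-height head radius so
#'   the head's smoothed edge is attributed to the head, not the tail.
#' @param bg_q,bg_width percentile and window (px) of the rolling
#'   background.
#' @return list of class `comet_segmentation`: `head_mask`, `tail_mask`
#'   (logical matrices, disjoint), `head_center` (x, y in px),
#'   `head_radius`, `subtracted` (background-subtracted image),
#'   `threshold`.
#' @export
segment_comet <- function(stack, k_mad = 3, smooth_sigma = 2, guard = 2,
                          bg_q = 0.5, bg_width = 25) {
  img <- if (inherits(stack, "image_stack")) {
    a <- stack_channel(stack, "comet")
    matrix(a[, , 1], dim(a)[1], dim(a)[2])
  } else as.matrix(stack)
  bg <- rolling_background(img, q = bg_q, width = bg_width)
  sub <- img - bg
  noise <- stats::mad(sub)
  thr <- k_mad * noise + 0.005 * max(abs(sub), 1e-12)
  if (max(sub) <= thr) stop("no signal above background in comet image")
  # head = leftmost strong peak of the y-collapsed profile: migration runs
  # +x, so the head leads and the tail trails; the global intensity mode
  # can sit in a bright tail, and summing over y suppresses pixel noise
  px <- colSums(sub)   # unclamped: zero-mean noise cancels in the column sum
  kk <- stats::dnorm(-9:9, sd = smooth_sigma + 1)
  pxs <- as.numeric(stats::filter(px, kk / sum(kk), sides = 2))
  pxs[is.na(pxs)] <- 0
  n <- length(pxs)
  is_max <- pxs > c(-Inf, pxs[-n]) & pxs >= c(pxs[-1], -Inf)
  cand_x <- which(is_max & pxs >= 0.25 * max(pxs))
  cx <- if (length(cand_x)) min(cand_x) else which.max(pxs)
  band <- pmax(sub[, max(1, cx - 3):min(ncol(sub), cx + 3), drop = FALSE], 0)
  cy <- if (sum(band) > 0) round(sum(seq_len(nrow(sub)) * rowSums(band)) /
                                   sum(band))
        else which.max(rowSums(sub))
  ny <- nrow(img); nx <- ncol(img)
  xs <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  ys <- matrix(seq_len(ny), ny, nx)
  rr <- sqrt((xs - cx)^2 + (ys - cy)^2)
  rmax <- floor(min(cx - 1, cy - 1, ny - cy, min(ny, nx) / 2))
  rmax <- max(rmax, 2)
  prof <- vapply(seq_len(rmax), function(r)
    mean(sub[rr >= r - 1 & rr < r]), numeric(1))
  p0 <- mean(sub[rr < 2])
  below <- which(prof < p0 / 2)
  head_radius <- if (length(below) == 0) rmax else max(1, below[1] - 1)
  head_mask <- rr <= head_radius + guard
  tail_mask <- (sub > thr) & (xs > cx + head_radius + guard) & !head_mask
  structure(list(head_mask = head_mask, tail_mask = tail_mask,
                 head_center = c(x = cx, y = cy), head_radius = head_radius,
                 subtracted = sub, threshold = thr),
            class = "comet_segmentation")
}

#' Comet DSB metrics: tail DNA percent, tail length, Olive tail moment
#'
#' Metrics follow the standard definitions: tail DNA % is the tail share of
#' total (head + tail) intensity; tail length is the distance from the head
#' intensity centroid to the farthest above-threshold tail pixel; the Olive
#' tail moment is the tail DNA fraction multiplied by the distance between
#' head and tail intensity centroids.
#'
#' @param image background-subtracted comet image (matrix).
#' @param head_mask,tail_mask disjoint logical masks (from
#'   [segment_comet()]).
#' @param pixel_size_um optional pixel size for tail length in um.
#' @return object of class `comet_measurement`: `tail_percent`,
#'   `tail_length_px` (and `tail_length_um` if pixel size given),
#'   `olive_moment`, `head_center` (intensity centroid), `head_intensity`,
#'   `tail_intensity`.
#' @export
tail_metrics <- function(image, head_mask, tail_mask, pixel_size_um = NULL) {
  image <- as.matrix(image)
  stopifnot(identical(dim(image), dim(head_mask)),
            identical(dim(image), dim(tail_mask)))
  if (any(head_mask & tail_mask)) stop("head and tail masks must be disjoint")
  pos <- pmax(image, 0)
  head_i <- sum(pos[head_mask])
  tail_i <- sum(pos[tail_mask])
  total <- head_i + tail_i
  if (total <= 0) stop("no intensity in head or tail mask")
  tail_percent <- 100 * tail_i / total
  ny <- nrow(image); nx <- ncol(image)
  xs <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  ys <- matrix(seq_len(ny), ny, nx)
  hc <- if (head_i > 0)
    c(x = sum(xs[head_mask] * pos[head_mask]) / head_i,
      y = sum(ys[head_mask] * pos[head_mask]) / head_i)
  else c(x = mean(xs[head_mask]), y = mean(ys[head_mask]))
  if (tail_i > 0) {
    tc_x <- sum(xs[tail_mask] * pos[tail_mask]) / tail_i
    tail_len <- max(xs[tail_mask]) - hc[["x"]]
    centroid_sep <- abs(tc_x - hc[["x"]])
  } else {
    tail_len <- 0
    centroid_sep <- 0
  }
  olive <- (tail_percent / 100) * centroid_sep
  out <- list(tail_percent = tail_percent, tail_length_px = tail_len,
              olive_moment = olive, head_center = hc,
              head_intensity = head_i, tail_intensity = tail_i)
  if (!is.null(pixel_size_um)) out$tail_length_um <- tail_len * pixel_size_um
  structure(out, class = "comet_measurement")
}

#' @export
print.comet_measurement <- function(x, ...) {
  cat(sprintf("<comet_measurement> tail DNA %.1f%%, tail length %.1f px, Olive moment %.2f\n",
              x$tail_percent, x$tail_length_px, x$olive_moment))
  invisible(x)
}

#' Convenience: segment a comet image and compute its metrics
#'
#' @inheritParams segment_comet
#' @param pixel_size_um optional pixel size (um).
#' @return a `comet_measurement`; see [tail_metrics()].
#' @export
measure_comet <- function(stack, k_mad = 3, pixel_size_um = NULL, ...) {
  seg <- segment_comet(stack, k_mad = k_mad, ...)
  tail_metrics(seg$subtracted, seg$head_mask, seg$tail_mask,
               pixel_size_um = pixel_size_um)
}

# Pure verdict logic, truth-table testable: induced = 0-h group
# significantly above control; residual = latest group still significantly
# above control.
recovery_verdict <- function(induced, residual) {
  if (!induced) "no induction" else if (residual) "not recovered" else "recovered"
}

#' DSB time course from grouped comet measurements
#'
#' Per-group mean tail DNA % with Welch tests of each group against the
#' control; the recovery verdict is `"recovered"` when the earliest
#' post-irradiation group is significantly above control and the latest is
#' not, `"not recovered"` when the latest still is, and `"no induction"`
#' when the earliest is not.
#'
#' @param groups named list: `"control"` plus time groups named by hours
#'   (e.g. `"0"`, `"24"`); each element a numeric vector of tail DNA
#'   percents or a list of `comet_measurement`s.
#' @param alpha significance level.
#' @param control name of the control group.
#' @return list of class `dsb_timecourse`: `summary` (per-group n/mean/sd),
#'   `tests` (group, p, significant, above), `verdict`.
#' @export
dsb_timecourse <- function(groups, alpha = 0.05, control = "control") {
  if (!control %in% names(groups)) stop("missing control group")
  as_vals <- function(g)
    if (is.numeric(g)) g
    else vapply(g, function(m) m$tail_percent, numeric(1))
  vals <- lapply(groups, as_vals)
  ctrl <- vals[[control]]
  times <- setdiff(names(vals), control)
  th <- suppressWarnings(as.numeric(times))
  if (any(is.na(th))) stop("time groups must be named by hours")
  times <- times[order(th)]
  summary <- do.call(rbind, lapply(names(vals), function(g)
    data.frame(group = g, n = length(vals[[g]]), mean = mean(vals[[g]]),
               sd = stats::sd(vals[[g]]))))
  tests <- do.call(rbind, lapply(times, function(g) {
    x <- vals[[g]]
    p <- if (stats::sd(x) == 0 && stats::sd(ctrl) == 0) {
      if (isTRUE(all.equal(mean(x), mean(ctrl)))) 1 else 0
    } else stats::t.test(x, ctrl)$p.value
    data.frame(group = g, p = p,
               above = mean(x) > mean(ctrl),
               significant = p < alpha & mean(x) > mean(ctrl))
  }))
  induced <- tests$significant[1]
  residual <- tests$significant[nrow(tests)]
  structure(list(summary = summary, tests = tests,
                 verdict = recovery_verdict(induced, residual),
                 alpha = alpha),
            class = "dsb_timecourse")
}

#' @export
print.dsb_timecourse <- function(x, ...) {
  cat("<dsb_timecourse> verdict:", x$verdict, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
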