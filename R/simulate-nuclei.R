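# Synthetic two-channel nucleus stacks with known focus ground truth.

# Uniform random unit directions (n x 3 matrix, columns x/y/z).
random_directions <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# Validity of points (n x 3, relative to nucleus centre): inside the
# ellipsoid and strictly outside the nucleolus.
in_nucleoplasm <- function(p, semi_axes, nucleolus_radius) {
  e <- (p[, 1] / semi_axes[["x"]])^2 + (p[, 2] / semi_axes[["y"]])^2 +
    (p[, 3] / semi_axes[["z"]])^2
  r2 <- rowSums(p^2)
  e <= 1 & r2 > nucleolus_radius^2
}

# One point uniform in the nucleoplasm (rejection from the bounding box).
sample_nucleoplasm <- function(n, semi_axes, nucleolus_radius, max_batches = 200) {
  out <- matrix(NA_real_, 0, 3)
  for (b in seq_len(max_batches)) {
    m <- max(64L, 2L * (n - nrow(out)))
    cand <- cbind(stats::runif(m, -semi_axes[["x"]], semi_axes[["x"]]),
                  stats::runif(m, -semi_axes[["y"]], semi_axes[["y"]]),
                  stats::runif(m, -semi_axes[["z"]], semi_axes[["z"]]))
    out <- rbind(out, cand[in_nucleoplasm(cand, semi_axes, nucleolus_radius), ,
                           drop = FALSE])
    if (nrow(out) >= n) return(out[seq_len(n), , drop = FALSE])
  }
  stop("nucleoplasm sampling failed (degenerate geometry?)")
}

# Place a pair of foci at exact separation `s`, both in the nucleoplasm.
# Batched rejection over (first endpoint, orientation); errors out when the
# separation cannot be placed.
sample_focus_pair <- function(s, semi_axes, nucleolus_radius,
                              batch = 512L, max_batches = 24L) {
  if (s == 0) {
    p <- sample_nucleoplasm(1, semi_axes, nucleolus_radius)
    return(rbind(p, p))
  }
  for (b in seq_len(max_batches)) {
    p1 <- sample_nucleoplasm(batch, semi_axes, nucleolus_radius)
    u <- random_directions(batch)
    p2 <- p1 + s * u
    ok <- in_nucleoplasm(p2, semi_axes, nucleolus_radius)
    if (any(ok)) {
      i <- which(ok)[1]
      return(rbind(p1[i, ], p2[i, ]))
    }
  }
  stop(sprintf(
    "separation %.3g um cannot be placed inside the nucleoplasm (semi-axes %s, nucleolus %.3g um)",
    s, paste(signif(semi_axes, 3), collapse = "/"), nucleolus_radius))
}

# Add an integrated-Gaussian point source (total photons = amplitude) to a
# (y, x, z) array. Per-axis weights are pnorm differences over voxel
# extents, so the rendered sum equals the amplitude up to window truncation.
add_spot <- function(a, voxel, pos, sigma_xyz, amplitude, halfwidth_sigma = 5) {
  d <- dim(a)
  w <- vector("list", 3)
  rng <- vector("list", 3)
  axes <- c("y", "x", "z")
  nn <- c(d[1], d[2], d[3])
  for (i in 1:3) {
    ax <- axes[i]
    v <- voxel[[ax]]
    s <- sigma_xyz[[ax]]
    centers <- (seq_len(nn[i]) - 0.5) * v
    lo <- max(1L, floor((pos[[ax]] - halfwidth_sigma * s) / v))
    hi <- min(nn[i], ceiling((pos[[ax]] + halfwidth_sigma * s) / v) + 1L)
    if (lo > hi) return(a)
    idx <- lo:hi
    cc <- centers[idx]
    w[[i]] <- stats::pnorm(cc + v / 2, pos[[ax]], s) -
      stats::pnorm(cc - v / 2, pos[[ax]], s)
    rng[[i]] <- idx
  }
  contrib <- amplitude * outer(outer(w[[1]], w[[2]]), w[[3]])
  a[rng[[1]], rng[[2]], rng[[3]]] <- a[rng[[1]], rng[[2]], rng[[3]]] + contrib
  a
}

# Filled-ellipsoid indicator on voxel centres, array (y, x, z).
ellipsoid_mask <- function(dims, voxel, center, semi_axes) {
  fy <- (((seq_len(dims[1]) - 0.5) * voxel[["y"]] - center[["y"]]) / semi_axes[["y"]])^2
  fx <- (((seq_len(dims[2]) - 0.5) * voxel[["x"]] - center[["x"]]) / semi_axes[["x"]])^2
  fz <- (((seq_len(dims[3]) - 0.5) * voxel[["z"]] - center[["z"]]) / semi_axes[["z"]])^2
  outer(outer(fy, fx, "+"), fz, "+") <= 1
}

apply_shot_noise <- function(a, read_noise) {
  n <- length(a)
  a <- stats::rpois(n, a) + stats::rnorm(n, 0, read_noise)
  pmax(a, 0)
}

render_nucleus_stack <- function(model, semi_axes, nucleolus_radius, sep,
                                 noise, dims = NULL, center = NULL) {
  voxel <- model$voxel_size
  if (is.null(dims)) {
    ext <- 2 * (semi_axes + model$margin)
    dims <- c(ceiling(ext[["y"]] / voxel[["y"]]),
              ceiling(ext[["x"]] / voxel[["x"]]),
              ceiling(ext[["z"]] / voxel[["z"]]))
  }
  if (is.null(center))
    center <- c(x = dims[2] * voxel[["x"]] / 2,
                y = dims[1] * voxel[["y"]] / 2,
                z = dims[3] * voxel[["z"]] / 2)
  rel <- sample_focus_pair(sep, semi_axes, nucleolus_radius)
  coords <- sweep(rel, 2, c(center[["x"]], center[["y"]], center[["z"]]), "+")
  colnames(coords) <- c("x", "y", "z")
  psf <- c(x = unname(model$psf_sigma["lateral"]),
           y = unname(model$psf_sigma["lateral"]),
           z = unname(model$psf_sigma["axial"]))
  foci <- array(model$background, dims)
  for (i in 1:2)
    foci <- add_spot(foci, voxel, as.list(coords[i, ]), psf, model$amplitude)
  nuc <- array(model$background, dims)
  nuc <- nuc + model$nucleus_amplitude *
    ellipsoid_mask(dims, voxel, as.list(center), as.list(semi_axes))
  if (noise) {
    foci <- array(apply_shot_noise(foci, model$read_noise), dims)
    nuc <- array(apply_shot_noise(nuc, model$read_noise), dims)
  }
  data <- array(0, c(dims, 2L))
  data[, , , 1] <- foci
  data[, , , 2] <- nuc
  list(stack = image_stack(data, voxel, c("foci", "nucleus")),
       coords = coords, center = center)
}

# Draw one true separation for a (possibly size-scaled) model; normal
# truncated to [0, longest chord of the nucleus].
draw_separation <- function(mean_um, sd_um, semi_axes) {
  rtruncnorm(1, mean_um, sd_um, lower = 0, upper = 2 * max(semi_axes))
}

#' Simulate one two-channel nucleus stack with ground truth
#'
#' Renders a two-channel 3D stack: a foci channel carrying two PSF-blurred
#' point sources (the homologous tagged loci) at an exact true separation,
#' both placed inside the nucleoplasm (inside the nucleus ellipsoid, outside
#' the nucleolus), and a nucleus channel carrying the filled ellipsoid.
#' Poisson shot noise and Gaussian read noise are applied when `noise` is
#' enabled. The sidecar truth record carries the exact focus coordinates,
#' separation, and analytic nucleus volume.
#'
#' When `separation` is `NULL`, the true separation is drawn from the
#' model's truncated-normal separation distribution (with its mean scaled by
#' the per-nucleus size factor, so larger nuclei carry proportionally longer
#' separations); if a drawn separation cannot be placed geometrically it is
#' redrawn, and an explicitly requested separation that cannot be placed is
#' an error.
#'
#' @param model a [nucleus_model()].
#' @param separation optional exact true separation (um) overriding the
#'   model's separation distribution. `0` produces two coincident foci.
#' @param seed integer seed; identical seed and model give a bit-identical
#'   stack.
#' @param noise logical, apply shot/read noise (default from the model).
#' @param size_jitter logical; apply the model's per-nucleus log-normal size
#'   factor.
#' @return list of class `nucleus_sim` with elements `stack` (an
#'   [image_stack()]) and `truth` (coordinates in um, separation, volume,
#'   condition metadata).
#' @export
simulate_nucleus_stack <- function(model, separation = NULL, seed = NULL,
                                   noise = model$noise, size_jitter = TRUE) {
  stopifnot(inherits(model, "nucleus_model"))
  with_seed(seed, {
    k <- if (size_jitter && model$size_jitter_sd > 0)
      exp(stats::rnorm(1, 0, model$size_jitter_sd)) else 1
    semi <- model$semi_axes * k
    rnucl <- model$nucleolus_radius * k
    if (is.null(separation)) {
      sep <- NULL
      for (try in 1:50) {
        cand <- draw_separation(model$separation_mean * k,
                                model$separation_sd, semi)
        ok <- tryCatch({
          r <- render_nucleus_stack(model, semi, rnucl, cand, noise)
          sep <- cand
          TRUE
        }, error = function(e) FALSE)
        if (ok) break
      }
      if (is.null(sep)) stop("could not place a drawn separation after 50 redraws")
    } else {
      if (separation < 0) stop("separation must be non-negative")
      sep <- separation
      r <- render_nucleus_stack(model, semi, rnucl, sep, noise)
    }
    truth <- structure(list(
      coords = r$coords, separation = sep,
      volume = nucleus_volume(semi),
      zone = model$zone, dose_gy = 0, time_h = 0, genotype = "wild_type",
      semi_axes = semi, nucleolus_radius = rnucl, center = r$center,
      size_factor = k, seed = seed), class = "synthetic_truth")
    structure(list(stack = r$stack, truth = truth), class = "nucleus_sim")
  })
}

#' @export
print.nucleus_sim <- function(x, ...) {
  cat(sprintf("<nucleus_sim> zone=%s, true separation %.3f um, volume %.1f um^3\n",
              x$truth$zone, x$truth$separation, x$truth$volume))
  invisible(x)
}

#' Simulate a time-lapse series of one nucleus
#'
#' The nucleus (with its two foci, held rigid) performs a random walk with a
#' stated per-step RMS displacement; the true inter-allelic separation is
#' held constant across timepoints by construction. Stacks share a common
#' grid that contains the nucleus at every timepoint.
#'
#' @param model a [nucleus_model()].
#' @param n_timepoints number of frames (>= 2).
#' @param interval_min acquisition interval in minutes (metadata only).
#' @param drift RMS nuclear displacement per step (um); `0` freezes the
#'   nucleus.
#' @param separation optional fixed true separation (um).
#' @param seed integer seed.
#' @param noise logical.
#' @param on_exit `"expand"` grows the grid to contain the whole walk;
#'   `"error"` fails if the walk would carry the nucleus outside the base
#'   grid margin.
#' @return list of class `nucleus_series`: one `nucleus_sim` per timepoint,
#'   each truth carrying `time_min`.
#' @export
simulate_time_series <- function(model, n_timepoints, interval_min = 10,
                                 drift = 0.1, separation = NULL, seed = NULL,
                                 noise = model$noise,
                                 on_exit = c("expand", "error")) {
  stopifnot(inherits(model, "nucleus_model"), n_timepoints >= 2, drift >= 0)
  on_exit <- match.arg(on_exit)
  with_seed(seed, {
    k <- if (model$size_jitter_sd > 0) exp(stats::rnorm(1, 0, model$size_jitter_sd)) else 1
    semi <- model$semi_axes * k
    rnucl <- model$nucleolus_radius * k
    sep <- if (is.null(separation))
      draw_separation(model$separation_mean * k, model$separation_sd, semi)
    else separation
    rel <- sample_focus_pair(sep, semi, rnucl)
    steps <- matrix(stats::rnorm(3 * (n_timepoints - 1), 0, drift / sqrt(3)),
                    ncol = 3)
    offsets <- rbind(c(0, 0, 0), apply(steps, 2, cumsum))
    if (n_timepoints == 2) offsets <- rbind(c(0, 0, 0), steps)
    colnames(offsets) <- c("x", "y", "z")
    if (on_exit == "error" &&
        any(abs(offsets) > model$margin))
      stop("nucleus walked outside the stack margin; use on_exit = \"expand\"")
    voxel <- model$voxel_size
    span <- apply(offsets, 2, function(o) diff(range(o)))
    ext <- 2 * (semi + model$margin) + span[c("x", "y", "z")]
    dims <- c(ceiling(ext[["y"]] / voxel[["y"]]),
              ceiling(ext[["x"]] / voxel[["x"]]),
              ceiling(ext[["z"]] / voxel[["z"]]))
    base_center <- c(x = dims[2] * voxel[["x"]] / 2 - mean(range(offsets[, "x"])),
                     y = dims[1] * voxel[["y"]] / 2 - mean(range(offsets[, "y"])),
                     z = dims[3] * voxel[["z"]] / 2 - mean(range(offsets[, "z"])))
    psf <- c(x = unname(model$psf_sigma["lateral"]),
             y = unname(model$psf_sigma["lateral"]),
             z = unname(model$psf_sigma["axial"]))
    sims <- vector("list", n_timepoints)
    for (t in seq_len(n_timepoints)) {
      center <- base_center + c(offsets[t, "x"], offsets[t, "y"], offsets[t, "z"])
      coords <- sweep(rel, 2, c(center[["x"]], center[["y"]], center[["z"]]), "+")
      colnames(coords) <- c("x", "y", "z")
      foci <- array(model$background, dims)
      for (i in 1:2)
        foci <- add_spot(foci, voxel, as.list(coords[i, ]), psf, model$amplitude)
      nuc <- array(model$background, dims) + model$nucleus_amplitude *
        ellipsoid_mask(dims, voxel, as.list(center), as.list(semi))
      if (noise) {
        foci <- array(apply_shot_noise(foci, model$read_noise), dims)
        nuc <- array(apply_shot_noise(nuc, model$read_noise), dims)
      }
      data <- array(0, c(dims, 2L))
      data[, , , 1] <- foci
      data[, , , 2] <- nuc
      truth <- structure(list(
        coords = coords, separation = sep, volume = nucleus_volume(semi),
        zone = model$zone, dose_gy = 0, time_h = 0, genotype = "wild_type",
        semi_axes = semi, nucleolus_radius = rnucl, center = center,
        size_factor = k, seed = seed,
        time_min = (t - 1) * interval_min), class = "synthetic_truth")
      sims[[t]] <- structure(list(
        stack = image_stack(data, voxel, c("foci", "nucleus")),
        truth = truth), class = "nucleus_sim")
    }
    structure(sims, class = "nucleus_series",
              interval_min = interval_min, drift = drift)
  })
}

#' Simulate a dose-response panel of nucleus stacks
#'
#' For each dose, per-nucleus true separations are drawn around the
#' dose-response model's predicted mean for (dose, time); with the model's
#' dose-dependent pairing probability a nucleus instead receives a
#' near-coincident pair (separation drawn uniformly below 0.2 um). Nucleus
#' size (and hence the volume distribution) does not depend on dose.
#' Genotype switches disable the distance shortening and/or the pairing
#' boost without touching anything else.
#'
#' @param model a [nucleus_model()].
#' @param dr a [dose_response_model()].
#' @param doses numeric vector of doses (Gy, >= 0).
#' @param n_per_dose nuclei per dose (>= 1).
#' @param time_h hours after irradiation.
#' @param seed integer seed; per-nucleus substreams are derived from it.
#' @param genotype list with `label`, `shortening`, `pairing` (defaults:
#'   wild type, both effects enabled).
#' @param noise logical.
#' @return list of class `dose_panel` with `sims` (list of `nucleus_sim`)
#'   and `manifest` (one data.frame row per nucleus: id, zone, dose_gy,
#'   time_h, genotype, truth_separation_um, truth_volume_um3, truth_paired).
#' @export
simulate_dose_panel <- function(model, dr, doses, n_per_dose, time_h = 0,
                                seed = NULL,
                                genotype = list(label = "wild_type",
                                                shortening = TRUE,
                                                pairing = TRUE),
                                noise = model$noise) {
  stopifnot(inherits(model, "nucleus_model"),
            inherits(dr, "dose_response_model"),
            all(doses >= 0), n_per_dose >= 1, time_h >= 0)
  seed <- seed %||% stats::runif(1, 1, 2^30)
  sims <- list()
  rows <- list()
  idx <- 0L
  for (d in doses) {
    mu <- predict_separation(dr, d, time_h, shortening = isTRUE(genotype$shortening))
    ppair <- predict_pairing(dr, d, time_h, pairing = isTRUE(genotype$pairing))
    for (i in seq_len(n_per_dose)) {
      idx <- idx + 1L
      sub_seed <- derive_seed(seed, idx)
      mod_i <- model
      mod_i$separation_mean <- mu
      paired_truth <- with_seed(derive_seed(sub_seed, 7L),
                                stats::runif(1) < ppair)
      sep_override <- if (paired_truth)
        with_seed(derive_seed(sub_seed, 11L), stats::runif(1, 0, 0.2)) else NULL
      sim <- simulate_nucleus_stack(mod_i, separation = sep_override,
                                    seed = sub_seed, noise = noise)
      sim$truth$dose_gy <- d
      sim$truth$time_h <- time_h
      sim$truth$genotype <- genotype$label
      sim$truth$paired_truth <- paired_truth
      sims[[idx]] <- sim
      rows[[idx]] <- data.frame(
        id = sprintf("n%04d", idx), zone = model$zone, dose_gy = d,
        time_h = time_h, genotype = genotype$label,
        truth_separation_um = sim$truth$separation,
        truth_volume_um3 = sim$truth$volume,
        truth_paired = paired_truth)
    }
  }
  structure(list(sims = sims, manifest = do.call(rbind, rows)),
            class = "dose_panel")
}
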