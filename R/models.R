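#' Generative model of a locus-tagged root nucleus
#'
#' Describes one interphase nucleus of an *Arabidopsis* root as an ellipsoid
#' with a central spherical nucleolus, carrying two sub-resolution
#' fluorescent foci (the two homologous tagged loci) at a controlled true 3D
#' separation. Meristematic-zone nuclei are small diploid-cycling nuclei
#' modelled as a 2.3-um-radius sphere; elongation-zone nuclei are
#' endoreplicated, roughly four-fold larger by volume, and elongated along x.
#'
#' Units are micrometres throughout; `amplitude` and `background` are in
#' photons (Poisson shot noise applies to both when noise is enabled).
#'
#' @param zone `"meristematic"` or `"elongation"`; selects the default
#'   geometry and separation distribution.
#' @param semi_axes ellipsoid semi-axes `c(x=, y=, z=)` in um.
#' @param nucleolus_radius radius (um) of the central nucleolar exclusion
#'   zone; must fit strictly inside the nucleus.
#' @param separation_mean,separation_sd mean and SD (um) of the true
#'   inter-allelic separation; draws come from a normal truncated to
#'   `[0, 2 * max(semi_axes)]` (the longest chord of the nucleus).
#' @param amplitude integrated photons per focus.
#' @param background photon background level per voxel (foci channel).
#' @param nucleus_amplitude photon level of the nucleus (chromatin) channel
#'   inside the nucleus, above the same background.
#' @param psf_sigma Gaussian PSF sigmas `c(lateral=, axial=)` in um.
#' @param voxel_size voxel size `c(x=, y=, z=)` in um.
#' @param margin clearance (um) between nucleus surface and stack border.
#' @param size_jitter_sd SD of the log-normal factor applied per nucleus to
#'   the linear size (semi-axes, nucleolus, separation mean), giving natural
#'   nucleus-to-nucleus volume variation without affecting dose conditions.
#' @param read_noise SD (photons) of additive Gaussian read noise.
#' @param noise logical; default noise setting for generated stacks.
#' @return object of class `nucleus_model`.
#' @export
nucleus_model <- function(zone = c("meristematic", "elongation"),
                          semi_axes = NULL,
                          nucleolus_radius = NULL,
                          separation_mean = NULL,
                          separation_sd = NULL,
                          amplitude = 2000,
                          background = 10,
                          nucleus_amplitude = 50,
                          psf_sigma = c(lateral = 0.125, axial = 0.3),
                          voxel_size = c(x = 0.1, y = 0.1, z = 0.5),
                          margin = 1,
                          size_jitter_sd = 0.08,
                          read_noise = 2,
                          noise = TRUE) {
  zone <- match.arg(zone)
  if (is.null(semi_axes))
    semi_axes <- if (zone == "meristematic") c(x = 2.3, y = 2.3, z = 2.3)
                 else c(x = 4.6, y = 3.25, z = 3.25)
  semi_axes <- semi_axes[c("x", "y", "z")]
  if (is.null(nucleolus_radius))
    nucleolus_radius <- if (zone == "meristematic") 1.17 else 1.86
  if (is.null(separation_mean))
    separation_mean <- if (zone == "meristematic") 3.5 else 5.5
  if (is.null(separation_sd))
    separation_sd <- if (zone == "meristematic") 1.0 else 1.2
  stopifnot(all(semi_axes > 0), nucleolus_radius > 0,
            separation_mean >= 0, separation_sd >= 0,
            amplitude > 0, background >= 0, all(psf_sigma > 0),
            all(voxel_size > 0), margin >= 0)
  if (nucleolus_radius >= min(semi_axes))
    stop("nucleolus must fit strictly inside the nucleus")
  structure(list(zone = zone, semi_axes = semi_axes,
                 nucleolus_radius = nucleolus_radius,
                 separation_mean = separation_mean,
                 separation_sd = separation_sd,
                 amplitude = amplitude, background = background,
                 nucleus_amplitude = nucleus_amplitude,
                 psf_sigma = c(lateral = unname(psf_sigma[1]),
                               axial = unname(psf_sigma[2])),
                 voxel_size = voxel_size[c("x", "y", "z")],
                 margin = margin, size_jitter_sd = size_jitter_sd,
                 read_noise = read_noise, noise = noise),
            class = "nucleus_model")
}

#' @export
print.nucleus_model <- function(x, ...) {
  cat(sprintf("<nucleus_model> zone=%s, semi-axes (um) %.2f/%.2f/%.2f, nucleolus %.2f um\n",
              x$zone, x$semi_axes["x"], x$semi_axes["y"], x$semi_axes["z"],
              x$nucleolus_radius))
  cat(sprintf("  separation %.2f +/- %.2f um; amplitude %g photons, background %g\n",
              x$separation_mean, x$separation_sd, x$amplitude, x$background))
  invisible(x)
}

nucleus_volume <- function(semi_axes) 4 / 3 * pi * prod(semi_axes)

#' Dose-response model for DSB-induced locus approach
#'
#' Parametric description of how the mean inter-allelic separation responds
#' to an acute DNA double-strand-break dose and then recovers: a saturating
#' exponential shortening in dose, relaxing exponentially in time,
#' \deqn{s(D, t) = s_0 - A (1 - e^{-D/D_{1/2}}) e^{-t/\tau}.}
#' The same saturating dose term, with the same relaxation, drives the
#' probability that the two loci fully pair (overlap below resolution).
#'
#' @param baseline unirradiated mean separation s0 (um).
#' @param amplitude maximal shortening A (um) at saturating dose.
#' @param half_dose_gy dose scale D1/2 (Gy) of the saturating exponential.
#' @param recovery_tau_h time constant tau (h) of post-dose recovery.
#' @param pairing_max maximal pairing probability at saturating dose (only
#'   expressed by pairing-competent genotypes).
#' @return object of class `dose_response_model`.
#' @export
dose_response_model <- function(baseline = 3.5, amplitude = 1.5,
                                half_dose_gy = 60, recovery_tau_h = 6,
                                pairing_max = 0.3) {
  stopifnot(baseline > 0, amplitude >= 0, amplitude <= baseline,
            half_dose_gy > 0, recovery_tau_h > 0,
            pairing_max >= 0, pairing_max <= 1)
  structure(list(baseline = baseline, amplitude = amplitude,
                 half_dose_gy = half_dose_gy,
                 recovery_tau_h = recovery_tau_h,
                 pairing_max = pairing_max),
            class = "dose_response_model")
}

#' Predicted mean separation at a given dose and post-dose time
#'
#' @param model a `dose_response_model`.
#' @param dose_gy dose in Gy (vectorized).
#' @param time_h hours after irradiation.
#' @param shortening logical; `FALSE` disables the dose effect (mutant
#'   genotypes that do not shorten).
#' @return predicted mean separation (um).
#' @export
predict_separation <- function(model, dose_gy, time_h = 0, shortening = TRUE) {
  stopifnot(inherits(model, "dose_response_model"), all(dose_gy >= 0),
            all(time_h >= 0))
  if (!shortening) return(rep(model$baseline, length(dose_gy)))
  model$baseline - model$amplitude * (1 - exp(-dose_gy / model$half_dose_gy)) *
    exp(-time_h / model$recovery_tau_h)
}

#' Predicted pairing probability at a given dose and post-dose time
#'
#' @inheritParams predict_separation
#' @param pairing logical; `FALSE` disables dose-induced pairing.
#' @return probability in [0, 1].
#' @export
predict_pairing <- function(model, dose_gy, time_h = 0, pairing = TRUE) {
  stopifnot(inherits(model, "dose_response_model"))
  if (!pairing) return(rep(0, length(dose_gy)))
  model$pairing_max * (1 - exp(-dose_gy / model$half_dose_gy)) *
    exp(-time_h / model$recovery_tau_h)
}

#' Generative model of a single neutral-comet image
#'
#' A bright circular head plus an exponentially decaying tail along +x
#' (the migration axis), carrying a requested fraction of the total DNA
#' signal. Total rendered intensity (head + tail, before noise) equals
#' `intensity` regardless of the split.
#'
#' @param head_center head centre `c(x=, y=)` in pixels.
#' @param head_radius head radius (px).
#' @param head_gap gap (px) between the head edge and the tail start, so
#'   head and tail signal remain attributable.
#' @param tail_length tail extent (px) beyond the head gap; the rendered
#'   tail decays with length constant `tail_length / 3` and is truncated at
#'   `tail_length`.
#' @param tail_fraction fraction of total intensity in the tail, in [0, 1].
#' @param intensity total signal photons (head + tail).
#' @param background photon background per pixel.
#' @param image_size image dimensions `c(ny=, nx=)` in pixels.
#' @param tail_sigma_y Gaussian cross-section SD (px) of the tail.
#' @param edge_sigma softening (px) of the head disc edge.
#' @param read_noise SD of additive Gaussian read noise (photons).
#' @param noise logical; default noise setting.
#' @return object of class `comet_model`.
#' @export
comet_model <- function(head_center = c(x = 64, y = 48), head_radius = 12,
                        head_gap = 3, tail_length = 96, tail_fraction = 0.3,
                        intensity = 20000, background = 5,
                        image_size = c(ny = 96, nx = 256),
                        tail_sigma_y = NULL, edge_sigma = 0.75,
                        read_noise = 2, noise = TRUE) {
  stopifnot(head_radius > 0, head_gap >= 0, tail_length >= 0,
            tail_fraction >= 0, tail_fraction <= 1,
            intensity > 0, background >= 0)
  if (is.null(tail_sigma_y)) tail_sigma_y <- 0.6 * head_radius
  hx <- head_center[["x"]]; hy <- head_center[["y"]]
  ny <- image_size[["ny"]]; nx <- image_size[["nx"]]
  if (hx - head_radius < 1 || hy - head_radius < 1 || hy + head_radius > ny ||
      hx + head_radius + head_gap + tail_length > nx)
    stop("head and tail must fit inside the image")
  structure(list(head_center = c(x = hx, y = hy), head_radius = head_radius,
                 head_gap = head_gap,
                 tail_length = tail_length, tail_fraction = tail_fraction,
                 intensity = intensity, background = background,
                 image_size = c(ny = ny, nx = nx),
                 tail_sigma_y = tail_sigma_y, edge_sigma = edge_sigma,
                 read_noise = read_noise, noise = noise),
            class = "comet_model")
}
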