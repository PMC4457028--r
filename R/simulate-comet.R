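# Synthetic neutral-comet images with a controlled tail DNA fraction.

#' Simulate one comet image with ground truth
#'
#' Renders a bright, edge-softened circular head and an exponentially
#' decaying tail along +x (the migration axis) starting at the head edge,
#' truncated at the model tail length. The head and tail are scaled so the
#' tail carries exactly the requested fraction of the total signal, and the
#' total rendered intensity (before noise) equals the model's `intensity`.
#'
#' @param model a [comet_model()].
#' @param seed integer seed.
#' @param noise logical (default from the model).
#' @return list of class `comet_sim`: `stack` (2D [image_stack()], channel
#'   `"comet"`, pixel units), `truth` (head_center, head_radius,
#'   tail_length_px = distance from head centre to tail end, tail_fraction,
#'   head_sum, tail_sum).
#' @export
simulate_comet_image <- function(model, seed = NULL, noise = model$noise) {
  stopifnot(inherits(model, "comet_model"))
  with_seed(seed, {
    ny <- model$image_size[["ny"]]; nx <- model$image_size[["nx"]]
    hx <- model$head_center[["x"]]; hy <- model$head_center[["y"]]
    R <- model$head_radius
    xs <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    ys <- matrix(seq_len(ny), ny, nx)
    rr <- sqrt((xs - hx)^2 + (ys - hy)^2)
    head_profile <- stats::pnorm((R - rr) / model$edge_sigma)
    f <- model$tail_fraction
    head_img <- if (sum(head_profile) > 0 && f < 1)
      (1 - f) * model$intensity * head_profile / sum(head_profile)
    else matrix(0, ny, nx)
    L <- model$tail_length
    tail_img <- matrix(0, ny, nx)
    if (f > 0 && L > 0) {
      dx <- xs - (hx + R + model$head_gap)
      prof <- exp(-dx / (L / 3)) * exp(-(ys - hy)^2 / (2 * model$tail_sigma_y^2))
      prof[dx <= 0 | dx > L] <- 0
      if (sum(prof) > 0) tail_img <- f * model$intensity * prof / sum(prof)
    }
    img <- model$background + head_img + tail_img
    if (noise)
      img <- matrix(apply_shot_noise(img, model$read_noise), ny, nx)
    truth <- structure(list(
      head_center = model$head_center, head_radius = R,
      tail_length_px = if (f > 0 && L > 0) R + model$head_gap + L else 0,
      tail_fraction = f,
      head_sum = sum(head_img), tail_sum = sum(tail_img)),
      class = "synthetic_truth")
    structure(list(stack = image_stack(array(img, c(ny, nx, 1, 1)),
                                       c(x = 1, y = 1, z = 1), "comet"),
                   truth = truth),
              class = "comet_sim")
  })
}

#' Simulate a panel of comet images over conditions
#'
#' @param model base [comet_model()].
#' @param tail_fractions named numeric vector: condition -> tail DNA
#'   fraction (e.g. `c(control = 0.05, "0" = 0.5, "24" = 0.08)`).
#' @param n_per_group comets per condition.
#' @param seed integer seed.
#' @return named list (per condition) of lists of `comet_sim`.
#' @export
simulate_comet_panel <- function(model, tail_fractions, n_per_group,
                                 seed = NULL) {
  stopifnot(inherits(model, "comet_model"), n_per_group >= 1,
            !is.null(names(tail_fractions)))
  seed <- seed %||% stats::runif(1, 1, 2^30)
  out <- list()
  k <- 0L
  for (g in names(tail_fractions)) {
    sims <- vector("list", n_per_group)
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      mod <- model
      # mild comet-to-comet variability around the condition's fraction
      f <- with_seed(derive_seed(seed, 10000L + k),
                     min(1, max(0, stats::rnorm(1, tail_fractions[[g]], 0.05))))
      mod$tail_fraction <- f
      sims[[i]] <- simulate_comet_image(mod, seed = derive_seed(seed, k))
    }
    out[[g]] <- sims
  }
  out
}
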