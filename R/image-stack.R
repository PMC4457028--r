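#' Multi-channel image stack with physical voxel sizes
#'
#' Container for a 3D (or 2D, with one z-slice) intensity array plus the
#' physical voxel size per axis and the role of each channel. All physical
#' positions produced by this package are voxel-center coordinates in
#' micrometres: a voxel with 0-based index i along an axis with voxel size v
#' is centred at (i + 0.5) * v.
#'
#' @param data numeric array, either 3D (y, x, z; single channel) or 4D
#'   (y, x, z, channel). Intensities must be finite and non-negative.
#' @param voxel_size named numeric vector `c(x=, y=, z=)`, micrometres per
#'   voxel along each axis (all > 0).
#' @param channels character vector of channel roles, e.g.
#'   `c("foci", "nucleus")` or `"comet"`; length must match the channel
#'   dimension.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, voxel_size, channels = "foci") {
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) == 3) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 4, all(dim(data) > 0))
  if (!all(is.finite(data)) || any(data < 0))
    stop("stack intensities must be finite and non-negative")
  voxel_size <- voxel_size[c("x", "y", "z")]
  if (any(is.na(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must provide positive x, y, z sizes")
  if (length(channels) != dim(data)[4])
    stop("length(channels) must equal the number of channels in `data`")
  structure(list(data = data, voxel_size = voxel_size,
                 channels = as.character(channels)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d x %d voxels, %d channel(s): %s\n",
              d[1], d[2], d[3], d[4], paste(x$channels, collapse = ", ")))
  cat(sprintf("  voxel size (um): x=%.3g y=%.3g z=%.3g\n",
              x$voxel_size["x"], x$voxel_size["y"], x$voxel_size["z"]))
  ext <- stack_extent(x)
  cat(sprintf("  physical extent (um): x=%.3g y=%.3g z=%.3g\n",
              ext["x"], ext["y"], ext["z"]))
  invisible(x)
}

#' Extract one channel of a stack as a 3D array
#'
#' @param stack an `image_stack`.
#' @param channel channel role name (e.g. `"foci"`) or integer index.
#' @return numeric 3D array (y, x, z).
#' @export
stack_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel)) {
    idx <- match(channel, stack$channels)
    if (is.na(idx)) stop(sprintf("stack has no '%s' channel", channel))
  } else idx <- as.integer(channel)
  a <- stack$data[, , , idx, drop = FALSE]
  dim(a) <- dim(a)[1:3]
  a
}

# Physical extent (um) along x, y, z.
stack_extent <- function(stack) {
  d <- dim(stack$data)
  c(x = d[2] * stack$voxel_size[["x"]],
    y = d[1] * stack$voxel_size[["y"]],
    z = d[3] * stack$voxel_size[["z"]])
}

# Voxel-center physical coordinates along one axis ("x", "y", "z").
axis_coords <- function(stack, axis) {
  d <- dim(stack$data)
  n <- switch(axis, y = d[1], x = d[2], z = d[3])
  (seq_len(n) - 0.5) * stack$voxel_size[[axis]]
}
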