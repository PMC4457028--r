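# TIFF + sidecar-JSON persistence for stacks, panel manifests, and
# measurement tables.

#' Write an image stack as multi-page TIFF with a sidecar JSON
#'
#' Pages are ordered channel-major (all z-slices of channel 1, then channel
#' 2, ...). Pixel data are stored as 32-bit float scaled into [0, 1]; the
#' scale factor, voxel sizes, channel roles and dimensions go into the
#' sidecar JSON (`<path>.json`), which is the authoritative carrier of the
#' physical geometry. Optional `truth` metadata (a `synthetic_truth`) is
#' embedded in the sidecar.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @param truth optional truth record to embed.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, truth = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  scale <- max(stack$data, 1e-12)
  pages <- list()
  for (c in seq_len(d[4])) for (z in seq_len(d[3]))
    pages[[length(pages) + 1]] <- stack$data[, , z, c] / scale
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  meta <- list(voxel_size_um = as.list(stack$voxel_size),
               channels = stack$channels,
               dims = d, intensity_scale = scale)
  if (!is.null(truth)) {
    tr <- unclass(truth)
    if (!is.null(tr$coords)) tr$coords <- unname(apply(tr$coords, 1, as.list))
    meta$truth <- tr
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an image stack written by [write_stack_tiff()]
#'
#' @param path TIFF path (expects `<path>.json` alongside).
#' @return list: `stack` (an [image_stack()]) and `truth` (list or `NULL`).
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dims)
  data <- array(0, d)
  k <- 0L
  for (c in seq_len(d[4])) for (z in seq_len(d[3])) {
    k <- k + 1L
    data[, , z, c] <- pages[[k]] * meta$intensity_scale
  }
  stack <- image_stack(data,
                       c(x = meta$voxel_size_um$x, y = meta$voxel_size_um$y,
                         z = meta$voxel_size_um$z),
                       meta$channels)
  list(stack = stack, truth = meta$truth)
}

#' Write a simulated panel to disk (TIFFs + manifest CSV)
#'
#' One TIFF + sidecar per nucleus; `manifest.csv` gets one row per stack
#' (path, zone, dose_gy, time_h, genotype, truth_separation_um,
#' truth_volume_um3).
#'
#' @param panel a `dose_panel` from [simulate_dose_panel()].
#' @param dir output directory (created if missing).
#' @return path of the manifest CSV, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "dose_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- panel$manifest
  man$path <- file.path(dir, paste0(man$id, ".tif"))
  for (i in seq_along(panel$sims))
    write_stack_tiff(panel$sims[[i]]$stack, man$path[i],
                     truth = panel$sims[[i]]$truth)
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  invisible(man_path)
}

#' Measure all stacks listed in a panel manifest
#'
#' Runs focus detection, pair measurement and (optionally) nucleus
#' segmentation on every stack of a manifest, returning the per-nucleus
#' measurements table.
#'
#' @param manifest manifest data.frame or path to a manifest CSV with a
#'   `path` column.
#' @param pairing_threshold pairing threshold (um), recorded per row.
#' @param spot_sigma expected spot sigmas `c(lateral=, axial=)` (um).
#' @param volumes logical; also segment the nucleus channel.
#' @return data.frame: one row per nucleus with id, condition metadata,
#'   `distance_um` (NA for unmeasurable nuclei), `paired`, `n_candidates`,
#'   `threshold_um`, and (if `volumes`) `volume_um3`, `clipped`.
#' @export
measure_panel <- function(manifest, pairing_threshold = 0.4,
                          spot_sigma = c(lateral = 0.125, axial = 0.3),
                          volumes = TRUE) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot("path" %in% names(manifest))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    st <- read_stack_tiff(manifest$path[i])$stack
    pair <- measure_stack(st, spot_sigma = spot_sigma,
                          pairing_threshold = pairing_threshold)
    row <- data.frame(
      id = manifest$id[i] %||% basename(manifest$path[i]),
      zone = manifest$zone[i] %||% NA,
      dose_gy = manifest$dose_gy[i] %||% NA,
      time_h = manifest$time_h[i] %||% NA,
      genotype = manifest$genotype[i] %||% NA,
      distance_um = if (is.null(pair)) NA_real_ else pair$distance_um,
      paired = if (is.null(pair)) NA else pair$paired,
      n_candidates = if (is.null(pair)) 0L else pair$n_candidates,
      threshold_um = pairing_threshold)
    if (volumes) {
      seg <- tryCatch(segment_nucleus(st), error = function(e) NULL)
      row$volume_um3 <- if (is.null(seg)) NA_real_ else seg$measurement$volume_um3
      row$clipped <- if (is.null(seg)) NA else seg$measurement$clipped
    }
    row
  })
  do.call(rbind, rows)
}
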