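#' Calibrated multi-channel z-stack
#'
#' Container for a confocal acquisition: three fluorescence channels
#' (Collagen IV basement-membrane stain, alpha-smooth-muscle-actin, and the
#' amyloid-beta channel), each a `z * y * x` array of nonnegative
#' intensities, with the lateral calibration in micrometres per pixel and
#' the axial step in micrometres.
#'
#' @param channels named list with elements `collagen4`, `sma`, `abeta`,
#'   each a 3D numeric array indexed `[z, y, x]` (a 2D matrix is promoted to
#'   a single-plane stack). All channels must share one shape.
#' @param pixel_size_um lateral calibration, micrometres per pixel (> 0).
#' @param z_step_um axial step between planes in micrometres (> 0).
#' @return An object of class `zstack_image`.
#' @export
zstack_image <- function(channels, pixel_size_um, z_step_um = 0.69) {
  required <- c("collagen4", "sma", "abeta")
  if (!is.list(channels) || !all(required %in% names(channels))) {
    stop("`channels` must be a named list containing: ",
         paste(required, collapse = ", "))
  }
  channels <- channels[required]
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, dim = c(1L, dim(ch)))
    if (!is.array(ch) || length(dim(ch)) != 3L)
      stop("each channel must be a 2D matrix or 3D array [z, y, x]")
    storage.mode(ch) <- "double"
    ch
  })
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all channels must share the same [z, y, x] shape")
  if (dims[[1]][1] < 1L) stop("stack has an empty z-dimension")
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1))))
    stop("intensities must be nonnegative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  if (!is.numeric(z_step_um) || z_step_um <= 0)
    stop("`z_step_um` must be positive")
  structure(list(channels = channels,
                 pixel_size_um = as.numeric(pixel_size_um),
                 z_step_um = as.numeric(z_step_um)),
            class = "zstack_image")
}

#' @export
print.zstack_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<zstack_image> %d plane(s), %d x %d px, %.4f um/px, dz = %.2f um\n",
              d[1], d[2], d[3], x$pixel_size_um, x$z_step_um))
  invisible(x)
}

#' Maximum-intensity projected image
#'
#' @param channels named list of 2D matrices (`collagen4`, `sma`, `abeta`).
#' @param pixel_size_um lateral calibration in micrometres per pixel.
#' @return An object of class `projected_image`.
#' @export
projected_image <- function(channels, pixel_size_um) {
  required <- c("collagen4", "sma", "abeta")
  if (!all(required %in% names(channels)))
    stop("`channels` must contain: ", paste(required, collapse = ", "))
  channels <- lapply(channels[required], function(ch) {
    if (!is.matrix(ch)) stop("projected channels must be 2D matrices")
    storage.mode(ch) <- "double"
    ch
  })
  dims <- lapply(channels, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all channels must share the same 2D shape")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be positive")
  structure(list(channels = channels, pixel_size_um = as.numeric(pixel_size_um)),
            class = "projected_image")
}

#' @export
print.projected_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<projected_image> %d x %d px, %.4f um/px\n", d[1], d[2],
              x$pixel_size_um))
  invisible(x)
}

#' Maximum Z-projection of a stack
#'
#' Collapses each channel of a z-stack to a 2D image by taking, at every
#' pixel, the maximum intensity across all z planes. Calibration is
#' preserved.
#'
#' @param stack a [zstack_image].
#' @return A [projected_image].
#' @export
max_project <- function(stack) {
  if (!inherits(stack, "zstack_image")) stop("`stack` must be a zstack_image")
  if (dim(stack$channels[[1]])[1] < 1L) stop("stack has an empty z-dimension")
  proj <- lapply(stack$channels, function(ch) apply(ch, c(2, 3), max))
  projected_image(proj, stack$pixel_size_um)
}

#' Lateral calibration from field width
#'
#' The calibration follows from the physical field of view and the matrix
#' size: a 581.25 um field imaged at 1024 px gives 0.5676 um/pixel.
#'
#' @param field_width_um physical field width in micrometres (> 0).
#' @param width_px matrix width in pixels (> 0).
#' @return Micrometres per pixel.
#' @export
compute_calibration <- function(field_width_um, width_px) {
  if (!is.numeric(field_width_um) || field_width_um <= 0)
    stop("`field_width_um` must be positive")
  if (!is.numeric(width_px) || width_px <= 0)
    stop("`width_px` must be positive")
  field_width_um / width_px
}

#' Pixel count to physical area
#'
#' @param n_px nonnegative pixel count.
#' @param um_per_px calibration in micrometres per pixel (> 0).
#' @return Area in square micrometres, `n_px * um_per_px^2`.
#' @export
px_to_um2 <- function(n_px, um_per_px) {
  if (!is.numeric(n_px) || any(n_px < 0)) stop("`n_px` must be nonnegative")
  if (!is.numeric(um_per_px) || any(um_per_px <= 0))
    stop("`um_per_px` must be positive")
  n_px * um_per_px^2
}

#' Write a z-stack to a multi-page TIFF
#'
#' Planes are stored channel-fastest (for each z: collagen4, sma, abeta) as
#' 16-bit pages; intensities must lie in `[0, 1]` and are quantised to the
#' 16-bit grid (`k / 65535`), the microscopy-standard bit depth. Values
#' already on that grid round-trip exactly. Because baseline TIFF
#' written by this toolchain carries no calibration tag, the calibration is
#' recorded in a JSON sidecar `<path>.json` which [read_zstack()] consults
#' when no explicit calibration is given.
#'
#' @param stack a [zstack_image].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_zstack <- function(stack, path) {
  if (!inherits(stack, "zstack_image")) stop("`stack` must be a zstack_image")
  if (any(vapply(stack$channels, max, numeric(1)) > 1))
    stop("TIFF storage is defined for intensities in [0, 1]; rescale first")
  nz <- dim(stack$channels[[1]])[1]
  pages <- vector("list", nz * 3L)
  k <- 0L
  for (z in seq_len(nz)) {
    for (ch in c("collagen4", "sma", "abeta")) {
      k <- k + 1L
      pages[[k]] <- stack$channels[[ch]][z, , ]
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size_um, z_step_um = stack$z_step_um,
         n_z = nz, channel_order = c("collagen4", "sma", "abeta")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibrated multi-channel z-stack from TIFF
#'
#' Pages are interpreted channel-fastest: page index `(z - 1) * n_channels +
#' channel_map[[name]] + 1`. Calibration precedence: an explicit
#' `pixel_size_um` argument overrides file metadata (the JSON sidecar
#' written by [write_zstack()]); if neither is available an error is raised.
#'
#' @param path TIFF file path.
#' @param channel_map named list of 0-based channel indices within a z-slot;
#'   must cover `collagen4`, `sma`, `abeta`. Default `list(collagen4 = 0,
#'   sma = 1, abeta = 2)`.
#' @param pixel_size_um optional explicit calibration override (um/pixel).
#' @param z_step_um optional explicit axial step override (um).
#' @param n_channels number of channels stored per z-slot (default: the
#'   number of entries needed to cover the largest mapped index).
#' @return A [zstack_image].
#' @export
read_zstack <- function(path, channel_map = list(collagen4 = 0, sma = 1, abeta = 2),
                        pixel_size_um = NULL, z_step_um = NULL,
                        n_channels = NULL) {
  required <- c("collagen4", "sma", "abeta")
  missing_ch <- setdiff(required, names(channel_map))
  if (length(missing_ch) > 0)
    stop("channel_map is missing channel(s): ", paste(missing_ch, collapse = ", "))
  idx <- vapply(channel_map[required], as.integer, integer(1))
  if (is.null(n_channels)) n_channels <- max(idx) + 1L
  if (any(idx >= n_channels) || any(idx < 0))
    stop("channel indices must lie in [0, n_channels)")

  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(pg) if (length(dim(pg)) == 3L) pg[, , 1] else pg)
  shapes <- lapply(pages, dim)
  if (!all(vapply(shapes, identical, logical(1), shapes[[1]])))
    stop("TIFF pages have inconsistent plane shapes")
  if (length(pages) %% n_channels != 0L)
    stop("page count ", length(pages), " is not a multiple of n_channels = ",
         n_channels)
  nz <- length(pages) %/% n_channels

  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- tryCatch(jsonlite::read_json(sidecar), error = function(e) NULL)
  if (is.null(pixel_size_um)) pixel_size_um <- meta$pixel_size_um
  if (is.null(z_step_um)) z_step_um <- if (!is.null(meta$z_step_um)) meta$z_step_um else 0.69
  if (is.null(pixel_size_um))
    stop("no pixel calibration: supply `pixel_size_um` or provide file metadata")

  ny <- shapes[[1]][1]; nx <- shapes[[1]][2]
  channels <- lapply(setNames(idx, required), function(ci) {
    arr <- array(0, dim = c(nz, ny, nx))
    for (z in seq_len(nz)) arr[z, , ] <- pages[[(z - 1L) * n_channels + ci + 1L]]
    arr
  })
  zstack_image(channels, pixel_size_um = as.numeric(pixel_size_um),
               z_step_um = as.numeric(z_step_um))
}
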