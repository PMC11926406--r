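#' Single-channel 3D voxel image
#'
#' A `voxel_image` holds one fluorescence channel as a 3D intensity grid in
#' `(z, y, x)` order together with its physical voxel spacing. The axial
#' (z) dimension corresponds to the optical-section axis of a confocal
#' z-stack; physical position of voxel index `i` (0-based) along an axis is
#' `i * spacing` (voxel centers).
#'
#' @param data 3D numeric array, dimensions `(nz, ny, nx)`, finite and
#'   non-negative intensities in arbitrary units.
#' @param spacing numeric length-3, `(dz, dy, dx)` voxel size in micrometers;
#'   all entries must be positive. The default axial step of 0.2 um matches
#'   typical spinning-disk optical sectioning.
#' @param channel_label free-text channel name.
#' @return An object of class `voxel_image`.
#' @examples
#' img <- voxel_image(array(0, c(4, 8, 8)), spacing = c(0.2, 0.1, 0.1))
#' dim(img$data)
#' @export
voxel_image <- function(data, spacing = c(0.2, 0.1, 0.1), channel_label = "") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_input("`data` must be a 3D array (z, y, x); got dimensions [%s]",
               paste(dim(data), collapse = ", "))
  }
  if (any(dim(data) < 1L)) stop_input("every axis needs at least one voxel")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    stop_input("`spacing` must be three positive values (dz, dy, dx) in um")
  }
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop_input("intensities must be finite")
  if (any(data < 0)) stop_input("intensities must be non-negative")
  structure(
    list(data = data, spacing = spacing, channel_label = as.character(channel_label)[1]),
    class = "voxel_image"
  )
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_image> %d x %d x %d (z,y,x), spacing %.3g/%.3g/%.3g um%s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              if (nzchar(x$channel_label)) paste0(", channel '", x$channel_label, "'") else ""))
  invisible(x)
}

#' Multi-channel 3D image
#'
#' Bundles co-registered channels of one acquired cell. All channels must
#' share grid shape and voxel spacing.
#'
#' @param channels list of [voxel_image()] objects, ordered as acquired.
#' @param cell_id identifier for the imaged cell.
#' @return An object of class `multi_channel_image`.
#' @export
multi_channel_image <- function(channels, cell_id = "cell") {
  if (!is.list(channels) || length(channels) < 1L) {
    stop_input("`channels` must be a non-empty list of voxel_image objects")
  }
  ok <- vapply(channels, inherits, logical(1), "voxel_image")
  if (!all(ok)) stop_input("all channels must be voxel_image objects")
  ref <- channels[[1]]
  for (ch in channels[-1]) {
    if (!identical(dim(ch$data), dim(ref$data))) {
      stop_input("all channels must share an identical grid shape")
    }
    if (max(abs(ch$spacing - ref$spacing)) > 1e-12) {
      stop_input("all channels must share identical voxel spacing")
    }
  }
  structure(list(channels = channels, cell_id = as.character(cell_id)[1]),
            class = "multi_channel_image")
}

#' @export
print.multi_channel_image <- function(x, ...) {
  d <- dim(x$channels[[1]]$data)
  cat(sprintf("<multi_channel_image> '%s': %d channel(s), %d x %d x %d voxels\n",
              x$cell_id, length(x$channels), d[1], d[2], d[3]))
  invisible(x)
}

#' Region-of-interest mask
#'
#' Boolean 3D mask gating which voxels enter a correlation or histogram.
#'
#' @param data 3D logical array, same shape as the images it gates.
#' @param description free text, e.g. what the ROI covers.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(data, description = "") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_input("`data` must be a 3D logical array")
  }
  if (!is.logical(data)) {
    if (is.numeric(data)) data <- array(data != 0, dim(data)) else
      stop_input("`data` must be logical")
  }
  if (anyNA(data)) stop_input("mask must not contain NA")
  structure(list(data = data, description = as.character(description)[1]),
            class = "roi_mask")
}

#' Whole-image region of interest
#'
#' Returns a mask that is true at every voxel — the default analysis region,
#' covering the entire imaged Golgi ribbon.
#'
#' @param img a [voxel_image()].
#' @return A [roi_mask()] true everywhere, same shape as `img`.
#' @examples
#' sum(whole_image_roi(voxel_image(array(0, c(4, 4, 4))))$data)
#' @export
whole_image_roi <- function(img) {
  stopifnot(inherits(img, "voxel_image"))
  roi_mask(array(TRUE, dim(img$data)), description = "whole image")
}

# internal: validate that a mask matches an image and select its voxels
check_roi <- function(img, roi, require_nonempty = TRUE) {
  if (is.null(roi)) roi <- whole_image_roi(img)
  stopifnot(inherits(roi, "roi_mask"))
  if (!identical(dim(roi$data), dim(img$data))) {
    stop_input("ROI shape [%s] does not match image shape [%s]",
               paste(dim(roi$data), collapse = ","),
               paste(dim(img$data), collapse = ","))
  }
  if (require_nonempty && !any(roi$data)) stop_input("ROI has no true voxel")
  roi
}
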