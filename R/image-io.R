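#' Write a 3D volume (optionally multi-channel) to a multi-page TIFF
#'
#' Z-planes are written as TIFF pages; for multi-channel images the page
#' order is channel-fastest within each z-plane (page = z * C + c), the
#' plane order also used by OME-TIFF `XYCZT` stacks. Because baseline TIFF
#' tags cannot carry voxel size, acquisition metadata (voxel spacing,
#' channel count and labels, intensity scale) is written to a JSON sidecar
#' at `<path>.json`; [read_volume()] consumes it transparently.
#'
#' Integer-valued data are stored bit-exactly at 8 or 16 bits; other data
#' are stored as 32-bit float scaled to the unit range, with the scale
#' recorded in the sidecar.
#'
#' @param x a [voxel_image()] or [multi_channel_image()].
#' @param path output file path (`.tif`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "voxel_image")) x <- multi_channel_image(list(x), cell_id = "")
  stopifnot(inherits(x, "multi_channel_image"))
  nc <- length(x$channels)
  d <- dim(x$channels[[1]]$data)
  vals <- unlist(lapply(x$channels, function(ch) range(ch$data)))
  vmax <- max(vals)
  integerish <- all(vapply(x$channels, function(ch) all(ch$data == round(ch$data)), logical(1)))
  if (integerish && vmax <= 255) {
    bits <- 8L; scale <- 255
  } else if (integerish && vmax <= 65535) {
    bits <- 16L; scale <- 65535
  } else {
    bits <- 32L; scale <- if (vmax > 0) vmax else 1
  }
  pages <- vector("list", d[1] * nc)
  for (z in seq_len(d[1])) {
    for (c in seq_len(nc)) {
      pg <- x$channels[[c]]$data[z, , , drop = FALSE] / scale
      dim(pg) <- d[2:3]
      pages[[(z - 1L) * nc + c]] <- pg
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "LZW")
  meta <- list(
    format = "golgiatlas-volume",
    shape_zyx = d,
    n_channels = nc,
    channel_labels = vapply(x$channels, function(ch) ch$channel_label, character(1)),
    cell_id = x$cell_id,
    spacing_um = x$channels[[1]]$spacing,
    bits_per_sample = bits,
    scale = scale
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# pull voxel spacing / channel count out of an OME-XML ImageDescription
parse_ome_description <- function(desc) {
  grab <- function(attr) {
    m <- regmatches(desc, regexpr(sprintf('%s="([0-9.eE+\\-]+)"', attr), desc))
    if (length(m) == 0L) return(NA_real_)
    as.numeric(sub(sprintf('%s="', attr), "", sub('"$', "", m), fixed = TRUE))
  }
  list(
    spacing = c(grab("PhysicalSizeZ"), grab("PhysicalSizeY"), grab("PhysicalSizeX")),
    n_channels = grab("SizeC")
  )
}

read_volume_meta <- function(path, spacing, pages) {
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    return(list(spacing = as.numeric(meta$spacing_um),
                n_channels = as.integer(meta$n_channels),
                channel_labels = as.character(meta$channel_labels),
                scale = as.numeric(meta$scale %||% 1),
                bits = as.integer(meta$bits_per_sample %||% NA_integer_)))
  }
  desc <- attr(pages[[1]], "description")
  if (!is.null(desc) && grepl("PhysicalSize", desc)) {
    ome <- parse_ome_description(desc)
    sp <- ome$spacing
    if (all(is.finite(sp)) && all(sp > 0)) {
      nch <- if (is.finite(ome$n_channels)) as.integer(ome$n_channels) else 1L
      return(list(spacing = sp, n_channels = nch,
                  channel_labels = rep("", nch), scale = NA_real_, bits = NA_integer_))
    }
  }
  if (!is.null(spacing)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
      stop_input("`spacing` override must be three positive values (dz, dy, dx)")
    }
    return(list(spacing = spacing, n_channels = 1L, channel_labels = "",
                scale = NA_real_, bits = NA_integer_))
  }
  stop_input(paste0(
    "no voxel spacing found for '", path,
    "': the file has no metadata sidecar or OME description, ",
    "and no `spacing` override was given"))
}

#' Read one channel of a 3D TIFF z-stack
#'
#' Reads a multi-page TIFF written by [write_volume()] (metadata from the
#' JSON sidecar) or a third-party OME-TIFF (voxel spacing and channel count
#' parsed from the OME-XML ImageDescription). For plain TIFF stacks with no
#' metadata a `spacing` override is required — there is no silent default.
#' Integer data round-trip bit-exactly.
#'
#' @param path TIFF file path.
#' @param channel_index 1-based channel to extract.
#' @param spacing optional `(dz, dy, dx)` um override used when the file
#'   carries no spacing metadata.
#' @return A [voxel_image()].
#' @export
read_volume <- function(path, channel_index = 1L, spacing = NULL) {
  if (!file.exists(path)) stop_input("file not found: '%s'", path)
  # integer data are read unscaled (as.is, bit-exact); 32-bit float pages
  # must not be reinterpreted as integers, so re-read once the sample
  # format is known
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  bits_file <- attr(pages[[1]], "bits.per.sample") %||% 8L
  if (bits_file > 16L) {
    pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  }
  meta <- read_volume_meta(path, spacing, pages)
  nc <- max(1L, meta$n_channels)
  if (length(pages) %% nc != 0L) {
    stop_input("page count %d is not a multiple of channel count %d",
               length(pages), nc)
  }
  channel_index <- as.integer(channel_index)
  if (channel_index < 1L || channel_index > nc) {
    stop_input("channel_index %d out of range: file has %d channel(s)",
               channel_index, nc)
  }
  nz <- length(pages) %/% nc
  p1 <- pages[[channel_index]]
  if (length(dim(p1)) > 2L) stop_input("multi-sample (RGB) TIFF pages are not supported")
  arr <- array(0, c(nz, nrow(p1), ncol(p1)))
  for (z in seq_len(nz)) {
    pg <- pages[[(z - 1L) * nc + channel_index]]
    arr[z, , ] <- pg
  }
  # our float volumes are stored scaled to [0,1]; undo using the sidecar scale
  if (is.finite(meta$scale) && !is.na(meta$bits) && meta$bits == 32L) {
    arr <- arr * meta$scale
  }
  label <- if (length(meta$channel_labels) >= channel_index) {
    meta$channel_labels[channel_index]
  } else ""
  voxel_image(arr, spacing = meta$spacing, channel_label = label)
}

#' Read all channels of a TIFF z-stack
#'
#' Convenience wrapper around [read_volume()] returning every channel as a
#' [multi_channel_image()].
#'
#' @inheritParams read_volume
#' @param cell_id identifier attached to the returned image (defaults to the
#'   sidecar's cell id, else the file name).
#' @return A [multi_channel_image()].
#' @export
read_multichannel <- function(path, spacing = NULL, cell_id = NULL) {
  if (!file.exists(path)) stop_input("file not found: '%s'", path)
  sidecar <- paste0(path, ".json")
  nc <- 1L
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    nc <- as.integer(meta$n_channels)
    cell_id <- cell_id %||% meta$cell_id
  }
  channels <- lapply(seq_len(nc), function(c) read_volume(path, c, spacing = spacing))
  multi_channel_image(channels, cell_id = cell_id %||% basename(path))
}

#' Write measurement records to CSV
#'
#' Columns appear in the order of the input; doubles are written with
#' shortest round-trippable precision so parsed values equal the originals.
#' An empty input produces a header-only file.
#'
#' @param rows a data frame / tibble of measurement records.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}
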