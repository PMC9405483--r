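# Calibrated multi-channel z-stack container and TIFF/PNG I/O.

STACK_CHANNELS <- c("NeuN", "GFAP", "IBA1")

#' Construct a calibrated multi-channel z-stack
#'
#' A `zstack` holds one 3D array per named channel (dimensions
#' `[y, x, layer]`, layer index = depth order), a physical calibration, and
#' provenance (source path and crop offset). All rasters are numeric in
#' `[0, 1]`. Pixel coordinates are 0-based with the origin at the top-left;
#' physical coordinates are in micrometres.
#'
#' @param channels Named list of 3D numeric arrays (`[y, x, layer]`) or 2D
#'   matrices (promoted to a single layer). Names usually `NeuN`, `GFAP`,
#'   `IBA1`.
#' @param calibration A [calibration()] object.
#' @param provenance Optional list (`source`, `crop_offset_px`).
#' @return An object of class `"zstack"`.
#' @export
zstack <- function(channels, calibration,
                   provenance = list(source = NA_character_,
                                     crop_offset_px = c(0L, 0L))) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), inherits(calibration, "calibration"))
  channels <- lapply(channels, function(a) {
    if (is.matrix(a)) a <- array(a, c(dim(a), 1L))
    stopifnot(is.array(a), length(dim(a)) == 3L)
    a
  })
  dims <- lapply(channels, dim)
  if (length(unique(dims)) != 1L) {
    stop("all channel rasters must have identical dimensions", call. = FALSE)
  }
  if (dims[[1]][3] < 1L) stop("a zstack needs at least one layer", call. = FALSE)
  structure(list(channels = channels, calibration = calibration,
                 provenance = provenance),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cal <- x$calibration
  cat(sprintf(
    "<zstack> %d x %d px, %d layer(s), channels: %s\n  %.3f x %.3f um/px, z step %g um (%.0f x %.0f um)\n",
    d[2], d[1], d[3], paste(names(x$channels), collapse = ", "),
    cal$um_per_px_x, cal$um_per_px_y, cal$z_step_um,
    d[2] * cal$um_per_px_x, d[1] * cal$um_per_px_y))
  invisible(x)
}

#' Number of z layers in a stack
#' @param stack A [zstack()].
#' @return Integer layer count.
#' @export
n_layers <- function(stack) dim(stack$channels[[1]])[3]

#' Physical ROI area of a stack in square millimetres
#' @param stack A [zstack()].
#' @return Area in mm^2.
#' @export
stack_area_mm2 <- function(stack) {
  d <- dim(stack$channels[[1]])
  cal <- stack$calibration
  (d[2] * cal$um_per_px_x) * (d[1] * cal$um_per_px_y) / 1e6
}

#' Rectangular region of interest in physical units
#'
#' Half-open convention: the rectangle covers `[x, x + width) x [y, y + height)`
#' micrometres.
#'
#' @param x_um,y_um Top-left corner in micrometres.
#' @param width_um,height_um Extent in micrometres; strictly positive.
#' @return A list of class `"roi_rect"`.
#' @export
roi_rect <- function(x_um, y_um, width_um, height_um) {
  if (width_um <= 0 || height_um <= 0) {
    stop("roi_rect extent must be strictly positive", call. = FALSE)
  }
  structure(list(x_um = x_um, y_um = y_um,
                 width_um = width_um, height_um = height_um),
            class = "roi_rect")
}

#' Crop a stack to a physical rectangle
#'
#' The rectangle is converted to pixel indices with the stack's calibration;
#' the crop offset is recorded in the provenance so nested crops compose in
#' pixel space. Physical size is preserved within one pixel per axis.
#'
#' @param stack A [zstack()].
#' @param rect A [roi_rect()], inside the stack bounds.
#' @return A cropped [zstack()].
#' @export
crop_roi <- function(stack, rect) {
  stopifnot(inherits(stack, "zstack"), inherits(rect, "roi_rect"))
  cal <- stack$calibration
  d <- dim(stack$channels[[1]])
  x0 <- um_to_px_x(rect$x_um, cal)
  y0 <- um_to_px_y(rect$y_um, cal)
  nx <- max(1L, as.integer(round(rect$width_um / cal$um_per_px_x)))
  ny <- max(1L, as.integer(round(rect$height_um / cal$um_per_px_y)))
  if (x0 < 0 || y0 < 0 || x0 + nx > d[2] || y0 + ny > d[1]) {
    stop("crop rectangle is out of the stack bounds", call. = FALSE)
  }
  channels <- lapply(stack$channels, function(a) {
    a[(y0 + 1L):(y0 + ny), (x0 + 1L):(x0 + nx), , drop = FALSE]
  })
  prov <- stack$provenance
  off <- prov$crop_offset_px %||% c(0L, 0L)
  prov$crop_offset_px <- c(off[1] + x0, off[2] + y0)
  zstack(channels, cal, prov)
}

#' Maximum-intensity projection of one channel
#' @param stack A [zstack()].
#' @param channel Channel name.
#' @return A numeric matrix `[y, x]`.
#' @export
max_projection <- function(stack, channel = "NeuN") {
  a <- stack$channels[[channel]]
  if (is.null(a)) stop("unknown channel: ", channel, call. = FALSE)
  apply(a, c(1, 2), max)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a stack as a multi-page TIFF with a JSON calibration sidecar
#'
#' Pages are channel-major (all layers of the first channel, then the next
#' channel) in the stored channel order; intensities are quantized to 16-bit.
#' The sidecar (`<path>.json`) records channel names, layer count, layout and
#' calibration so [read_stack()] can reconstruct the stack exactly.
#'
#' @param stack A [zstack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  pages <- list()
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    for (l in seq_len(dim(a)[3])) pages <- c(pages, list(quantize16(a[, , l])))
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(channels = names(stack$channels),
               n_layers = n_layers(stack),
               layout = "channel-major",
               calibration = unclass(stack$calibration))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibrated multi-channel z-stack from TIFF
#'
#' Accepts either a multi-page single-sample TIFF written by [write_stack()]
#' (layout and calibration from the JSON sidecar) or an RGB-composite TIFF
#' whose colour planes are split into channels via `channel_map`. Calibration
#' is taken from the sidecar when present, else from the `calibration`
#' argument; when both are absent the call fails rather than guessing.
#'
#' @param path TIFF path.
#' @param calibration Optional [calibration()] used when no sidecar exists.
#' @param channel_map Named character vector mapping channel name to an RGB
#'   plane (`"R"`, `"G"`, `"B"`) for composite input. The default follows the
#'   common pseudocolouring: green carries NeuN, cyan (stored in the blue
#'   plane) GFAP, red IBA1.
#' @param channels Channel names for multi-page input without a sidecar.
#' @return A [zstack()].
#' @export
read_stack <- function(path, calibration = NULL,
                       channel_map = c(NeuN = "G", GFAP = "B", IBA1 = "R"),
                       channels = STACK_CHANNELS) {
  sc <- sidecar_path(path)
  meta <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else NULL
  cal <- if (!is.null(meta)) {
    do.call(calibration_from_list, list(meta$calibration))
  } else if (!is.null(calibration)) {
    calibration
  } else {
    stop("no calibration: neither an embedded sidecar (", sc,
         ") nor a `calibration` argument was supplied", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) == 1L && length(dim(pages[[1]])) == 3L) {
    # RGB composite: split planes per the configured mapping
    rgb <- pages[[1]]
    if (dim(rgb)[3] < 3L) stop("composite input must have 3 colour planes",
                               call. = FALSE)
    plane <- c(R = 1L, G = 2L, B = 3L)
    chs <- lapply(channel_map, function(p) rgb[, , plane[[p]]])
    names(chs) <- names(channel_map)
    return(zstack(chs, cal, list(source = path, crop_offset_px = c(0L, 0L))))
  }
  if (any(vapply(pages, function(p) length(dim(p)) == 3L, logical(1)))) {
    stop("mixed multi-sample pages are not supported", call. = FALSE)
  }
  ch_names <- if (!is.null(meta)) meta$channels else channels
  nl <- if (!is.null(meta)) meta$n_layers else {
    if (length(pages) %% length(ch_names) != 0L) {
      stop("page count ", length(pages), " is not a multiple of the ",
           length(ch_names), " channels; supply a channel mapping",
           call. = FALSE)
    }
    length(pages) %/% length(ch_names)
  }
  if (length(pages) != nl * length(ch_names)) {
    stop("channel/layer count mismatch: ", length(pages), " pages for ",
         length(ch_names), " channels x ", nl, " layers", call. = FALSE)
  }
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L) stop("ragged layer dimensions", call. = FALSE)
  chs <- list()
  i <- 0L
  for (ch in ch_names) {
    a <- array(0, c(dims[[1]], nl))
    for (l in seq_len(nl)) {
      i <- i + 1L
      a[, , l] <- pages[[i]]
    }
    chs[[ch]] <- a
  }
  zstack(chs, cal, list(source = path, crop_offset_px = c(0L, 0L)))
}

calibration_from_list <- function(x) {
  calibration(x$um_per_px_x, x$um_per_px_y, x$z_step_um)
}

#' Merge three channels into an RGB composite array
#'
#' Inverse of the composite split in [read_stack()]: each channel's maximum
#' projection (or single layer) is written into its mapped RGB plane.
#'
#' @param stack A [zstack()] with a single layer per channel.
#' @param channel_map As in [read_stack()].
#' @return A `[y, x, 3]` array.
#' @export
merge_composite <- function(stack, channel_map = c(NeuN = "G", GFAP = "B",
                                                   IBA1 = "R")) {
  d <- dim(stack$channels[[1]])
  rgb <- array(0, c(d[1], d[2], 3L))
  plane <- c(R = 1L, G = 2L, B = 3L)
  for (ch in names(channel_map)) {
    rgb[, , plane[[channel_map[[ch]]]]] <- max_projection(stack, ch)
  }
  rgb
}

#' Burn detection contours into a projection and write a QC overlay
#'
#' Renders the maximum-intensity projection of the three channels as an RGB
#' image and recolours the supplied contour pixels, enabling visual
#' inspection of the detected structures.
#'
#' @param stack A [zstack()].
#' @param contours List of integer matrices (`[row, col]`, 1-based pixel
#'   coordinates of this stack) — e.g. blob boundary pixels from
#'   [run_detector()] results.
#' @param path Output PNG path.
#' @param colour Overlay colour, RGB in `[0, 1]`.
#' @return The RGB array, invisibly.
#' @export
write_overlay <- function(stack, contours, path,
                          colour = c(1, 1, 0)) {
  default_map <- c(NeuN = "G", GFAP = "B", IBA1 = "R")
  known <- intersect(names(stack$channels), names(default_map))
  d2 <- dim(stack$channels[[1]])
  rgb <- array(0, c(d2[1], d2[2], 3L))
  plane <- c(R = 1L, G = 2L, B = 3L)
  if (length(known)) {
    for (ch in known) rgb[, , plane[[default_map[[ch]]]]] <-
        max_projection(stack, ch)
  } else {
    mp <- max_projection(stack, names(stack$channels)[1])
    for (p in 1:3) rgb[, , p] <- mp
  }
  d <- dim(rgb)
  for (ct in contours) {
    if (is.null(ct) || nrow(ct) == 0L) next
    if (any(ct[, 1] < 1L | ct[, 1] > d[1] | ct[, 2] < 1L | ct[, 2] > d[2])) {
      stop("contour outside the raster", call. = FALSE)
    }
    for (p in 1:3) rgb[cbind(ct[, 1], ct[, 2], p)] <- colour[p]
  }
  png::writePNG(rgb, path)
  invisible(rgb)
}
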