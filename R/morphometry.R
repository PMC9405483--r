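# Per-ROI quantification: densities in cells/mm^2, pyramidal-layer
# thickness on the maximum-intensity projection, and tile bookkeeping.

#' Object density per square millimetre
#'
#' @param count Non-negative object count.
#' @param area_mm2 ROI area in mm^2, strictly positive.
#' @return `count / area_mm2`, exact.
#' @export
density_per_mm2 <- function(count, area_mm2) {
  if (any(count < 0)) stop("count must be >= 0", call. = FALSE)
  if (any(area_mm2 <= 0)) stop("ROI area must be > 0", call. = FALSE)
  count / area_mm2
}

#' Pyramidal-layer thickness from a NeuN projection
#'
#' The projection is binarized with a global Otsu threshold (the band is the
#' dominant bright structure; an adaptive local-mean threshold would hollow
#' regions wider than its block and is deliberately not used here). The
#' column-wise foreground profile is smoothed along y with a small Gaussian;
#' in each column the band extent is the longest contiguous run above
#' `frac` of that column's peak, converted to micrometres with the y
#' calibration. Columns with no band are excluded and their fraction
#' reported; when more than half the columns lack a band the result is
#' flagged and the mean thickness undefined.
#'
#' @param x A [zstack()] (its NeuN channel is projected) or a numeric
#'   matrix (a projection).
#' @param cal A [calibration()]; taken from the stack when `x` is one.
#' @param frac Fraction of the per-column peak defining the band run.
#' @param smooth_sigma_px Gaussian sigma (pixels) for the profile smoothing.
#' @param angle_deg Optional rotation applied before measuring, for bands
#'   that are not roughly horizontal.
#' @param min_peak Minimum smoothed peak for a column to count as banded.
#' @param min_contrast Minimum separation between the median foreground and
#'   median background intensity at the Otsu split for the image to count as
#'   containing a band at all (a signal-free raster would otherwise be split
#'   mid-noise).
#' @return A list of class `"thickness_result"`: `mean_um`, `sd_um`,
#'   `n_columns`, `coverage` (fraction of banded columns), `flagged`, and a
#'   `profile` tibble (`x_um`, `thickness_um`).
#' @export
pyramidal_thickness <- function(x, cal = NULL, frac = 0.5,
                                smooth_sigma_px = 2, angle_deg = 0,
                                min_peak = 0.2, min_contrast = 0.1) {
  if (inherits(x, "zstack")) {
    cal <- x$calibration
    proj <- max_projection(x, "NeuN")
  } else {
    proj <- x
    if (is.null(cal)) stop("supply a calibration with a raw projection",
                           call. = FALSE)
  }
  if (angle_deg != 0) {
    proj <- EBImage::rotate(proj, -angle_deg, bg.col = min(proj))
    proj <- matrix(as.numeric(proj), nrow(proj), ncol(proj))
  }
  thr <- otsu_threshold(proj)
  fg <- proj > thr
  no_signal <- !any(fg) || all(fg) ||
    (stats::median(proj[fg]) - stats::median(proj[!fg])) < min_contrast
  mask <- if (no_signal) matrix(0, nrow(proj), ncol(proj)) else fg * 1
  kern <- matrix(gauss_kernel_1d(smooth_sigma_px), ncol = 1)
  sm <- convolve_replicate(mask, kern)
  nc <- ncol(sm)
  th_px <- rep(NA_real_, nc)
  for (j in seq_len(nc)) {
    col <- sm[, j]
    pk <- max(col)
    if (pk < min_peak) next
    above <- col >= frac * pk
    r <- rle(above)
    runs <- r$lengths[r$values]
    th_px[j] <- max(runs)
  }
  valid <- !is.na(th_px)
  coverage <- mean(valid)
  flagged <- coverage < 0.5
  profile <- tibble::tibble(
    x_um = (seq_len(nc) - 0.5) * cal$um_per_px_x,
    thickness_um = th_px * cal$um_per_px_y)
  structure(list(
    mean_um = if (flagged) NA_real_ else mean(profile$thickness_um[valid]),
    sd_um = if (flagged) NA_real_ else stats::sd(profile$thickness_um[valid]),
    n_columns = sum(valid),
    coverage = coverage,
    flagged = flagged,
    profile = profile), class = "thickness_result")
}

#' @export
print.thickness_result <- function(x, ...) {
  if (x$flagged) {
    cat(sprintf("<thickness_result> flagged: band found in only %.0f%% of columns\n",
                100 * x$coverage))
  } else {
    cat(sprintf("<thickness_result> mean %.2f um (sd %.2f) over %d columns (coverage %.0f%%)\n",
                x$mean_um, x$sd_um, x$n_columns, 100 * x$coverage))
  }
  invisible(x)
}

#' Mean band thickness from a hand-drawn polygon
#'
#' Entry point for manually delimited bands: the mean vertical extent of the
#' polygon over its horizontal span (shoelace area divided by width), in
#' micrometres.
#'
#' @param polygon Numeric matrix of vertices (`x_um`, `y_um`), in order.
#' @return Mean thickness in micrometres.
#' @export
thickness_from_polygon <- function(polygon) {
  stopifnot(is.matrix(polygon), ncol(polygon) == 2, nrow(polygon) >= 3)
  x <- polygon[, 1]; y <- polygon[, 2]
  n <- nrow(polygon)
  j <- c(2:n, 1)
  area <- abs(sum(x * y[j] - x[j] * y)) / 2
  width <- diff(range(x))
  if (width <= 0) stop("degenerate polygon", call. = FALSE)
  area / width
}

#' Quantify a full ROI stack
#'
#' Runs the detector on each channel (NeuN with debris via GFAP; GFAP and
#' IBA1 for astrocyte and microglia counts), measures the pyramidal-layer
#' thickness when requested, and reports counts and densities in
#' objects/mm^2. `density * area_mm2 = count` holds exactly.
#'
#' @param stack A calibrated [zstack()] with NeuN, GFAP, IBA1 channels.
#' @param params A [detection_params()].
#' @param roi_id,region Identifiers echoed into the result.
#' @param measure_thickness Also run [pyramidal_thickness()].
#' @return A one-row tibble: identifiers, `area_mm2`, per-class counts and
#'   densities, thickness columns (NA when not measured or flagged).
#' @export
quantify_roi <- function(stack, params = detection_params(),
                         roi_id = NA_character_, region = NA_character_,
                         measure_thickness = FALSE) {
  area <- stack_area_mm2(stack)
  neun <- run_detector(stack, "NeuN", params)
  gfap <- run_detector(stack, "GFAP", params, gfap_from = NULL)
  iba1 <- run_detector(stack, "IBA1", params, gfap_from = NULL)
  th <- if (measure_thickness) pyramidal_thickness(stack) else NULL
  tibble::tibble(
    roi_id = roi_id, region = region, area_mm2 = area,
    n_neurons = neun$n_cells, n_astrocytes = gfap$n_cells,
    n_microglia = iba1$n_cells, n_debris = neun$n_debris,
    neuron_density_mm2 = density_per_mm2(neun$n_cells, area),
    astrocyte_density_mm2 = density_per_mm2(gfap$n_cells, area),
    microglia_density_mm2 = density_per_mm2(iba1$n_cells, area),
    debris_density_mm2 = density_per_mm2(neun$n_debris, area),
    thickness_um = if (is.null(th)) NA_real_ else th$mean_um,
    thickness_sd_um = if (is.null(th)) NA_real_ else th$sd_um,
    thickness_flagged = if (is.null(th)) NA else th$flagged)
}

#' Assign object centroids to ROI tiles
#'
#' Splits the ROI into an `nx` by `ny` grid and assigns each object to the
#' tile containing its centroid (half-open tiles, so counts over disjoint
#' tiles sum exactly to the whole-ROI count).
#'
#' @param objects Tibble with `centroid_x_um` / `centroid_y_um` (or
#'   `x_um` / `y_um`) columns.
#' @param roi_width_um,roi_height_um ROI extent.
#' @param nx,ny Grid size.
#' @return `objects` with `tile_x`, `tile_y`, `tile` columns.
#' @export
assign_tiles <- function(objects, roi_width_um, roi_height_um,
                         nx = 2, ny = 2) {
  x <- if ("centroid_x_um" %in% names(objects)) objects$centroid_x_um else objects$x_um
  y <- if ("centroid_y_um" %in% names(objects)) objects$centroid_y_um else objects$y_um
  tx <- pmin(floor(x / (roi_width_um / nx)), nx - 1)
  ty <- pmin(floor(y / (roi_height_um / ny)), ny - 1)
  dplyr::mutate(objects, tile_x = tx, tile_y = ty,
                tile = ty * nx + tx + 1)
}
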