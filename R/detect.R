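# Per-layer segmentation and blob measurement: Gaussian preprocessing,
# local-mean adaptive thresholding, morphological refinement, 8-connected
# component extraction with Feret (longest-diagonal) measurement.

#' Detection parameters
#'
#' Every tunable of the layered cell-counting algorithm. The biologically
#' anchored rules are fixed by the assay definition: a linked element is a
#' cell when consecutive-layer blobs overlap by at least 60% of the smaller
#' area and the longest (Feret) diagonal strictly exceeds 6.5 um; neuronal
#' debris are NeuN fragments between 2.5 and 6.5 um (closed interval)
#' encircled by astrocyte signal. The remaining knobs (blur sigma, threshold
#' block and offset, morphology radius, ring geometry) are calibration
#' choices surfaced here and echoed in every result.
#'
#' @param blur_sigma_um Gaussian smoothing sigma (um), converted to pixels
#'   per axis.
#' @param thresh_block_um Adaptive-threshold neighbourhood size (um); the
#'   local reference is the mean over this block, converted to an odd pixel
#'   count of at least 3 per axis.
#' @param thresh_offset Constant added to the local mean, on the 0-255
#'   intensity scale (rasters are `[0,1]` floats; the offset is divided by
#'   255 internally). A pixel is foreground iff it exceeds local mean +
#'   offset, so a constant raster yields an empty mask.
#' @param morph_radius_um Disc structuring-element radius for the
#'   opening-then-closing refinement.
#' @param min_overlap_frac Minimum consecutive-layer overlap, as a fraction
#'   of the smaller blob area.
#' @param min_cell_diag_um Feret diagonal a cell must strictly exceed.
#' @param debris_diag_um Closed Feret interval for debris candidates; its
#'   upper bound must equal `min_cell_diag_um`.
#' @param encircle_frac Minimum fraction of a debris fragment's surrounding
#'   ring covered by astrocyte mask.
#' @param ring_width_um Width of that ring (blob dilated by this much, blob
#'   subtracted).
#' @param min_layer_support Minimum layer span of a cell track (>= 2: the
#'   overlap rule needs at least one linked pair).
#' @param exclude_border Drop blobs touching the raster border (edge photon
#'   scatter is excluded from analysis).
#' @param apply_morphology Apply the opening/closing refinement (kept
#'   configurable; on by default).
#' @return A validated list of class `"detection_params"`.
#' @export
detection_params <- function(blur_sigma_um = 0.5,
                             thresh_block_um = 30,
                             thresh_offset = 70,
                             morph_radius_um = 0.5,
                             min_overlap_frac = 0.60,
                             min_cell_diag_um = 6.5,
                             debris_diag_um = c(2.5, 6.5),
                             encircle_frac = 0.5,
                             ring_width_um = 1.0,
                             min_layer_support = 2,
                             exclude_border = TRUE,
                             apply_morphology = TRUE) {
  if (blur_sigma_um <= 0) stop("blur sigma must be > 0", call. = FALSE)
  if (min_overlap_frac <= 0 || min_overlap_frac > 1) {
    stop("min_overlap_frac must be in (0, 1]", call. = FALSE)
  }
  if (length(debris_diag_um) != 2 || debris_diag_um[1] <= 0 ||
      debris_diag_um[1] >= debris_diag_um[2]) {
    stop("debris_diag_um must be an increasing positive interval", call. = FALSE)
  }
  if (!isTRUE(all.equal(debris_diag_um[2], min_cell_diag_um))) {
    stop("debris upper bound must equal min_cell_diag_um", call. = FALSE)
  }
  if (min_layer_support < 2) stop("min_layer_support must be >= 2", call. = FALSE)
  if (thresh_block_um <= 0 || morph_radius_um <= 0 || ring_width_um <= 0 ||
      min_cell_diag_um <= 0) {
    stop("physical sizes must be > 0", call. = FALSE)
  }
  structure(list(blur_sigma_um = blur_sigma_um,
                 thresh_block_um = thresh_block_um,
                 thresh_offset = thresh_offset,
                 morph_radius_um = morph_radius_um,
                 min_overlap_frac = min_overlap_frac,
                 min_cell_diag_um = min_cell_diag_um,
                 debris_diag_um = debris_diag_um,
                 encircle_frac = encircle_frac,
                 ring_width_um = ring_width_um,
                 min_layer_support = as.integer(min_layer_support),
                 exclude_border = isTRUE(exclude_border),
                 apply_morphology = isTRUE(apply_morphology)),
            class = "detection_params")
}

#' Gaussian preprocessing of a single layer
#'
#' Smooths background noise with a normalized separable Gaussian kernel;
#' sigma is specified in micrometres and converted to pixels per axis, so
#' anisotropic calibrations blur isotropically in physical space. Replicated
#' borders keep constants exactly constant and conserve total intensity up
#' to the filter normalization.
#'
#' @param raster Single-channel numeric matrix `[y, x]`.
#' @param cal A [calibration()].
#' @param params A [detection_params()].
#' @return Smoothed matrix of identical dimensions.
#' @export
preprocess_layer <- function(raster, cal, params = detection_params()) {
  if (params$blur_sigma_um <= 0) stop("non-positive sigma", call. = FALSE)
  k <- gauss_kernel_2d(params$blur_sigma_um / cal$um_per_px_y,
                       params$blur_sigma_um / cal$um_per_px_x)
  convolve_replicate(raster, k)
}

#' Local-mean adaptive thresholding
#'
#' A pixel is foreground iff its intensity exceeds the mean of its
#' `thresh_block_um` neighbourhood plus `thresh_offset` (0-255 scale). The
#' block converts to an odd pixel count per axis; fewer than 3 px is an
#' error. Robust to smooth background gradients that defeat any global
#' threshold.
#'
#' @inheritParams preprocess_layer
#' @return A 0/1 numeric matrix.
#' @export
threshold_layer <- function(raster, cal, params = detection_params()) {
  clamp_odd <- function(n, maxn) {
    m <- min(n, maxn)
    if (m %% 2 == 0) m <- m - 1L
    max(m, 3L)
  }
  bx <- clamp_odd(odd_block_px(params$thresh_block_um, cal$um_per_px_x),
                  ncol(raster))
  by <- clamp_odd(odd_block_px(params$thresh_block_um, cal$um_per_px_y),
                  nrow(raster))
  box <- matrix(1 / (bx * by), by, bx)
  local_mean <- convolve_replicate(raster, box)
  (raster > local_mean + params$thresh_offset / 255) * 1
}

#' Morphological refinement of a binary mask
#'
#' Opening (erode-dilate) then closing (dilate-erode) with a disc
#' structuring element of `morph_radius_um` (isotropic in pixels, radius
#' converted with the mean pixel pitch). The open-close alternating filter
#' is idempotent: re-application changes nothing.
#'
#' @param mask Binary (0/1) matrix.
#' @inheritParams preprocess_layer
#' @return Refined 0/1 matrix.
#' @export
refine_mask <- function(mask, cal, params = detection_params()) {
  if (!params$apply_morphology) return(mask)
  r_px <- params$morph_radius_um * 2 / (cal$um_per_px_x + cal$um_per_px_y)
  brush <- disc_brush(r_px)
  m <- EBImage::opening(mask, brush)
  m <- EBImage::closing(m, brush)
  matrix(as.numeric(m > 0), nrow(mask), ncol(mask))
}

#' Extract measured blobs from a refined mask
#'
#' 8-connected components are labelled and measured: area is pixel count
#' times physical pixel area; the Feret (longest) diagonal is the maximum
#' pairwise distance over the boundary-pixel corner points with per-axis
#' micrometre scaling; the centroid is the mean member-pixel centre. Blobs
#' touching the raster border are flagged and, when `exclude_border`,
#' dropped (edge photon scatter is excluded from analysis).
#'
#' @param mask Binary (0/1) matrix.
#' @param cal A [calibration()].
#' @param exclude_border Drop border-touching blobs.
#' @return A list: `blobs` (tibble with `label`, `n_px`, `area_um2`,
#'   `feret_um`, `centroid_x_um`, `centroid_y_um`, `touches_border`,
#'   `contour` list-column of boundary pixels) and `labels` (the labelled
#'   matrix, with excluded labels zeroed).
#' @export
extract_blobs <- function(mask, cal, exclude_border = TRUE) {
  lab <- label_components(mask)
  k <- max(lab)
  rows <- vector("list", k)
  keep_lab <- lab
  nr <- nrow(lab); nc <- ncol(lab)
  if (k > 0) {
    px_area <- cal$um_per_px_x * cal$um_per_px_y
    idx <- which(lab > 0, arr.ind = TRUE)
    ids <- lab[lab > 0]
    for (id in seq_len(k)) {
      sel <- ids == id
      py <- idx[sel, 1]; px <- idx[sel, 2]
      touches <- any(py == 1L | py == nr | px == 1L | px == nc)
      if (touches && exclude_border) {
        keep_lab[cbind(py, px)] <- 0L
        next
      }
      y0 <- min(py); y1 <- max(py); x0 <- min(px); x1 <- max(px)
      sub <- lab[y0:y1, x0:x1, drop = FALSE] == id
      bpx <- boundary_pixels(sub)
      bpx[, 1] <- bpx[, 1] + y0 - 1L
      bpx[, 2] <- bpx[, 2] + x0 - 1L
      rows[[id]] <- tibble::tibble(
        label = id,
        n_px = length(py),
        area_um2 = length(py) * px_area,
        feret_um = feret_from_boundary(bpx, cal),
        centroid_x_um = mean((px - 0.5) * cal$um_per_px_x),
        centroid_y_um = mean((py - 0.5) * cal$um_per_px_y),
        touches_border = touches,
        contour = list(bpx))
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  blobs <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(label = integer(), n_px = integer(), area_um2 = numeric(),
                   feret_um = numeric(), centroid_x_um = numeric(),
                   centroid_y_um = numeric(), touches_border = logical(),
                   contour = list())
  list(blobs = blobs, labels = keep_lab)
}

segment_layer <- function(raster, cal, params) {
  sm <- preprocess_layer(raster, cal, params)
  mk <- threshold_layer(sm, cal, params)
  refine_mask(mk, cal, params)
}

#' Segment every layer of one channel
#'
#' Composition of [preprocess_layer()], [threshold_layer()], [refine_mask()]
#' and [extract_blobs()] applied to each z layer.
#'
#' @param stack A [zstack()].
#' @param channel Channel name.
#' @param params A [detection_params()].
#' @return A list with one [extract_blobs()] result per layer.
#' @export
segment_channel <- function(stack, channel, params = detection_params()) {
  a <- stack$channels[[channel]]
  if (is.null(a)) stop("unknown channel: ", channel, call. = FALSE)
  cal <- stack$calibration
  lapply(seq_len(dim(a)[3]), function(l) {
    extract_blobs(segment_layer(a[, , l], cal, params), cal,
                  params$exclude_border)
  })
}
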