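# Internal helpers shared across modules.
#
# Raster convention: a layer is a numeric matrix indexed [row, col] with
# row = y (top-left origin) and col = x.  Pixel coordinates are 0-based and
# half-open; the centre of pixel (i, j) (1-based R indices) sits at physical
# position ((j - 0.5) * um_per_px_x, (i - 0.5) * um_per_px_y).

#' Build a calibration record
#'
#' @param um_per_px_x,um_per_px_y Physical pixel pitch in micrometres per
#'   pixel along x (columns) and y (rows). Must be strictly positive.
#' @param z_step_um Axial distance between consecutive z layers in
#'   micrometres.
#' @return A list of class `"calibration"`.
#' @export
calibration <- function(um_per_px_x, um_per_px_y = um_per_px_x,
                        z_step_um = 5) {
  stopifnot(is.numeric(um_per_px_x), is.numeric(um_per_px_y),
            is.numeric(z_step_um))
  if (um_per_px_x <= 0 || um_per_px_y <= 0 || z_step_um <= 0) {
    stop("calibration values must be strictly positive", call. = FALSE)
  }
  structure(list(um_per_px_x = as.numeric(um_per_px_x),
                 um_per_px_y = as.numeric(um_per_px_y),
                 z_step_um = as.numeric(z_step_um)),
            class = "calibration")
}

# micrometre -> pixel index conversions (0-based px offsets)
um_to_px_x <- function(x_um, cal) floor(x_um / cal$um_per_px_x + 1e-9)
um_to_px_y <- function(y_um, cal) floor(y_um / cal$um_per_px_y + 1e-9)

px_centers_x <- function(ncol, cal) (seq_len(ncol) - 0.5) * cal$um_per_px_x
px_centers_y <- function(nrow, cal) (seq_len(nrow) - 0.5) * cal$um_per_px_y

# Odd pixel count >= 3 for a physical block size; errors when the converted
# block is below 3 px (the caller's neighbourhood would be degenerate).
odd_block_px <- function(size_um, um_per_px) {
  n <- round(size_um / um_per_px)
  if (n < 3) {
    stop("adaptive-threshold block converts to fewer than 3 px (",
         n, " px); increase the block size or the resolution", call. = FALSE)
  }
  if (n %% 2 == 0) n <- n + 1
  as.integer(n)
}

# 1D normalized Gaussian kernel (radius 3 sigma, at least 1 px)
gauss_kernel_1d <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = max(sigma_px, 1e-6))
  k / sum(k)
}

# Separable 2D kernel from per-axis sigmas, as a [y, x] matrix.
gauss_kernel_2d <- function(sigma_y_px, sigma_x_px) {
  outer(gauss_kernel_1d(sigma_y_px), gauss_kernel_1d(sigma_x_px))
}

# Convolution with replicated borders (EBImage does the heavy lifting).
convolve_replicate <- function(m, kernel) {
  EBImage::filter2(m, kernel, boundary = "replicate")
}

# 8-connected labelling.  EBImage::bwlabel is 4-connected; diagonal
# adjacencies between distinct labels are merged with a small union-find.
label_components <- function(mask) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  k <- max(lab)
  if (k < 2L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                   pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(k), find, integer(1))
  dense <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- dense[lab[lab > 0]]
  out
}

# Binary disc brush of the given pixel radius (odd size, isotropic in px).
disc_brush <- function(radius_px) {
  r <- max(1L, as.integer(round(radius_px)))
  EBImage::makeBrush(2L * r + 1L, shape = "disc")
}

# Boundary pixels of a component given as a logical matrix: any member
# pixel with a 4-neighbour outside the component (or on the raster border).
boundary_pixels <- function(inside) {
  nr <- nrow(inside); nc <- ncol(inside)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- inside
  nb <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  which(inside & !nb, arr.ind = TRUE)
}

# Feret (longest) diagonal of a pixel set in micrometres: the maximum
# caliper over the corner points of the boundary pixels, reduced through the
# convex hull.  Per-axis scaling keeps anisotropic calibrations honest.
feret_from_boundary <- function(bpx, cal) {
  y <- bpx[, 1]; x <- bpx[, 2]
  xs <- c(x - 1, x, x - 1, x) * cal$um_per_px_x
  ys <- c(y - 1, y - 1, y, y) * cal$um_per_px_y
  pts <- unique(cbind(xs, ys))
  if (nrow(pts) < 2L) return(0)
  h <- grDevices::chull(pts)
  pts <- pts[h, , drop = FALSE]
  d2 <- 0
  n <- nrow(pts)
  for (i in seq_len(n - 1L)) {
    dx <- pts[(i + 1L):n, 1] - pts[i, 1]
    dy <- pts[(i + 1L):n, 2] - pts[i, 2]
    d2 <- max(d2, max(dx * dx + dy * dy))
  }
  sqrt(d2)
}

# Otsu threshold on a [0,1] raster (256-bin histogram).
otsu_threshold <- function(m) {
  EBImage::otsu(EBImage::Image(m), range = c(0, 1), levels = 256)
}

# Quantize a [0,1] raster to the 16-bit grid used by the TIFF writer, so a
# written stack round-trips bit-identically.
quantize16 <- function(m) {
  round(pmin(pmax(m, 0), 1) * 65535) / 65535
}

`%||%` <- function(a, b) if (is.null(a)) b else a
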