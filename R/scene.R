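# Synthetic three-channel z-stack generator with exported ground truth.
#
# The generator emulates the imaging substrate the detector was designed
# for: disk-like NeuN somata (spheres sampled by the z planes), filamentous
# GFAP astrocyte arbors, small IBA1 microglial somata with thin processes,
# sub-somatic NeuN fragments ("debris") ring-painted with GFAP signal, an
# optional dense pyramidal band, a planar background gradient, and additive
# Gaussian noise.  Ground truth records every object before noise.

#' Pyramidal-band geometry for synthetic scenes
#'
#' @param center_frac Vertical position of the band centreline as a fraction
#'   of the ROI height.
#' @param thickness_um Band thickness in micrometres.
#' @param angle_deg Rotation of the band centreline from horizontal.
#' @param intensity Fill intensity of the band somata.
#' @return A list of class `"band_spec"`.
#' @export
band_spec <- function(center_frac = 0.5, thickness_um = 60, angle_deg = 0,
                      intensity = 0.55) {
  stopifnot(center_frac > 0, center_frac < 1, thickness_um > 0)
  structure(list(center_frac = center_frac, thickness_um = thickness_um,
                 angle_deg = angle_deg, intensity = intensity),
            class = "band_spec")
}

#' Specification of a synthetic scene
#'
#' Defaults follow the acquisition conventions of the target assay: a
#' 600 x 400 um ROI rastered at 1024 x 1024 px (hence anisotropic pixel
#' calibration), three z layers 5 um apart, 25 neuronal somata of 8-15 um,
#' and 15 neuronal-debris fragments of 2.5-6.5 um each encircled by
#' astrocyte signal.  The band is off by default: cell-recovery scenes are
#' band-free because touching band somata are deliberately not split by the
#' detector; use [band_spec()] for thickness studies.
#'
#' @param roi_width_um,roi_height_um Physical ROI extent.
#' @param px_per_um_x,px_per_um_y Raster resolution per axis.
#' @param n_layers Number of z planes.
#' @param z_step_um Axial spacing between planes.
#' @param n_neurons,n_astrocytes,n_microglia,n_debris,n_decoys Object counts
#'   (decoys are NeuN fragments without a GFAP ring).
#' @param soma_diameter_um Length-2 sampling range for neuronal somata.
#' @param debris_diameter_um Length-2 sampling range for debris fragments;
#'   its upper bound must not exceed the smallest soma diameter.
#' @param band A [band_spec()] or `NULL` (no band).
#' @param background Length-2 numeric: flat offset and planar gradient
#'   amplitude (the gradient defeats any global threshold).
#' @param noise_sd Additive zero-mean Gaussian noise scale.
#' @param contrast Peak object intensity above background.
#' @param ring_coverage Fraction of each debris fragment's surrounding
#'   annulus painted with GFAP signal.
#' @param seed Integer seed; identical seed and spec give bit-identical
#'   output.
#' @return A validated list of class `"scene_spec"`.
#' @export
scene_spec <- function(roi_width_um = 600, roi_height_um = 400,
                       px_per_um_x = 1024 / 600, px_per_um_y = 1024 / 400,
                       n_layers = 3, z_step_um = 5,
                       n_neurons = 25, soma_diameter_um = c(8, 15),
                       n_astrocytes = 10, n_microglia = 12,
                       n_debris = 15, debris_diameter_um = c(2.5, 6.5),
                       n_decoys = 0,
                       band = NULL,
                       background = c(offset = 0.10, gradient = 0.08),
                       noise_sd = 0.03, contrast = 0.45,
                       ring_coverage = 0.8,
                       seed = 1L) {
  counts <- c(n_neurons, n_astrocytes, n_microglia, n_debris, n_decoys)
  if (any(counts < 0)) stop("object counts must be >= 0", call. = FALSE)
  if (roi_width_um <= 0 || roi_height_um <= 0 || px_per_um_x <= 0 ||
      px_per_um_y <= 0 || z_step_um <= 0) {
    stop("physical sizes and resolutions must be > 0", call. = FALSE)
  }
  if (n_layers < 1) stop("need at least one layer", call. = FALSE)
  stopifnot(length(soma_diameter_um) == 2, length(debris_diameter_um) == 2)
  if (debris_diameter_um[2] > soma_diameter_um[1]) {
    stop("debris upper bound must not exceed the smallest soma diameter",
         call. = FALSE)
  }
  if (!is.null(band)) stopifnot(inherits(band, "band_spec"))
  structure(list(roi_width_um = roi_width_um, roi_height_um = roi_height_um,
                 px_per_um_x = px_per_um_x, px_per_um_y = px_per_um_y,
                 n_layers = as.integer(n_layers), z_step_um = z_step_um,
                 n_neurons = as.integer(n_neurons),
                 soma_diameter_um = soma_diameter_um,
                 n_astrocytes = as.integer(n_astrocytes),
                 n_microglia = as.integer(n_microglia),
                 n_debris = as.integer(n_debris),
                 debris_diameter_um = debris_diameter_um,
                 n_decoys = as.integer(n_decoys),
                 band = band, background = background,
                 noise_sd = noise_sd, contrast = contrast,
                 ring_coverage = ring_coverage, seed = as.integer(seed)),
            class = "scene_spec")
}

scene_calibration <- function(spec) {
  calibration(1 / spec$px_per_um_x, 1 / spec$px_per_um_y, spec$z_step_um)
}

scene_dims <- function(spec) {
  c(ny = as.integer(round(spec$roi_height_um * spec$px_per_um_y)),
    nx = as.integer(round(spec$roi_width_um * spec$px_per_um_x)))
}

# --- rasterisation primitives (physical coordinates, [y, x] matrices) -----

paint_disk <- function(m, cal, cx, cy, r, amp) {
  j0 <- max(1L, ceiling((cx - r) / cal$um_per_px_x))
  j1 <- min(ncol(m), ceiling((cx + r) / cal$um_per_px_x))
  i0 <- max(1L, ceiling((cy - r) / cal$um_per_px_y))
  i1 <- min(nrow(m), ceiling((cy + r) / cal$um_per_px_y))
  if (j0 > j1 || i0 > i1) return(m)
  xs <- (j0:j1 - 0.5) * cal$um_per_px_x
  ys <- (i0:i1 - 0.5) * cal$um_per_px_y
  dx2 <- outer(rep(1, length(ys)), (xs - cx)^2)
  dy2 <- outer((ys - cy)^2, rep(1, length(xs)))
  sub <- m[i0:i1, j0:j1, drop = FALSE]
  hit <- dx2 + dy2 <= r^2
  sub[hit] <- pmax(sub[hit], amp)
  m[i0:i1, j0:j1] <- sub
  m
}

paint_segment <- function(m, cal, x0, y0, x1, y1, width, amp) {
  r <- width / 2
  j0 <- max(1L, ceiling((min(x0, x1) - r) / cal$um_per_px_x))
  j1 <- min(ncol(m), ceiling((max(x0, x1) + r) / cal$um_per_px_x))
  i0 <- max(1L, ceiling((min(y0, y1) - r) / cal$um_per_px_y))
  i1 <- min(nrow(m), ceiling((max(y0, y1) + r) / cal$um_per_px_y))
  if (j0 > j1 || i0 > i1) return(m)
  xs <- (j0:j1 - 0.5) * cal$um_per_px_x
  ys <- (i0:i1 - 0.5) * cal$um_per_px_y
  px <- outer(rep(1, length(ys)), xs)
  py <- outer(ys, rep(1, length(xs)))
  vx <- x1 - x0; vy <- y1 - y0
  len2 <- vx * vx + vy * vy
  t <- if (len2 > 0) pmin(pmax(((px - x0) * vx + (py - y0) * vy) / len2, 0), 1) else 0
  d2 <- (px - (x0 + t * vx))^2 + (py - (y0 + t * vy))^2
  sub <- m[i0:i1, j0:j1, drop = FALSE]
  hit <- d2 <= r^2
  sub[hit] <- pmax(sub[hit], amp)
  m[i0:i1, j0:j1] <- sub
  m
}

# partial annulus: arcs covering `coverage` of the ring, randomized gaps
paint_ring <- function(m, cal, cx, cy, r_in, r_out, amp, coverage) {
  if (coverage <= 0) return(m)
  j0 <- max(1L, ceiling((cx - r_out) / cal$um_per_px_x))
  j1 <- min(ncol(m), ceiling((cx + r_out) / cal$um_per_px_x))
  i0 <- max(1L, ceiling((cy - r_out) / cal$um_per_px_y))
  i1 <- min(nrow(m), ceiling((cy + r_out) / cal$um_per_px_y))
  if (j0 > j1 || i0 > i1) return(m)
  xs <- (j0:j1 - 0.5) * cal$um_per_px_x
  ys <- (i0:i1 - 0.5) * cal$um_per_px_y
  px <- outer(rep(1, length(ys)), xs) - cx
  py <- outer(ys, rep(1, length(xs))) - cy
  d2 <- px^2 + py^2
  hit <- d2 >= r_in^2 & d2 <= r_out^2
  if (coverage < 1) {
    phase <- stats::runif(1, 0, 2 * pi)
    ang <- (atan2(py, px) - phase) %% (2 * pi)
    # two arcs, each coverage/2 of the circle, opposite sides
    inarc <- (ang %% pi) <= coverage * pi
    hit <- hit & inarc
  }
  sub <- m[i0:i1, j0:j1, drop = FALSE]
  sub[hit] <- pmax(sub[hit], amp)
  m[i0:i1, j0:j1] <- sub
  m
}

band_mask <- function(spec, cal, dims) {
  b <- spec$band
  xs <- (seq_len(dims[["nx"]]) - 0.5) * cal$um_per_px_x
  ys <- (seq_len(dims[["ny"]]) - 0.5) * cal$um_per_px_y
  cy <- b$center_frac * spec$roi_height_um
  th <- b$angle_deg * pi / 180
  px <- outer(rep(1, length(ys)), xs) - spec$roi_width_um / 2
  py <- outer(ys, rep(1, length(xs))) - cy
  dist <- abs(py * cos(th) - px * sin(th))
  dist <= b$thickness_um / 2
}

band_polygon <- function(spec) {
  b <- spec$band
  cy <- b$center_frac * spec$roi_height_um
  th <- b$angle_deg * pi / 180
  w <- spec$roi_width_um
  h <- b$thickness_um / 2
  cx <- w / 2
  ex <- c(-1, 1) * w  # extend beyond the ROI; polygon clipped implicitly
  corners <- rbind(
    c(cx + ex[1] * cos(th), cy + ex[1] * sin(th)),
    c(cx + ex[2] * cos(th), cy + ex[2] * sin(th))
  )
  nx <- -sin(th); ny <- cos(th)
  rbind(corners[1, ] + h * c(nx, ny),
        corners[2, ] + h * c(nx, ny),
        corners[2, ] - h * c(nx, ny),
        corners[1, ] - h * c(nx, ny))
}

# Non-overlapping placement by rejection sampling.  `margin_um` keeps
# centres off the border so border exclusion never drops a truth object.
place_centers <- function(n, diam, spec, placed, margin_um = 2,
                          max_tries = 400L, avoid_band = FALSE) {
  out <- matrix(NA_real_, n, 2)
  w <- spec$roi_width_um; h <- spec$roi_height_um
  bandc <- if (avoid_band && !is.null(spec$band)) {
    spec$band$center_frac * h
  } else NA_real_
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      r <- diam[i] / 2 + margin_um
      cx <- stats::runif(1, r, w - r)
      cy <- stats::runif(1, r, h - r)
      if (!is.na(bandc) &&
          abs(cy - bandc) < spec$band$thickness_um / 2 + r + 2) next
      if (nrow(placed) > 0) {
        dmin <- min(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2) -
                      placed[, 3] / 2)
        if (dmin < diam[i] / 2 + 2 * margin_um) next
      }
      out[i, ] <- c(cx, cy)
      placed <- rbind(placed, c(cx, cy, diam[i]))
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("over-crowded scene: could not place all requested objects ",
           "without exceeding the overlap budget", call. = FALSE)
    }
  }
  list(centers = out, placed = placed)
}

#' Generate a synthetic calibrated z-stack with ground truth
#'
#' Renders the scene described by a [scene_spec()]: NeuN somata are spheres
#' whose per-layer cross-sections follow chord geometry (each spans at least
#' two consecutive planes), debris fragments are single-plane NeuN disks
#' each surrounded by a GFAP annulus at the configured coverage, astrocytes
#' are GFAP somata with radiating processes, microglia are small IBA1 somata
#' with thin processes.  A planar background gradient and Gaussian noise are
#' applied last; ground truth records every object and per-channel truth
#' masks before noise.  Intensities are quantized to the 16-bit grid so a
#' written stack round-trips exactly.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `stack` (a [zstack()]) and `truth`
#'   (`objects` tibble, optional `band` list, per-channel `masks`).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)

  cal <- scene_calibration(spec)
  dims <- scene_dims(spec)
  ny <- dims[["ny"]]; nx <- dims[["nx"]]
  nl <- spec$n_layers
  zplanes <- (seq_len(nl) - 1) * spec$z_step_um
  blank <- function() matrix(0, ny, nx)
  neun <- replicate(nl, blank(), simplify = FALSE)
  gfap <- replicate(nl, blank(), simplify = FALSE)
  iba1 <- replicate(nl, blank(), simplify = FALSE)
  amp <- spec$contrast

  objects <- list()
  placed <- matrix(numeric(0), 0, 3)

  # band (filled analytically; adds packed somata texture on top)
  band_truth <- NULL
  if (!is.null(spec$band)) {
    bm <- band_mask(spec, cal, dims)
    for (l in seq_len(nl)) neun[[l]][bm] <- pmax(neun[[l]][bm], spec$band$intensity)
    band_truth <- list(polygon = band_polygon(spec),
                       thickness_um = spec$band$thickness_um)
  }

  # neurons: spheres spanning >= 2 consecutive planes
  if (spec$n_neurons > 0) {
    d <- stats::runif(spec$n_neurons, spec$soma_diameter_um[1],
                      spec$soma_diameter_um[2])
    pl <- place_centers(spec$n_neurons, d, spec, placed, avoid_band = TRUE)
    placed <- pl$placed
    for (i in seq_len(spec$n_neurons)) {
      pair <- if (nl >= 2) sample.int(nl - 1L, 1L) else 1L
      u <- stats::runif(1, 0.4, 0.6)
      zc <- zplanes[pair] + u * spec$z_step_um
      lo <- nl; hi <- 1L
      for (l in seq_len(nl)) {
        dz <- abs(zplanes[l] - zc)
        if (dz < d[i] / 2) {
          rl <- sqrt((d[i] / 2)^2 - dz^2)
          neun[[l]] <- paint_disk(neun[[l]], cal, pl$centers[i, 1],
                                  pl$centers[i, 2], rl, amp)
          lo <- min(lo, l); hi <- max(hi, l)
        }
      }
      objects[[length(objects) + 1L]] <- tibble::tibble(
        class = "neuron", x_um = pl$centers[i, 1], y_um = pl$centers[i, 2],
        diameter_um = d[i], layer_lo = lo, layer_hi = hi)
    }
  }

  # debris: single-plane NeuN fragments with a GFAP annulus
  if (spec$n_debris > 0) {
    d <- stats::runif(spec$n_debris, spec$debris_diameter_um[1],
                      spec$debris_diameter_um[2])
    pl <- place_centers(spec$n_debris, d + 7, spec, placed, avoid_band = TRUE)
    placed <- pl$placed
    for (i in seq_len(spec$n_debris)) {
      l <- sample.int(nl, 1L)
      neun[[l]] <- paint_disk(neun[[l]], cal, pl$centers[i, 1],
                              pl$centers[i, 2], d[i] / 2, amp)
      # annulus in contact with the fragment (debris sit attached to
      # astrocyte branches), wide enough to cover the encirclement ring
      gfap[[l]] <- paint_ring(gfap[[l]], cal, pl$centers[i, 1],
                              pl$centers[i, 2], max(0, d[i] / 2 - 0.3),
                              d[i] / 2 + 3, amp, spec$ring_coverage)
      objects[[length(objects) + 1L]] <- tibble::tibble(
        class = "debris", x_um = pl$centers[i, 1], y_um = pl$centers[i, 2],
        diameter_um = d[i], layer_lo = l, layer_hi = l)
    }
  }

  # decoys: NeuN fragments with no surrounding astrocyte signal
  if (spec$n_decoys > 0) {
    d <- stats::runif(spec$n_decoys, spec$debris_diameter_um[1],
                      spec$debris_diameter_um[2])
    pl <- place_centers(spec$n_decoys, d + 7, spec, placed, avoid_band = TRUE)
    placed <- pl$placed
    for (i in seq_len(spec$n_decoys)) {
      l <- sample.int(nl, 1L)
      neun[[l]] <- paint_disk(neun[[l]], cal, pl$centers[i, 1],
                              pl$centers[i, 2], d[i] / 2, amp)
      objects[[length(objects) + 1L]] <- tibble::tibble(
        class = "decoy", x_um = pl$centers[i, 1], y_um = pl$centers[i, 2],
        diameter_um = d[i], layer_lo = l, layer_hi = l)
    }
  }

  # astrocytes: GFAP soma + radiating processes over two planes
  if (spec$n_astrocytes > 0) {
    d <- stats::runif(spec$n_astrocytes, 7, 9)
    pl <- place_centers(spec$n_astrocytes, d + 20, spec, placed)
    placed <- pl$placed
    for (i in seq_len(spec$n_astrocytes)) {
      l0 <- if (nl >= 2) sample.int(nl - 1L, 1L) else 1L
      lspan <- if (nl >= 2) c(l0, l0 + 1L) else l0
      nproc <- sample(4:6, 1)
      angs <- stats::runif(nproc, 0, 2 * pi)
      lens <- stats::runif(nproc, 9, 16)
      for (l in lspan) {
        gfap[[l]] <- paint_disk(gfap[[l]], cal, pl$centers[i, 1],
                                pl$centers[i, 2], d[i] / 2, amp)
        for (p in seq_len(nproc)) {
          gfap[[l]] <- paint_segment(
            gfap[[l]], cal, pl$centers[i, 1], pl$centers[i, 2],
            pl$centers[i, 1] + lens[p] * cos(angs[p]),
            pl$centers[i, 2] + lens[p] * sin(angs[p]), 1.4, amp)
        }
      }
      objects[[length(objects) + 1L]] <- tibble::tibble(
        class = "astrocyte", x_um = pl$centers[i, 1], y_um = pl$centers[i, 2],
        diameter_um = d[i], layer_lo = lspan[1], layer_hi = lspan[length(lspan)])
    }
  }

  # microglia: small IBA1 somata with thin processes over two planes
  if (spec$n_microglia > 0) {
    d <- stats::runif(spec$n_microglia, 7, 9)
    pl <- place_centers(spec$n_microglia, d + 12, spec, placed)
    placed <- pl$placed
    for (i in seq_len(spec$n_microglia)) {
      l0 <- if (nl >= 2) sample.int(nl - 1L, 1L) else 1L
      lspan <- if (nl >= 2) c(l0, l0 + 1L) else l0
      nproc <- sample(2:4, 1)
      angs <- stats::runif(nproc, 0, 2 * pi)
      lens <- stats::runif(nproc, 6, 10)
      for (l in lspan) {
        iba1[[l]] <- paint_disk(iba1[[l]], cal, pl$centers[i, 1],
                                pl$centers[i, 2], d[i] / 2, amp)
        for (p in seq_len(nproc)) {
          iba1[[l]] <- paint_segment(
            iba1[[l]], cal, pl$centers[i, 1], pl$centers[i, 2],
            pl$centers[i, 1] + lens[p] * cos(angs[p]),
            pl$centers[i, 2] + lens[p] * sin(angs[p]), 0.9, amp)
        }
      }
      objects[[length(objects) + 1L]] <- tibble::tibble(
        class = "microglia", x_um = pl$centers[i, 1], y_um = pl$centers[i, 2],
        diameter_um = d[i], layer_lo = lspan[1], layer_hi = lspan[length(lspan)])
    }
  }

  masks <- list(NeuN = simplify2array(lapply(neun, function(m) m > 0)),
                GFAP = simplify2array(lapply(gfap, function(m) m > 0)),
                IBA1 = simplify2array(lapply(iba1, function(m) m > 0)))

  # background gradient + noise, applied last
  xs <- (seq_len(nx) - 0.5) / nx
  ys <- (seq_len(ny) - 0.5) / ny
  grad <- spec$background[["offset"]] +
    spec$background[["gradient"]] * (outer(ys, rep(1, nx)) +
                                       outer(rep(1, ny), xs)) / 2
  finalize <- function(layers) {
    a <- array(0, c(ny, nx, nl))
    for (l in seq_len(nl)) {
      m <- pmax(layers[[l]], 0) + grad
      if (spec$noise_sd > 0) {
        m <- m + stats::rnorm(length(m), 0, spec$noise_sd)
      }
      a[, , l] <- quantize16(m)
    }
    a
  }
  stack <- zstack(list(NeuN = finalize(neun), GFAP = finalize(gfap),
                       IBA1 = finalize(iba1)),
                  cal, list(source = "synthetic", crop_offset_px = c(0L, 0L)))

  objects <- if (length(objects)) dplyr::bind_rows(objects) else
    tibble::tibble(class = character(), x_um = numeric(), y_um = numeric(),
                   diameter_um = numeric(), layer_lo = integer(),
                   layer_hi = integer())
  stopifnot(all(objects$x_um >= 0 & objects$x_um <= spec$roi_width_um),
            all(objects$y_um >= 0 & objects$y_um <= spec$roi_height_um))
  list(stack = stack,
       truth = list(objects = objects, band = band_truth, masks = masks))
}

#' Ground-truth object densities per square millimetre
#'
#' @param truth The `truth` element of [generate_scene()] output.
#' @param spec The matching [scene_spec()].
#' @return A tibble with one row per object class: `class`, `n`,
#'   `density_mm2` (count divided by the ROI area in mm^2).
#' @export
ground_truth_density <- function(truth, spec) {
  area <- spec$roi_width_um * spec$roi_height_um / 1e6
  if (area <= 0) stop("zero-area ROI", call. = FALSE)
  truth$objects |>
    dplyr::count(.data$class, name = "n") |>
    dplyr::mutate(density_mm2 = .data$n / area)
}

#' Write a generated scene to disk
#'
#' Writes the stack as a calibrated multi-page TIFF (with JSON sidecar), the
#' ground-truth object list as CSV (class, centre, diameter, layer span) and
#' the per-channel truth masks as a multi-page TIFF.
#'
#' @param scene Output of [generate_scene()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(scene$stack, file.path(dir, "stack.tiff"))
  utils::write.csv(scene$truth$objects, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  mask_stack <- zstack(lapply(scene$truth$masks, function(a) a * 1),
                       scene$stack$calibration)
  write_stack(mask_stack, file.path(dir, "truth_masks.tiff"))
  invisible(dir)
}
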