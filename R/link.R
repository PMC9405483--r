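# Cross-layer linking of blobs into tracks, cell classification, and
# neuronal-debris detection.

#' Link per-layer blobs into cross-layer tracks
#'
#' A blob in layer *i* links to a blob in layer *i + 1* iff their pixel
#' overlap is at least `min_overlap_frac` of the smaller blob's area.
#' Candidate pairs are resolved greedily — largest overlap area first, ties
#' by smallest centroid distance — so each blob has at most one predecessor
#' and one successor; tracks are the maximal chains (strictly consecutive
#' layers). Every blob belongs to exactly one track (possibly a singleton).
#'
#' @param layers List of per-layer [extract_blobs()] results, ordered by
#'   depth.
#' @param params A [detection_params()].
#' @return A tibble with one row per track: `track_id`, `layer_lo`,
#'   `layer_hi`, `n_layers_spanned`, `max_feret_um`, area-weighted
#'   `centroid_x_um` / `centroid_y_um`, total `n_px`, and a `members`
#'   list-column (per-member `layer`, `label`, `feret_um`, `area_um2`,
#'   `n_px`).
#' @export
link_layers <- function(layers, params = detection_params()) {
  nl <- length(layers)
  # node key: layer * 1e6 + label (labels are per-layer)
  key <- function(l, lab) l * 1e6 + lab
  succ <- new.env(parent = emptyenv())
  pred <- new.env(parent = emptyenv())

  for (l in seq_len(max(nl - 1L, 0L))) {
    a <- layers[[l]]; b <- layers[[l + 1L]]
    if (nrow(a$blobs) == 0L || nrow(b$blobs) == 0L) next
    cand <- overlap_candidates(a, b, params$min_overlap_frac)
    if (nrow(cand) == 0L) next
    cand <- cand[order(-cand$overlap_px, cand$centroid_dist), , drop = FALSE]
    used_a <- integer(0); used_b <- integer(0)
    for (r in seq_len(nrow(cand))) {
      la <- cand$label_a[r]; lb <- cand$label_b[r]
      if (la %in% used_a || lb %in% used_b) next
      assign(as.character(key(l, la)), lb, envir = succ)
      assign(as.character(key(l + 1L, lb)), la, envir = pred)
      used_a <- c(used_a, la); used_b <- c(used_b, lb)
    }
  }

  tracks <- list()
  tid <- 0L
  for (l in seq_len(nl)) {
    bl <- layers[[l]]$blobs
    for (i in seq_len(nrow(bl))) {
      lab <- bl$label[i]
      if (!is.null(get0(as.character(key(l, lab)), envir = pred))) next
      # chain head: walk successors
      members <- list()
      cl <- l; clab <- lab
      repeat {
        row <- layers[[cl]]$blobs[layers[[cl]]$blobs$label == clab, ]
        members[[length(members) + 1L]] <- tibble::tibble(
          layer = cl, label = clab, feret_um = row$feret_um,
          area_um2 = row$area_um2, n_px = row$n_px,
          centroid_x_um = row$centroid_x_um,
          centroid_y_um = row$centroid_y_um)
        nxt <- get0(as.character(key(cl, clab)), envir = succ)
        if (is.null(nxt)) break
        cl <- cl + 1L; clab <- nxt
      }
      members <- dplyr::bind_rows(members)
      tid <- tid + 1L
      w <- members$n_px / sum(members$n_px)
      tracks[[tid]] <- tibble::tibble(
        track_id = tid,
        layer_lo = min(members$layer), layer_hi = max(members$layer),
        n_layers_spanned = nrow(members),
        max_feret_um = max(members$feret_um),
        centroid_x_um = sum(w * members$centroid_x_um),
        centroid_y_um = sum(w * members$centroid_y_um),
        n_px = sum(members$n_px),
        members = list(members))
    }
  }
  if (length(tracks)) dplyr::bind_rows(tracks) else
    tibble::tibble(track_id = integer(), layer_lo = integer(),
                   layer_hi = integer(), n_layers_spanned = integer(),
                   max_feret_um = numeric(), centroid_x_um = numeric(),
                   centroid_y_um = numeric(), n_px = integer(),
                   members = list())
}

# All admissible (label_a, label_b) pairs between two segmented layers,
# with overlap pixel counts tabulated jointly on the two label matrices.
overlap_candidates <- function(a, b, min_overlap_frac) {
  la <- a$labels; lb <- b$labels
  sel <- la > 0 & lb > 0
  empty <- tibble::tibble(label_a = integer(), label_b = integer(),
                          overlap_px = integer(), frac = numeric(),
                          centroid_dist = numeric())
  if (!any(sel)) return(empty)
  kb <- max(lb)
  pair_id <- (la[sel] - 1) * kb + lb[sel]  # unique id per (a, b) pair
  tab <- table(pair_id)
  ids <- as.numeric(names(tab))
  label_a <- floor((ids - 1) / kb) + 1
  label_b <- ids - (label_a - 1) * kb
  da <- a$blobs; db <- b$blobs
  keep <- label_a %in% da$label & label_b %in% db$label
  label_a <- label_a[keep]; label_b <- label_b[keep]
  overlap_px <- as.integer(tab)[keep]
  if (!length(label_a)) return(empty)
  na <- da$n_px[match(label_a, da$label)]
  nb <- db$n_px[match(label_b, db$label)]
  frac <- overlap_px / pmin(na, nb)
  cd <- sqrt((da$centroid_x_um[match(label_a, da$label)] -
                db$centroid_x_um[match(label_b, db$label)])^2 +
               (da$centroid_y_um[match(label_a, da$label)] -
                  db$centroid_y_um[match(label_b, db$label)])^2)
  out <- tibble::tibble(label_a = as.integer(label_a),
                        label_b = as.integer(label_b),
                        overlap_px = overlap_px, frac = frac,
                        centroid_dist = cd)
  out[out$frac >= min_overlap_frac, , drop = FALSE]
}

#' Classify tracks as cells
#'
#' A track is a cell iff it spans at least `min_layer_support` consecutive
#' layers (the overlap rule requires at least one linked pair) and its
#' maximum Feret diagonal strictly exceeds `min_cell_diag_um`. Each cell is
#' counted once as a track, never per layer.
#'
#' @param tracks Output of [link_layers()].
#' @param params A [detection_params()].
#' @return `tracks` with an `is_cell` logical column.
#' @export
classify_cells <- function(tracks, params = detection_params()) {
  dplyr::mutate(tracks,
                is_cell = .data$n_layers_spanned >= params$min_layer_support &
                  .data$max_feret_um > params$min_cell_diag_um)
}

#' Detect neuronal debris
#'
#' Candidates are tracks that are not cells and whose maximum Feret
#' diagonal lies in the closed `debris_diag_um` interval (deduplicated at
#' track level so no fragment is counted twice across layers).
#' Encirclement of a member blob is the fraction of its surrounding ring —
#' the blob dilated by `ring_width_um`, blob subtracted — covered by the
#' astrocyte (GFAP) mask of the same layer; a candidate is accepted iff its
#' best member reaches `encircle_frac`. No blob can be both in a cell track
#' and an accepted debris particle.
#'
#' @param layers Per-layer [extract_blobs()] results for the NeuN channel.
#' @param gfap_masks List of binary GFAP masks, one per layer (same
#'   dimensions as the NeuN rasters).
#' @param tracks Classified tracks from [classify_cells()].
#' @param cal A [calibration()].
#' @param params A [detection_params()].
#' @return A tibble of candidates: `track_id`, `max_feret_um`,
#'   `encirclement`, `accepted`, centroid columns.
#' @export
detect_debris <- function(layers, gfap_masks, tracks, cal,
                          params = detection_params()) {
  dims <- dim(layers[[1]]$labels)
  for (g in gfap_masks) {
    if (!all(dim(g) == dims)) stop("mismatched raster dimensions", call. = FALSE)
  }
  cand <- dplyr::filter(tracks, !.data$is_cell,
                        .data$max_feret_um >= params$debris_diag_um[1],
                        .data$max_feret_um <= params$debris_diag_um[2])
  if (nrow(cand) == 0L) {
    return(tibble::tibble(track_id = integer(), max_feret_um = numeric(),
                          encirclement = numeric(), accepted = logical(),
                          centroid_x_um = numeric(), centroid_y_um = numeric()))
  }
  r_px <- params$ring_width_um * 2 / (cal$um_per_px_x + cal$um_per_px_y)
  brush <- disc_brush(r_px)
  enc <- vapply(seq_len(nrow(cand)), function(i) {
    mem <- cand$members[[i]]
    best <- 0
    for (m in seq_len(nrow(mem))) {
      best <- max(best, ring_coverage(layers[[mem$layer[m]]]$labels,
                                      mem$label[m],
                                      gfap_masks[[mem$layer[m]]], brush))
    }
    best
  }, numeric(1))
  tibble::tibble(track_id = cand$track_id,
                 max_feret_um = cand$max_feret_um,
                 encirclement = enc,
                 accepted = enc >= params$encircle_frac,
                 centroid_x_um = cand$centroid_x_um,
                 centroid_y_um = cand$centroid_y_um)
}

# Fraction of the dilation ring of one labelled blob covered by a mask.
# Works on a padded bounding box to stay cheap on large rasters.
ring_coverage <- function(labels, id, gfap_mask, brush) {
  idx <- which(labels == id, arr.ind = TRUE)
  pad <- (dim(brush)[1] - 1L) %/% 2L + 1L
  y0 <- max(1L, min(idx[, 1]) - pad); y1 <- min(nrow(labels), max(idx[, 1]) + pad)
  x0 <- max(1L, min(idx[, 2]) - pad); x1 <- min(ncol(labels), max(idx[, 2]) + pad)
  blob <- (labels[y0:y1, x0:x1, drop = FALSE] == id) * 1
  ring <- EBImage::dilate(blob, brush) > 0 & blob == 0
  if (!any(ring)) return(0)
  g <- gfap_mask[y0:y1, x0:x1, drop = FALSE] > 0
  sum(g & ring) / sum(ring)
}

#' Run the full layered cell-counting pipeline on one channel
#'
#' Composes segmentation ([segment_channel()]), linking ([link_layers()]),
#' classification ([classify_cells()]) and — when the channel is NeuN and a
#' GFAP channel is available — debris detection ([detect_debris()]).
#' Deterministic for fixed inputs and parameters.
#'
#' @param stack A calibrated [zstack()].
#' @param channel Channel to count.
#' @param params A [detection_params()].
#' @param gfap_from Channel supplying the astrocyte mask for debris
#'   detection, or `NULL` to skip debris.
#' @return An object of class `"detection_result"`: list with `tracks`
#'   (classified tibble), `debris` (candidate tibble), `layers` (per-layer
#'   blobs), `n_cells`, `n_debris`, `channel`, `params`, `calibration`.
#' @export
run_detector <- function(stack, channel = "NeuN",
                         params = detection_params(),
                         gfap_from = if (channel == "NeuN" &&
                                         "GFAP" %in% names(stack$channels))
                           "GFAP" else NULL) {
  layers <- segment_channel(stack, channel, params)
  tracks <- classify_cells(link_layers(layers, params), params)
  cal <- stack$calibration
  debris <- if (!is.null(gfap_from)) {
    gm <- lapply(seq_len(n_layers(stack)), function(l) {
      segment_layer(stack$channels[[gfap_from]][, , l], cal,
                    gfap_params(params))
    })
    detect_debris(layers, gm, tracks, cal, params)
  } else {
    tibble::tibble(track_id = integer(), max_feret_um = numeric(),
                   encirclement = numeric(), accepted = logical(),
                   centroid_x_um = numeric(), centroid_y_um = numeric())
  }
  structure(list(tracks = tracks, debris = debris, layers = layers,
                 n_cells = sum(tracks$is_cell),
                 n_debris = sum(debris$accepted),
                 channel = channel, params = params, calibration = cal),
            class = "detection_result")
}

# The astrocyte mask used for encirclement is a presence mask, not a
# measurement mask: morphological refinement is skipped so a narrow GFAP
# annulus is not eroded away, and the threshold offset is halved so faint
# arms and arc edges still register as "astrocyte present".
gfap_params <- function(params) {
  p <- params
  p$apply_morphology <- FALSE
  p$thresh_offset <- params$thresh_offset / 2
  p
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> channel %s: %d cell(s), %d debris, %d track(s) over %d layer(s)\n",
              x$channel, x$n_cells, x$n_debris, nrow(x$tracks),
              length(x$layers)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a detection result into one row per track
#' @param x A `detection_result`.
#' @param ... Unused.
#' @return Tibble of tracks with `is_cell` and debris acceptance merged in.
#' @export
tidy.detection_result <- function(x, ...) {
  out <- dplyr::select(x$tracks, -"members")
  deb <- dplyr::select(x$debris, "track_id", "encirclement",
                       debris_accepted = "accepted")
  dplyr::left_join(out, deb, by = "track_id") |>
    dplyr::mutate(debris_accepted = !is.na(.data$debris_accepted) &
                    .data$debris_accepted)
}

#' One-row summary of a detection result
#' @param x A `detection_result`.
#' @param ... Unused.
#' @return Tibble with `n_cells`, `n_debris`, `n_tracks`, `n_blobs`,
#'   `channel`.
#' @export
glance.detection_result <- function(x, ...) {
  tibble::tibble(channel = x$channel,
                 n_cells = x$n_cells,
                 n_debris = x$n_debris,
                 n_tracks = nrow(x$tracks),
                 n_blobs = sum(vapply(x$layers,
                                      function(l) nrow(l$blobs), integer(1))))
}
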