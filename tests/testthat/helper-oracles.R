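# Independent oracles and small fixtures built in code.

# Small, fast scene: anisotropic calibration like the full-frame default,
# reduced ROI and object counts.
small_scene_spec <- function(seed = 1, ...) {
  defaults <- list(roi_width_um = 200, roi_height_um = 150,
                   px_per_um_x = 1024 / 600, px_per_um_y = 1024 / 400,
                   n_neurons = 6, n_astrocytes = 2, n_microglia = 2,
                   n_debris = 4, seed = seed)
  do.call(scene_spec, utils::modifyList(defaults, list(...)))
}

test_cal <- function(ux = 0.5, uy = 0.5, z = 5) calibration(ux, uy, z)

# Draw a filled disk into a matrix, physical coordinates (um).
disk_mask <- function(ny, nx, cal, cx, cy, r) {
  xs <- (seq_len(nx) - 0.5) * cal$um_per_px_x
  ys <- (seq_len(ny) - 0.5) * cal$um_per_px_y
  (outer(ys, rep(1, nx), function(y, o) (y - cy)^2) +
      outer(rep(1, ny), xs, function(o, x) (x - cx)^2) <= r^2) * 1
}

# O(n^2) Feret oracle: max pairwise distance over ALL corner points of all
# member pixels (not just boundary, no hull).
feret_oracle <- function(mask, cal) {
  idx <- which(mask > 0, arr.ind = TRUE)
  xs <- c(idx[, 2] - 1, idx[, 2], idx[, 2] - 1, idx[, 2]) * cal$um_per_px_x
  ys <- c(idx[, 1] - 1, idx[, 1] - 1, idx[, 1], idx[, 1]) * cal$um_per_px_y
  pts <- unique(cbind(xs, ys))
  best <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    d2 <- (pts[-(1:i), 1] - pts[i, 1])^2 + (pts[-(1:i), 2] - pts[i, 2])^2
    best <- max(best, max(d2))
  }
  sqrt(best)
}

# Brute-force linking oracle: overlaps computed by explicit pixel-set
# intersection, greedy resolution re-implemented independently; returns a
# canonical representation of the track partition (sorted member keys).
link_oracle <- function(layers, min_overlap_frac) {
  nl <- length(layers)
  links <- list()
  for (l in seq_len(max(nl - 1, 0))) {
    a <- layers[[l]]; b <- layers[[l + 1]]
    cand <- NULL
    for (ia in a$blobs$label) {
      pa <- which(a$labels == ia)
      for (ib in b$blobs$label) {
        pb <- which(b$labels == ib)
        ov <- length(intersect(pa, pb))
        if (ov == 0) next
        frac <- ov / min(length(pa), length(pb))
        if (frac >= min_overlap_frac) {
          ra <- a$blobs[a$blobs$label == ia, ]
          rb <- b$blobs[b$blobs$label == ib, ]
          cd <- sqrt((ra$centroid_x_um - rb$centroid_x_um)^2 +
                       (ra$centroid_y_um - rb$centroid_y_um)^2)
          cand <- rbind(cand, data.frame(ia = ia, ib = ib, ov = ov, cd = cd))
        }
      }
    }
    chosen <- NULL
    if (!is.null(cand)) {
      cand <- cand[order(-cand$ov, cand$cd), , drop = FALSE]
      ua <- ub <- integer(0)
      for (r in seq_len(nrow(cand))) {
        if (cand$ia[r] %in% ua || cand$ib[r] %in% ub) next
        chosen <- rbind(chosen, cand[r, ])
        ua <- c(ua, cand$ia[r]); ub <- c(ub, cand$ib[r])
      }
    }
    links[[l]] <- chosen
  }
  # assemble chains
  succ <- list()
  for (l in seq_along(links)) {
    if (is.null(links[[l]])) next
    for (r in seq_len(nrow(links[[l]]))) {
      succ[[paste(l, links[[l]]$ia[r])]] <- c(l + 1, links[[l]]$ib[r])
    }
  }
  has_pred <- unlist(lapply(succ, function(v) paste(v[1], v[2])))
  chains <- list()
  for (l in seq_len(nl)) {
    for (lab in layers[[l]]$blobs$label) {
      k <- paste(l, lab)
      if (k %in% has_pred) next
      chain <- k
      cur <- k
      repeat {
        nxt <- succ[[cur]]
        if (is.null(nxt)) break
        cur <- paste(nxt[1], nxt[2])
        chain <- c(chain, cur)
      }
      chains[[length(chains) + 1]] <- chain
    }
  }
  sort(vapply(chains, function(ch) paste(ch, collapse = "|"), character(1)))
}

# Canonical representation of link_layers() output for comparison.
track_partition <- function(tracks) {
  sort(vapply(seq_len(nrow(tracks)), function(i) {
    m <- tracks$members[[i]]
    paste(paste(m$layer, m$label), collapse = "|")
  }, character(1)))
}

# Random multi-layer label scenes for linking tests: blobs are random
# rectangles, possibly overlapping across layers.
random_blob_layers <- function(n_layers, max_blobs, ny = 40, nx = 40,
                               cal = test_cal()) {
  lapply(seq_len(n_layers), function(l) {
    m <- matrix(0, ny, nx)
    nb <- sample.int(max_blobs, 1)
    for (b in seq_len(nb)) {
      h <- sample(2:6, 1); w <- sample(2:6, 1)
      i0 <- sample.int(ny - h, 1); j0 <- sample.int(nx - w, 1)
      m[i0:(i0 + h), j0:(j0 + w)] <- 1
    }
    extract_blobs(m, cal, exclude_border = FALSE)
  })
}
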