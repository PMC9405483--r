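cal <- test_cal(0.5, 0.5)

test_that("Gaussian preprocessing preserves constants, mass, and reduces noise", {
  p <- detection_params()
  const <- matrix(0.4, 30, 30)
  expect_equal(preprocess_layer(const, cal, p), const)
  # single bright pixel away from borders: total intensity conserved
  spike <- matrix(0, 41, 41); spike[21, 21] <- 1
  sm <- preprocess_layer(spike, cal, p)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_equal(dim(sm), dim(spike))
  # white noise: variance strictly reduced, every seed
  set.seed(101)
  for (i in 1:10) {
    x <- matrix(rnorm(40 * 40, 0.5, 0.1), 40, 40)
    expect_lt(var(as.vector(preprocess_layer(x, cal, p))), var(as.vector(x)))
  }
  expect_error(preprocess_layer(const, cal,
                                detection_params(blur_sigma_um = -1)))
})

test_that("adaptive thresholding empties constants and recovers disks on gradients", {
  p <- detection_params()
  expect_equal(sum(threshold_layer(matrix(0.4, 40, 40), cal, p)), 0)
  # bright disk on a flat background
  ny <- 80; nx <- 80
  disk <- disk_mask(ny, nx, cal, 20, 20, 5)
  img <- 0.1 + 0.5 * disk
  mk <- threshold_layer(img, cal, p)
  eroded <- EBImage::erode(disk, EBImage::makeBrush(5, "disc"))
  dilated <- EBImage::dilate(disk, EBImage::makeBrush(5, "disc"))
  expect_true(all(mk[eroded > 0] == 1))   # contains interior eroded by 2 px
  expect_true(all(mk[dilated == 0] == 0)) # within dilation by 2 px
  # gradient steeper than disk contrast defeats a global threshold but not
  # the adaptive one
  grad <- outer(rep(1, ny), seq(0, 0.8, length.out = nx))
  img2 <- grad + 0.3 * disk_mask(ny, nx, cal, 20, 20, 5)
  mka <- threshold_layer(img2, cal, p)
  d <- disk_mask(ny, nx, cal, 20, 20, 5)
  recovered <- sum(mka[d > 0]) / sum(d)
  expect_gt(recovered, 0.8)
  # best global threshold floods or misses: measure its Jaccard vs the disk
  jac <- function(m) sum(m > 0 & d > 0) / sum(m > 0 | d > 0)
  best_global <- max(vapply(seq(0.05, 0.95, by = 0.05),
                            function(t) jac(img2 > t), numeric(1)))
  expect_gt(jac(mka), best_global)
  expect_error(threshold_layer(matrix(0, 5, 5),
                               calibration(20, 20), p), "3 px")
})

test_that("morphological refinement removes speckle and is idempotent", {
  p <- detection_params()
  expect_equal(sum(refine_mask(matrix(0, 20, 20), cal, p)), 0)
  speck <- matrix(0, 30, 30); speck[15, 15] <- 1
  expect_equal(sum(refine_mask(speck, cal, p)), 0)
  set.seed(77)
  for (i in 1:10) {
    m <- matrix(rbinom(900, 1, 0.35), 30, 30)
    once <- refine_mask(m, cal, p)
    expect_identical(refine_mask(once, cal, p), once)
  }
})

test_that("blob measurement matches known geometry and the pairwise oracle", {
  # one 10 um disk: area ~ pi * 25, feret ~ 10 within a pixel equivalent
  m <- disk_mask(60, 60, cal, 15, 15, 5)
  bl <- extract_blobs(m, cal, exclude_border = TRUE)
  expect_equal(nrow(bl$blobs), 1)
  expect_equal(bl$blobs$area_um2, pi * 25, tolerance = 0.1)
  expect_equal(bl$blobs$feret_um, 10, tolerance = 2 * 0.5)
  expect_equal(bl$blobs$centroid_x_um, 15, tolerance = 0.5)
  # two disjoint disks -> two blobs; touching border flagged/dropped
  m2 <- m + disk_mask(60, 60, cal, 25, 4, 4)
  bl2 <- extract_blobs(m2, cal, exclude_border = FALSE)
  expect_equal(nrow(bl2$blobs), 2)
  expect_true(any(bl2$blobs$touches_border))
  bl2b <- extract_blobs(m2, cal, exclude_border = TRUE)
  expect_equal(nrow(bl2b$blobs), 1)
  expect_equal(sort(unique(as.vector(bl2b$labels)))[-1],
               bl2b$blobs$label)
  # diagonal pixels are one 8-connected blob
  dg <- matrix(0, 6, 6); dg[2, 2] <- 1; dg[3, 3] <- 1
  expect_equal(nrow(extract_blobs(dg, cal, FALSE)$blobs), 1)
  # random masks: feret equals the O(n^2) corner-pair oracle
  set.seed(55)
  for (i in 1:8) {
    m3 <- matrix(0, 25, 25)
    m3[sample(625, 40)] <- 1
    bl3 <- extract_blobs(m3, cal, exclude_border = FALSE)
    for (k in seq_len(nrow(bl3$blobs))) {
      expect_equal(bl3$blobs$feret_um[k],
                   feret_oracle(bl3$labels == bl3$blobs$label[k], cal))
    }
  }
})

test_that("linking follows the smaller-area overlap rule", {
  p <- detection_params()
  # identical masks in consecutive layers: one track spanning all layers
  m <- disk_mask(40, 40, cal, 8, 8, 3) + disk_mask(40, 40, cal, 14, 3.5, 2.5)
  layers <- lapply(1:3, function(l) extract_blobs(m, cal, FALSE))
  tr <- link_layers(layers, p)
  expect_equal(nrow(tr), 2)
  expect_true(all(tr$n_layers_spanned == 3))
  # exactly 50% mutual overlap at threshold 0.60: not linked
  a <- matrix(0, 20, 20); a[5:8, 5:8] <- 1      # 16 px
  b <- matrix(0, 20, 20); b[5:8, 7:10] <- 1     # 16 px, 8 px overlap
  la <- list(extract_blobs(a, cal, FALSE), extract_blobs(b, cal, FALSE))
  tr2 <- link_layers(la, p)
  expect_equal(nrow(tr2), 2)
  expect_true(all(tr2$n_layers_spanned == 1))
  # at 61% overlap of the smaller blob they do link
  b3 <- matrix(0, 20, 20); b3[5:8, 5:9] <- 1    # overlap 16 of min(16, 20)
  la3 <- list(extract_blobs(a, cal, FALSE), extract_blobs(b3, cal, FALSE))
  expect_equal(nrow(link_layers(la3, p)), 1)
})

test_that("linking equals the brute-force oracle on random scenes", {
  p <- detection_params()
  set.seed(202)
  for (i in 1:40) {
    layers <- random_blob_layers(n_layers = sample(2:4, 1), max_blobs = 6)
    expect_identical(track_partition(link_layers(layers, p)),
                     link_oracle(layers, p$min_overlap_frac))
  }
})

test_that("cell classification applies the strict Feret and layer-support rules", {
  p <- detection_params()
  mk_track <- function(feret, span) {
    tibble::tibble(track_id = 1L, layer_lo = 1L, layer_hi = span,
                   n_layers_spanned = span, max_feret_um = feret,
                   centroid_x_um = 0, centroid_y_um = 0, n_px = 10L,
                   members = list(tibble::tibble()))
  }
  # exactly 6.5 um is NOT a cell (strict exceedance)
  expect_false(classify_cells(mk_track(6.5, 2), p)$is_cell)
  expect_true(classify_cells(mk_track(6.5 + 1e-9, 2), p)$is_cell)
  # a large single-layer blob is not a cell (no cross-layer support)
  expect_false(classify_cells(mk_track(12, 1), p)$is_cell)
})

test_that("debris detection requires size, ring coverage, and non-cell status", {
  p <- detection_params()
  ny <- 40; nx <- 40
  frag <- disk_mask(ny, nx, cal, 10, 10, 2)      # 4 um fragment
  layers <- list(extract_blobs(frag, cal, FALSE))
  tracks <- classify_cells(link_layers(layers, p), p)
  ring_full <- (disk_mask(ny, nx, cal, 10, 10, 4.5) - frag) > 0
  deb <- detect_debris(layers, list(ring_full * 1), tracks, cal, p)
  expect_equal(sum(deb$accepted), 1)
  expect_gte(deb$encirclement[1], 0.99)
  # zero GFAP anywhere: rejected
  deb0 <- detect_debris(layers, list(matrix(0, ny, nx)), tracks, cal, p)
  expect_equal(sum(deb0$accepted), 0)
  # a blob belonging to a cell track is never debris even if ring-covered
  big <- disk_mask(ny, nx, cal, 10, 10, 5)
  layers2 <- list(extract_blobs(big, cal, FALSE),
                  extract_blobs(big, cal, FALSE))
  tracks2 <- classify_cells(link_layers(layers2, p), p)
  expect_true(all(tracks2$is_cell))
  deb2 <- detect_debris(layers2, list(matrix(1, ny, nx), matrix(1, ny, nx)),
                        tracks2, cal, p)
  expect_equal(nrow(deb2), 0)
  expect_error(detect_debris(layers, list(matrix(0, 5, 5)), tracks, cal, p),
               "dimensions")
})

test_that("the full pipeline is exact on empty scenes and stable under intensity shifts", {
  spec <- small_scene_spec(seed = 31, n_neurons = 0, n_astrocytes = 0,
                           n_microglia = 0, n_debris = 0)
  sc <- generate_scene(spec)
  res <- run_detector(sc$stack)
  expect_equal(res$n_cells, 0)
  expect_equal(res$n_debris, 0)

  sc2 <- generate_scene(small_scene_spec(seed = 32))
  res2 <- run_detector(sc2$stack)
  # adding a constant to all intensities leaves counts unchanged
  shifted <- sc2$stack
  shifted$channels <- lapply(shifted$channels, function(a) a + 0.15)
  res_shift <- run_detector(shifted)
  expect_equal(res_shift$n_cells, res2$n_cells)
  expect_equal(res_shift$n_debris, res2$n_debris)
  # no track double-counts blobs: members are unique (layer, label) pairs
  all_members <- dplyr::bind_rows(res2$tracks$members)
  expect_equal(nrow(all_members),
               nrow(dplyr::distinct(all_members, layer, label)))
  expect_gte(sum(vapply(res2$tracks$members, nrow, integer(1))),
             res2$n_cells)
  # debris/cell exclusivity
  cell_ids <- res2$tracks$track_id[res2$tracks$is_cell]
  expect_length(intersect(cell_ids, res2$debris$track_id[res2$debris$accepted]), 0)
  # permuting layers and un-permuting is a no-op on the result
  res2b <- run_detector(sc2$stack)
  expect_equal(glance(res2), glance(res2b))
})

test_that("detection parameters are validated", {
  expect_error(detection_params(min_overlap_frac = 0), "overlap")
  expect_error(detection_params(min_layer_support = 1), ">= 2")
  expect_error(detection_params(debris_diag_um = c(2.5, 7)), "equal")
  expect_error(detection_params(blur_sigma_um = 0), "sigma")
})

test_that("non-encircled decoy fragments are rejected while true debris pass", {
  spec <- small_scene_spec(seed = 61, n_neurons = 0, n_astrocytes = 0,
                           n_microglia = 0, n_debris = 5, n_decoys = 4)
  sc <- generate_scene(spec)
  res <- run_detector(sc$stack)
  acc <- dplyr::filter(res$debris, accepted)
  # no accepted particle sits on a decoy
  decoys <- dplyr::filter(sc$truth$objects, class == "decoy")
  for (i in seq_len(nrow(acc))) {
    dmin <- min(sqrt((decoys$x_um - acc$centroid_x_um[i])^2 +
                       (decoys$y_um - acc$centroid_y_um[i])^2))
    expect_gt(dmin, 2)
  }
  # most true debris are accepted (fragments sampled at the very edges of
  # the 2.5-6.5 um window can scatter out), and never over-counted
  expect_gte(nrow(acc), 3)
  expect_lte(nrow(acc), 5)
})
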