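test_that("an empty noiseless scene is exactly the background field", {
  spec <- scene_spec(roi_width_um = 100, roi_height_um = 80,
                     px_per_um_x = 1, px_per_um_y = 1,
                     n_neurons = 0, n_astrocytes = 0, n_microglia = 0,
                     n_debris = 0, noise_sd = 0, seed = 3)
  sc <- generate_scene(spec)
  expect_equal(nrow(sc$truth$objects), 0)
  # all channels identical and equal to the smooth background gradient
  expect_identical(sc$stack$channels$NeuN, sc$stack$channels$GFAP)
  expect_identical(sc$stack$channels$NeuN, sc$stack$channels$IBA1)
  rng <- range(sc$stack$channels$NeuN)
  expect_gte(rng[1], spec$background[["offset"]] - 1e-3)
  expect_lte(rng[2], sum(spec$background) + 1e-3)
  # and every layer carries the same gradient
  expect_identical(sc$stack$channels$NeuN[, , 1], sc$stack$channels$NeuN[, , 2])
})

test_that("ground truth bookkeeping matches the requested counts", {
  sc <- generate_scene(small_scene_spec(seed = 11))
  counts <- table(sc$truth$objects$class)
  expect_equal(unname(counts[["neuron"]]), 6)
  expect_equal(unname(counts[["debris"]]), 4)
  expect_equal(unname(counts[["astrocyte"]]), 2)
  expect_equal(unname(counts[["microglia"]]), 2)
  # every centre inside the ROI
  expect_true(all(sc$truth$objects$x_um >= 0 & sc$truth$objects$x_um <= 200))
  expect_true(all(sc$truth$objects$y_um >= 0 & sc$truth$objects$y_um <= 150))
  # every neuron spans at least two consecutive layers
  neurons <- dplyr::filter(sc$truth$objects, class == "neuron")
  expect_true(all(neurons$layer_hi - neurons$layer_lo >= 1))
})

test_that("generation is deterministic in the seed and monotone in counts", {
  a <- generate_scene(small_scene_spec(seed = 5))
  b <- generate_scene(small_scene_spec(seed = 5))
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$objects, b$truth$objects)
  c <- generate_scene(small_scene_spec(seed = 6))
  expect_false(identical(a$stack$channels$NeuN, c$stack$channels$NeuN))
  # monotonicity of the truth list under increasing n_neurons
  n1 <- generate_scene(small_scene_spec(seed = 5))
  n2 <- generate_scene(small_scene_spec(seed = 5, n_neurons = 9))
  expect_gte(sum(n2$truth$objects$class == "neuron"),
             sum(n1$truth$objects$class == "neuron"))
})

test_that("noiseless truth objects exceed background by the contrast", {
  spec <- small_scene_spec(seed = 2, noise_sd = 0)
  sc <- generate_scene(spec)
  for (ch in c("NeuN", "GFAP", "IBA1")) {
    m <- sc$truth$masks[[ch]]
    if (!any(m)) next
    vals <- sc$stack$channels[[ch]][m]
    expect_gte(min(vals), spec$contrast)
  }
})

test_that("over-crowded scenes are rejected", {
  spec <- scene_spec(roi_width_um = 60, roi_height_um = 50,
                     px_per_um_x = 1, px_per_um_y = 1,
                     n_neurons = 60, n_astrocytes = 0, n_microglia = 0,
                     n_debris = 0, seed = 1)
  expect_error(generate_scene(spec), "over-crowded")
})

test_that("scene specs are validated", {
  expect_error(scene_spec(n_neurons = -1), "counts")
  expect_error(scene_spec(roi_width_um = 0), "> 0")
  expect_error(scene_spec(debris_diameter_um = c(2.5, 9)),
               "smallest soma diameter")
})

test_that("ground-truth densities are count over area, exactly", {
  # 24 objects in a 0.24 mm^2 ROI -> 100 / mm^2
  spec <- scene_spec(n_neurons = 24, n_astrocytes = 0, n_microglia = 0,
                     n_debris = 0, seed = 4)
  sc <- generate_scene(spec)
  dens <- ground_truth_density(sc$truth, spec)
  expect_equal(dens$density_mm2[dens$class == "neuron"], 100)
  # empty scene: zero everywhere
  spec0 <- small_scene_spec(seed = 1, n_neurons = 0, n_astrocytes = 0,
                            n_microglia = 0, n_debris = 0)
  sc0 <- generate_scene(spec0)
  expect_equal(nrow(ground_truth_density(sc0$truth, spec0)), 0)
  # random spec: brute-force count over area
  sc2 <- generate_scene(small_scene_spec(seed = 9))
  d2 <- ground_truth_density(sc2$truth, small_scene_spec(seed = 9))
  area <- 200 * 150 / 1e6
  for (cl in unique(sc2$truth$objects$class)) {
    expect_equal(d2$density_mm2[d2$class == cl],
                 sum(sc2$truth$objects$class == cl) / area)
  }
})
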