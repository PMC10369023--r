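test_that("boldness depends on the animal region only", {
  obs <- observer()
  sp <- scene_spec(seed = 4)
  sc <- generate_scene(sp)
  amap <- local_edge_map(sc$image, obs, sc$masks$animal)
  b1 <- boldness(amap)
  # scramble every background pixel; the animal map cannot change
  st <- unclass(sc$image)
  set.seed(1)
  for (ch in 1:4) {
    plane <- st[, , ch]
    plane[!sc$masks$animal] <- runif(sum(!sc$masks$animal), 0.1, 1)
    st[, , ch] <- plane
  }
  img2 <- cone_catch_image(st, 50)
  b2 <- boldness(local_edge_map(img2, obs, sc$masks$animal))
  expect_equal(b1, b2, tolerance = 1e-12)
  expect_true(all(b1 >= 0))
})

test_that("halving pattern contrast towards the noise floor lowers boldness", {
  # CoV is scale invariant far above the noise floor, so the contrast
  # dependence of boldness comes from the floor: a pattern whose contrast
  # approaches the pixel-noise level loses its heterogeneity signature
  obs <- observer()
  mk <- function(contrast) {
    sp <- scene_spec(seed = 8, pixel_noise_sd = 0.05,
                     animal = list(element_size_px = 5,
                                   phase_fraction = 0.25,
                                   achromatic_contrast = contrast,
                                   chromatic_contrast = contrast * 0.6))
    sc <- generate_scene(sp)
    proc <- rnl_ranked_filter(acuity_blur(sc$image, obs, 2), obs)
    boldness(local_edge_map(proc, obs, sc$masks$animal))
  }
  strong <- mk(8)
  weak <- mk(2)
  expect_gt(strong["lum_boldness"], weak["lum_boldness"])
})

test_that("detectability is a folded difference of animal and background CoV", {
  obs <- observer()
  sc <- generate_scene(scene_spec(seed = 6))
  amap <- local_edge_map(sc$image, obs, sc$masks$animal,
                         region_label = "animal")
  bmap <- local_edge_map(sc$image, obs, sc$masks$background,
                         region_label = "background")
  d1 <- detectability(amap, bmap)
  expect_true(all(d1 >= 0))
  # identical maps: exactly zero
  d0 <- detectability(amap, amap)
  expect_equal(unname(d0), c(0, 0))
  # order of arguments is irrelevant
  d2 <- detectability(bmap, amap)
  expect_equal(unname(d1), unname(d2), tolerance = 1e-12)
})

test_that("statistically matched animal and background give near-null detectability", {
  obs <- observer()
  # same texture parameters for animal and background, different realizations
  det <- replicate(12, NA_real_)
  for (k in 1:12) {
    sp <- scene_spec(seed = 1000 + k, animal = list(boundary_contrast = 0))
    sc <- generate_scene(sp)
    proc <- rnl_ranked_filter(acuity_blur(sc$image, obs, 2), obs)
    amap <- local_edge_map(proc, obs, sc$masks$animal)
    bmap <- local_edge_map(proc, obs, sc$masks$background)
    det[k] <- detectability(amap, bmap)["lum_detectability"]
  }
  # mismatched control at the same seeds
  det_alt <- replicate(6, NA_real_)
  for (k in 1:6) {
    sp <- scene_spec(seed = 2000 + k,
                     animal = list(boundary_contrast = 0,
                                   phase_fraction = 0.12,
                                   achromatic_contrast = 8))
    sc <- generate_scene(sp)
    proc <- rnl_ranked_filter(acuity_blur(sc$image, obs, 2), obs)
    amap <- local_edge_map(proc, obs, sc$masks$animal)
    bmap <- local_edge_map(proc, obs, sc$masks$background)
    det_alt[k] <- detectability(amap, bmap)["lum_detectability"]
  }
  expect_lt(median(det), min(det_alt))
})

test_that("distance_profile emits one record per distance with metadata", {
  sc <- generate_scene(scene_spec(seed = 2))
  rec <- distance_profile(sc$image, sc$masks, observer(),
                          individual_id = "ind7", species = "spX",
                          defence_class = "II", unpalatability = 0.4)
  expect_equal(nrow(rec), 4)
  expect_equal(rec$distance_cm, c(2, 5, 10, 30))
  expect_equal(unique(rec$species), "spX")
  expect_true(all(rec$lum_boldness >= 0))
  expect_error(distance_profile(sc$image, sc$masks, observer(),
                                distances_cm = c(5, 2)), "sorted")
  expect_error(distance_profile(sc$image, sc$masks, observer(),
                                distances_cm = c(-2, 5)), "> 0")
})

test_that("an effectively infinite acuity yields identical records at all distances", {
  sc <- generate_scene(scene_spec(seed = 3))
  obs <- observer(acuity_cpd = 1e7)
  rec <- distance_profile(sc$image, sc$masks, obs)
  for (col in c("lum_boldness", "col_boldness", "lum_detectability",
                "col_detectability"))
    expect_equal(diff(range(rec[[col]])), 0, tolerance = 1e-12)
})

test_that("a flat animal is dropped with a warning, not imputed", {
  # fully constant scene: every edge map is all-zero, both CoVs undefined
  img <- cone_catch_image(array(0.5, c(32, 32, 4)), 50)
  sc0 <- generate_scene(scene_spec(seed = 5, image_size_px = 32))
  expect_warning(
    rec <- distance_profile(img, sc0$masks, observer(),
                            distances_cm = c(2)),
    "undefined|dropping")
  expect_true(is.null(rec) || nrow(rec) == 0)
})

test_that("fine bold patterns lose boldness between 2 cm and 30 cm", {
  obs <- observer()
  sp <- scene_spec(image_size_px = 128, pixels_per_cm = 100, seed = 19,
                   animal = list(element_size_px = 6,
                                 chromatic_contrast = 9,
                                 achromatic_contrast = 9,
                                 boundary_contrast = 1))
  sc <- generate_scene(sp)
  rec <- distance_profile(sc$image, sc$masks, obs)
  expect_lt(rec$lum_boldness[4], rec$lum_boldness[1])
  expect_lt(rec$col_boldness[4], rec$col_boldness[1])
})

test_that("large-element matched patterns are stable across the distance grid", {
  obs <- observer()
  # element size far above the resolvable scale at 30 cm
  sp <- scene_spec(image_size_px = 64, pixels_per_cm = 10, seed = 23,
                   pixel_noise_sd = 0.01,
                   background = list(element_size_px = 16),
                   animal = list(element_size_px = 16, boundary_contrast = 0))
  sc <- generate_scene(sp)
  rec <- distance_profile(sc$image, sc$masks, obs)
  for (col in c("lum_boldness", "col_boldness")) {
    spread <- diff(range(rec[[col]])) / mean(rec[[col]])
    expect_lt(spread, 0.10)
  }
})
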