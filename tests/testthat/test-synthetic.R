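test_that("scene generation is deterministic and spec-faithful", {
  sp <- scene_spec(seed = 13)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$masks$animal, b$masks$animal)
  expect_equal(dim(a$image), c(64, 64, 4))
  expect_true(all(unclass(a$image) > 0))
  # masks: animal inside, annulus around it, disjoint
  expect_false(any(a$masks$animal & a$masks$background))
  expect_gt(sum(a$masks$background), sum(a$masks$animal))
})

test_that("target achromatic contrast inverts to the expected luminance ratio", {
  # delta-S of 13.8629 at omega = 0.05 means a 2:1 phase luminance ratio
  sp <- scene_spec(seed = 2, pixel_noise_sd = 0,
                   background = list(achromatic_contrast = log(2) / 0.05,
                                     chromatic_contrast = 0),
                   animal = list(achromatic_contrast = 0,
                                 chromatic_contrast = 0,
                                 boundary_contrast = 0))
  sc <- generate_scene(sp)
  lum <- unclass(sc$image)[, , 4]
  bg_lums <- sort(unique(round(lum[!sc$masks$animal &
                                   !sc$masks$background], 10)))
  # outside both masks only background texture exists: exactly two phases
  expect_length(bg_lums, 2)
  expect_equal(bg_lums[2] / bg_lums[1], 2, tolerance = 1e-9)
})

test_that("realized phase contrasts hit their delta-S targets exactly (pre-noise)", {
  obs <- observer()
  sp <- scene_spec(seed = 5, pixel_noise_sd = 0,
                   background = list(chromatic_contrast = 2.5,
                                     achromatic_contrast = 4))
  sc <- generate_scene(sp)
  st <- unclass(sc$image)
  out <- !sc$masks$animal & !sc$masks$background
  lums <- sort(unique(round(st[, , 4][out], 12)))
  expect_equal(achromatic_delta_s(lums[2], lums[1], obs), 4,
               tolerance = 1e-9)
  # chromatic: collect the two distinct catch vectors
  key <- round(st[, , 1][out], 12)
  ks <- sort(unique(key))
  qa <- sapply(1:3, function(ch) st[, , ch][out][key == ks[1]][1])
  qb <- sapply(1:3, function(ch) st[, , ch][out][key == ks[2]][1])
  expect_equal(chromatic_delta_s(qa, qb, obs), 2.5, tolerance = 1e-9)
})

test_that("zero internal contrast gives a uniform animal (pre-noise)", {
  sp <- scene_spec(seed = 3, pixel_noise_sd = 0,
                   animal = list(chromatic_contrast = 0,
                                 achromatic_contrast = 0))
  sc <- generate_scene(sp)
  st <- unclass(sc$image)
  for (ch in 1:4)
    expect_equal(length(unique(round(st[, , ch][sc$masks$animal], 10))), 1)
})

test_that("the sparse-phase mixture stays mean-centred in log space", {
  # pooled (blurred-to-uniform) appearance must not drift with coverage,
  # otherwise sparse bold patterns could never background-match at distance
  for (pf in c(0.2, 0.5, 0.8)) {
    sp <- scene_spec(seed = 9, pixel_noise_sd = 0,
                     background = list(phase_fraction = pf,
                                       achromatic_contrast = 6))
    sc <- generate_scene(sp)
    lum <- unclass(sc$image)[, , 4]
    # the background texture is centred over the whole non-animal region
    got_mean <- mean(log(lum[!sc$masks$animal]))
    expect_equal(got_mean, log(0.5), tolerance = 1e-9)
  }
})

test_that("cohort defaults mirror the 13-species field design", {
  cs <- cohort_spec(seed = 21)
  co <- generate_cohort(cs)
  md <- co$metadata
  expect_equal(nrow(md), 13)
  expect_equal(sum(md$n_individuals), 226)
  expect_equal(sort(unique(md$defence_class)), sort(c("NR", "II", "I_II")))
  expect_equal(as.vector(table(md$defence_class)[c("NR", "II", "I_II")]),
               c(3, 4, 6))
  expect_equal(length(co$scenes), 226)
  # u spans [0, 1] with observed endpoints and increases with class severity
  expect_equal(min(md$unpalatability), 0)
  expect_equal(max(md$unpalatability), 1)
  expect_lt(max(md$unpalatability[md$defence_class == "NR"]),
            min(md$unpalatability[md$defence_class != "NR"]))
})

test_that("cohort generation is deterministic and scales down", {
  cs <- cohort_spec(individuals_per_species = 2, seed = 77)
  a <- generate_cohort(cs)
  b <- generate_cohort(cs)
  expect_equal(length(a$scenes), 26)
  expect_identical(a$metadata, b$metadata)
  expect_identical(unclass(a$scenes[[5]]$image), unclass(b$scenes[[5]]$image))
})

test_that("the null cohort decouples u from every pattern parameter", {
  cs <- cohort_spec(individuals_per_species = 1, effect_gain = 0,
                    sparseness_gain = 0, fine_pattern_for_defended = FALSE,
                    coarse_contrast_span = 1,
                    animal_coarse_coverage = c(0.2, 0.2), seed = 31)
  co <- generate_cohort(cs)
  # all animals share identical texture parameters; check a realized proxy
  expect_equal(cs$effect_gain, 0)
  imgs <- lapply(co$scenes, function(s) unclass(s$image))
  # with zero effects every animal's pattern statistics are exchangeable;
  # a cheap proxy: the per-scene sd of log luminance inside the animal is
  # uncorrelated with u
  stat <- vapply(co$scenes, function(s)
    sd(log(unclass(s$image)[, , 4][s$masks$animal])), numeric(1))
  u <- vapply(co$scenes, function(s) s$unpalatability, numeric(1))
  expect_lt(abs(cor(stat, u, method = "spearman")), 0.55) # n=13, null
})

test_that("the effect cohort couples u to contrast and sparseness by construction", {
  cs <- cohort_spec(individuals_per_species = 1, seed = 41)
  co <- generate_cohort(cs)
  u <- vapply(co$scenes, function(s) s$unpalatability, numeric(1))
  spec_of <- function(s, field) s$scene_spec$animal[[field]]
  contrast <- vapply(co$scenes, spec_of, numeric(1), "achromatic_contrast")
  coverage <- vapply(co$scenes, spec_of, numeric(1), "phase_fraction")
  # specified internal contrast rises with u (up to background jitter) and
  # fine-spot coverage falls deterministically with u
  expect_gt(cor(contrast, u, method = "spearman"), 0.5)
  expect_equal(cor(coverage, u, method = "spearman"), -1)
})

test_that("invalid cohort and scene specs are rejected", {
  expect_error(cohort_spec(n_species = 2), "at least 3")
  expect_error(cohort_spec(class_counts = c(NR = 2, II = 2, I_II = 2)),
               "sum to n_species")
  expect_error(cohort_spec(effect_gain = -1), "monotone")
  expect_error(scene_spec(animal = list(size_px = c(100, 100))), "fit")
  expect_error(scene_spec(background = list(base_catch = c(1, 1))),
               "match the observer")
})
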