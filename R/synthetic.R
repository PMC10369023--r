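#' Specify a synthetic cone-catch scene
#'
#' Describes one animal-on-background scene as a stated world: a two-phase
#' blob texture background, an elliptical animal with its own internal
#' two-phase pattern, and multiplicative pixel noise. All contrasts are
#' target RNL \eqn{\Delta S} values between the two phases of a texture
#' (chromatic and achromatic separately), which keeps the construction
#' analytically invertible: phases are placed symmetrically around a base
#' catch in noise-scaled log space, so the realized pre-noise phase contrast
#' equals the target exactly.
#'
#' @param image_size_px scene edge length in pixels (square scene).
#' @param pixels_per_cm spatial calibration.
#' @param obs the [observer()] whose noise matrix defines the \eqn{\Delta S}
#'   targets (needed to invert contrast into catch space).
#' @param background list: `base_catch` (chromatic base vector),
#'   `base_luminance`, `element_size_px`, `phase_fraction` (coverage of the
#'   displaced "spot" phase; 0.5 = balanced two-phase texture),
#'   `chromatic_contrast`, `achromatic_contrast`.
#' @param animal list: `size_px` (full ellipse axes, c(height, width)),
#'   `element_size_px`, `phase_fraction`, `chromatic_contrast`,
#'   `achromatic_contrast`, `boundary_contrast` (displacement of the
#'   animal's base from the background's base, recycled to chromatic and
#'   achromatic if scalar).
#' @param pixel_noise_sd sdlog of the multiplicative lognormal pixel noise
#'   applied post-construction in linear catch space.
#' @param background_extent background ROI = ellipse scaled by this factor,
#'   animal excluded (default 2: an annulus out to twice the animal's
#'   equivalent diameter).
#' @param seed integer RNG seed; the same spec and seed give bit-identical
#'   stacks.
#' @return A `scene_spec` list.
#' @seealso [generate_scene()]
#' @export
scene_spec <- function(image_size_px = 64,
                       pixels_per_cm = 50,
                       obs = observer(),
                       background = list(),
                       animal = list(),
                       pixel_noise_sd = 0.02,
                       background_extent = 2,
                       seed = 1L) {
  bg <- utils::modifyList(list(
    base_catch = c(0.35, 0.5, 0.65),
    base_luminance = 0.5,
    element_size_px = 4,
    phase_fraction = 0.5,
    chromatic_contrast = 2,
    achromatic_contrast = 3,
    coarse_element_size_px = 8,
    coarse_phase_fraction = 0,
    coarse_chromatic_contrast = 2,
    coarse_achromatic_contrast = 3), background)
  an <- utils::modifyList(list(
    size_px = round(c(0.6, 0.38) * image_size_px),
    element_size_px = 4,
    phase_fraction = 0.5,
    chromatic_contrast = 2,
    achromatic_contrast = 3,
    coarse_element_size_px = 8,
    coarse_phase_fraction = 0,
    coarse_chromatic_contrast = 2,
    coarse_achromatic_contrast = 3,
    boundary_contrast = 1), animal)
  if (length(an$boundary_contrast) == 1L)
    an$boundary_contrast <- rep(an$boundary_contrast, 2L)
  if (length(bg$base_catch) != n_receptors(obs))
    stop("background base_catch length must match the observer's chromatic channels")
  stopifnot(bg$chromatic_contrast >= 0, bg$achromatic_contrast >= 0,
            an$chromatic_contrast >= 0, an$achromatic_contrast >= 0,
            bg$element_size_px >= 1, an$element_size_px >= 1)
  if (any(an$size_px >= image_size_px))
    stop("animal does not fit inside the image")
  structure(list(image_size_px = as.integer(image_size_px),
                 pixels_per_cm = pixels_per_cm, obs = obs,
                 background = bg, animal = an,
                 pixel_noise_sd = pixel_noise_sd,
                 background_extent = background_extent,
                 seed = seed),
            class = "scene_spec")
}

# Binary blob phase map: thresholded smoothed Gaussian field. Blob scale is
# set by the smoothing sigma (element_size_px / 2); the threshold quantile
# sets the coverage of the TRUE ("spot") phase, so phase_fraction = 0.5 gives
# an equal-abundance two-phase texture and small fractions give sparse bold
# markings on a matrix.
blob_phase_map <- function(n, element_size_px, phase_fraction = 0.5) {
  if (phase_fraction <= 0) return(matrix(FALSE, n, n))
  z <- matrix(stats::rnorm(n * n), n, n)
  sigma <- max(element_size_px / 2, 0.51)
  z <- conv_separable_cpp(z, gaussian_kernel(sigma))
  z > stats::quantile(z, 1 - phase_fraction)
}

# Two-scale additive texture level maps. Each layer is a binary blob map
# scaled by its delta-S contrast; `chrom`/`achrom` are real-valued fields in
# perceptual units such that two pixels differing by one fine (or coarse)
# phase flip differ by exactly the layer's target delta-S. Levels are
# centred on the realized coverage inside `region`, so the region's
# abundance-weighted mean appearance sits exactly at the base colour — a
# spatially pooled (blurred-to-uniform) view looks like the base whatever
# the coverage, which is what lets sparse bold patterns background-match at
# distance.
texture_levels <- function(n, tx, region) {
  fine <- blob_phase_map(n, tx$element_size_px, tx$phase_fraction)
  coarse <- blob_phase_map(n, tx$coarse_element_size_px %||% 8,
                           tx$coarse_phase_fraction %||% 0)
  centre <- function(m) m - mean(m[region])
  f <- centre(fine); cs <- centre(coarse)
  list(chrom = tx$chromatic_contrast * f +
         (tx$coarse_chromatic_contrast %||% 0) * cs,
       achrom = tx$achromatic_contrast * f +
         (tx$coarse_achromatic_contrast %||% 0) * cs)
}

# Unit RNL-length log-opponent direction used to realize chromatic levels.
chromatic_direction <- function(nc, A) {
  d <- c(1, -1, rep(0, nc - 2))
  d / sqrt(drop(d %*% A %*% d))
}

# Convenience: two catch vectors separated by `delta_s` around base `q0`
# (used for the animal-base boundary displacement).
phase_pair_chromatic <- function(q0, delta_s, A) {
  d <- chromatic_direction(length(q0), A)
  f0 <- log(q0)
  list(a = exp(f0 - d * delta_s / 2), b = exp(f0 + d * delta_s / 2))
}

phase_pair_luminance <- function(l0, delta_s, omega) {
  list(a = l0 * exp(-omega * delta_s / 2), b = l0 * exp(omega * delta_s / 2))
}

#' Generate a synthetic cone-catch scene
#'
#' Realizes a [scene_spec()]: a two-phase blob background, an elliptical
#' animal with an internal two-phase pattern at its target contrasts, and
#' multiplicative lognormal pixel noise. Returns the cone-catch stack
#' together with the animal mask and an annular background ROI
#' (animal excluded).
#'
#' @param spec a [scene_spec()].
#' @return list with elements `image` (a [cone_catch_image()]) and `masks`
#'   (a [region_masks()]).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    n <- spec$image_size_px
    obs <- spec$obs
    A <- rnl_noise_matrix(obs)
    nc <- n_receptors(obs)
    omega <- obs$luminance_weber

    bg <- spec$background
    an <- spec$animal

    # animal base displaced from the background base by the boundary contrast
    an_base <- phase_pair_chromatic(bg$base_catch, 2 * an$boundary_contrast[1], A)$b
    an_lum <- phase_pair_luminance(bg$base_luminance,
                                   2 * an$boundary_contrast[2], omega)$b

    ctr <- (n + 1) / 2
    a_semi <- an$size_px[1] / 2
    b_semi <- an$size_px[2] / 2
    rr <- matrix(seq_len(n), n, n)
    cc <- matrix(seq_len(n), n, n, byrow = TRUE)
    rad2 <- ((rr - ctr) / a_semi)^2 + ((cc - ctr) / b_semi)^2
    animal_mask <- rad2 <= 1
    ext <- spec$background_extent
    background_mask <- (rad2 <= ext^2) & !animal_mask

    bg_lv <- texture_levels(n, bg, !animal_mask)
    an_lv <- texture_levels(n, an, animal_mask)

    d <- chromatic_direction(nc, A)
    stack <- array(NA_real_, c(n, n, nc + 1L))
    for (ch in seq_len(nc)) {
      plane <- bg$base_catch[ch] * exp(d[ch] * bg_lv$chrom)
      plane[animal_mask] <- (an_base[ch] *
                               exp(d[ch] * an_lv$chrom))[animal_mask]
      stack[, , ch] <- plane
    }
    lum <- bg$base_luminance * exp(omega * bg_lv$achrom)
    lum[animal_mask] <- (an_lum * exp(omega * an_lv$achrom))[animal_mask]
    stack[, , nc + 1L] <- lum

    if (spec$pixel_noise_sd > 0)
      stack <- stack * exp(array(stats::rnorm(length(stack),
                                              sd = spec$pixel_noise_sd),
                                 dim(stack)))

    list(image = cone_catch_image(stack, spec$pixels_per_cm),
         masks = region_masks(animal_mask, background_mask))
  })
}

#' Specify a synthetic species cohort
#'
#' Encodes the study design the downstream statistics assume: species split
#' into defence classes (`NR` undefended, `II` weakly toxic / highly
#' unpalatable, `I_II` highly toxic and unpalatable), an unpalatability score
#' u in [0, 1] increasing with class severity, and a monotone effect map
#' coupling u to the animals' internal pattern contrast and to
#' animal-background similarity. At `effect_gain = 0` the cohort is a null:
#' every animal carries the background's own texture statistics regardless
#' of u.
#'
#' The default design mirrors a 13-species field study: 3 NR, 4 Class II and
#' 6 Class I & II species with per-species sample sizes
#' (24, 21, 17, 15, 27, 15, 15, 25, 10, 8, 23, 8, 18) — 226 individuals in
#' total. Pass `individuals_per_species` to scale the cohort down for quick
#' experiments.
#'
#' @param n_species number of species (>= 3).
#' @param class_counts named integer vector giving species per class; must
#'   sum to `n_species` and name every used class at least once.
#' @param individuals_per_species `NULL` for the default per-species counts
#'   (13-species design above; otherwise drawn uniformly from 8-27), a
#'   scalar, or a vector of length `n_species`.
#' @param effect_gain monotone coupling strength between u and the animal's
#'   internal contrast (0 = null cohort). Internal contrast =
#'   background contrast * (1 + effect_gain * u), so u = 0 animals match the
#'   background exactly.
#' @param sparseness_gain monotone coupling between u and pattern
#'   heterogeneity: the spot-phase coverage is 0.5 * (1 - sparseness_gain *
#'   u), so defended species carry sparse bold markings (high edge-contrast
#'   CoV) while u = 0 animals keep the background's balanced texture. 0
#'   disables the coupling.
#' @param fine_pattern_for_defended if `TRUE`, element size interpolates
#'   from the background's towards `fine_element_size_px` as u rises, so
#'   well-defended species get fine markings that are sub-resolvable at the
#'   far end of the distance grid; if `FALSE` every animal keeps the
#'   background's element size.
#' @param fine_element_size_px see above.
#' @param coarse_contrast_span coarse-layer contrast range, as a multiple
#'   of the base fine contrast: background coarse contrast is drawn
#'   uniformly from [1, span] x base per scene, and a fully defended
#'   animal's coarse contrast sits at span x base, i.e. at the top of the
#'   same range.
#' @param bg_jitter per-scene multiplicative jitter (+/- fraction) on the
#'   background phase contrasts: each individual sits on its own natural
#'   background.
#' @param bg_coarse_range per-scene uniform range for the background's
#'   coarse-element coverage; wide, because natural backgrounds vary a lot
#'   in large-scale structure.
#' @param animal_coarse_coverage coverage of the animal's coarse elements
#'   at u = 0 and u = 1: defended species get sparser (hence more
#'   heterogeneous) large markings. The animal's coarse layer is
#'   independent of its background's coarse draw, so background matching
#'   is imperfect at the coarse scale for defended and undefended species
#'   alike; animal coarse contrast sits fixed at the middle of the range
#'   backgrounds span.
#' @param background_element_size_px blob element size of the background
#'   texture (and of undefended animals, which carry the background's
#'   texture statistics).
#' @param image_size_px,pixels_per_cm,pixel_noise_sd scene parameters
#'   forwarded to [scene_spec()].
#' @param animal_frac full ellipse axes of each animal as a fraction of the
#'   image (macro framing: the animal fills most of the frame).
#' @param obs the [observer()].
#' @param seed master seed; per-scene substreams are derived from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_species = 13,
                        class_counts = c(NR = 3, II = 4, I_II = 6),
                        individuals_per_species = NULL,
                        effect_gain = 1.5,
                        sparseness_gain = 0.8,
                        coarse_contrast_span = 3,
                        bg_jitter = 0.2,
                        bg_coarse_range = c(0.05, 0.3),
                        animal_coarse_coverage = c(0.35, 0.08),
                        background_element_size_px = 4,
                        fine_pattern_for_defended = TRUE,
                        fine_element_size_px = 3,
                        image_size_px = 64,
                        pixels_per_cm = 50,
                        pixel_noise_sd = 0.05,
                        animal_frac = c(0.72, 0.46),
                        obs = observer(),
                        seed = 1L) {
  if (n_species < 3) stop("need at least 3 species")
  if (sum(class_counts) != n_species)
    stop("class_counts must sum to n_species")
  if (any(class_counts < 1))
    stop("at least one species per class is required")
  if (effect_gain < 0) stop("effect_gain must be >= 0 (monotone effect map)")
  if (is.null(individuals_per_species)) {
    ips <- NULL # resolved at generation time
  } else {
    ips <- rep_len(as.integer(individuals_per_species), n_species)
    if (any(ips < 1)) stop("individuals_per_species must be >= 1")
  }
  structure(list(n_species = as.integer(n_species),
                 class_counts = class_counts,
                 individuals_per_species = ips,
                 effect_gain = effect_gain,
                 sparseness_gain = sparseness_gain,
                 coarse_contrast_span = coarse_contrast_span,
                 bg_jitter = bg_jitter,
                 bg_coarse_range = bg_coarse_range,
                 animal_coarse_coverage = animal_coarse_coverage,
                 background_element_size_px = background_element_size_px,
                 fine_pattern_for_defended = fine_pattern_for_defended,
                 fine_element_size_px = fine_element_size_px,
                 image_size_px = as.integer(image_size_px),
                 pixels_per_cm = pixels_per_cm,
                 pixel_noise_sd = pixel_noise_sd,
                 animal_frac = animal_frac,
                 obs = obs, seed = seed),
            class = "cohort_spec")
}

# default per-species sample sizes of the 13-species design
default_species_n <- c(24, 21, 17, 15, 27, 15, 15, 25, 10, 8, 23, 8, 18)

# unpalatability ranges by class severity; jittered draws are range-normalized
class_u_range <- list(NR = c(0, 0.1), II = c(0.45, 0.7), I_II = c(0.65, 1))

#' Generate a synthetic species cohort
#'
#' Draws species-level parameters from a [cohort_spec()], realizes one scene
#' per individual, and returns the scenes plus the species metadata table
#' (species, defence class, unpalatability u on [0, 1] with observed
#' endpoints 0 and 1, per the 1 - ED50 range-normalized convention).
#'
#' @param cspec a [cohort_spec()].
#' @return list with `scenes` (list of per-individual lists: `image`,
#'   `masks`, `individual_id`, `species`, `defence_class`, `unpalatability`)
#'   and `metadata` (one-row-per-species data frame).
#' @export
generate_cohort <- function(cspec) {
  stopifnot(inherits(cspec, "cohort_spec"))
  with_seed(cspec$seed, {
    classes <- rep(names(cspec$class_counts), cspec$class_counts)
    ns <- cspec$n_species
    u_raw <- vapply(classes, function(cl) {
      r <- class_u_range[[cl]]
      if (is.null(r)) stop("unknown defence class: ", cl)
      stats::runif(1, r[1], r[2])
    }, numeric(1))
    u <- range_normalize(u_raw)
    species <- sprintf("sp%02d", seq_len(ns))
    ips <- cspec$individuals_per_species
    if (is.null(ips)) {
      ips <- if (ns == length(default_species_n)) default_species_n
             else sample(8:27, ns, replace = TRUE)
    }

    base <- scene_spec(obs = cspec$obs)$background
    metadata <- data.frame(species = species, defence_class = classes,
                           unpalatability = u, n_individuals = ips,
                           stringsAsFactors = FALSE, row.names = NULL)

    g <- cspec$effect_gain
    scenes <- list()
    idx <- 0L
    for (s in seq_len(ns)) {
      us <- u[s]
      for (i in seq_len(ips[s])) {
        idx <- idx + 1L
        # each individual sits on its own natural background: jittered
        # contrasts and a variable amount of coarse large-scale structure
        jit <- function(x) x * stats::runif(1, 1 - cspec$bg_jitter,
                                            1 + cspec$bg_jitter)
        span <- cspec$coarse_contrast_span
        bg_scene <- list(
          element_size_px = cspec$background_element_size_px,
          phase_fraction = 0.5,
          chromatic_contrast = jit(base$chromatic_contrast),
          achromatic_contrast = jit(base$achromatic_contrast),
          coarse_phase_fraction = stats::runif(1, cspec$bg_coarse_range[1],
                                               cspec$bg_coarse_range[2]),
          coarse_chromatic_contrast = base$chromatic_contrast *
            stats::runif(1, 1, span),
          coarse_achromatic_contrast = base$achromatic_contrast *
            stats::runif(1, 1, span))
        # monotone effect map: the fine layer interpolates from the
        # background's own statistics (u = 0: matching) to a sparse, fine,
        # high-contrast defended phenotype. Coarse large-scale markings are
        # an independent draw for every animal and every background —
        # matching is imperfect at the coarse scale for all species — with
        # the defended coarse contrast rising through the same range the
        # backgrounds span, so bold rims survive far-distance blur without
        # standing outside the background distribution.
        animal <- list(
          size_px = round(cspec$animal_frac * cspec$image_size_px),
          element_size_px = if (cspec$fine_pattern_for_defended)
            (1 - us) * bg_scene$element_size_px +
              us * cspec$fine_element_size_px
          else bg_scene$element_size_px,
          phase_fraction = 0.5 * (1 - cspec$sparseness_gain * us),
          chromatic_contrast = bg_scene$chromatic_contrast * (1 + g * us),
          achromatic_contrast = bg_scene$achromatic_contrast * (1 + g * us),
          coarse_phase_fraction = (1 - us) * cspec$animal_coarse_coverage[1] +
            us * cspec$animal_coarse_coverage[2],
          coarse_chromatic_contrast = base$chromatic_contrast *
            (1 + (span - 1) / 2),
          coarse_achromatic_contrast = base$achromatic_contrast *
            (1 + (span - 1) / 2),
          boundary_contrast = 0)
        sp <- scene_spec(
          image_size_px = cspec$image_size_px,
          pixels_per_cm = cspec$pixels_per_cm,
          obs = cspec$obs,
          background = bg_scene,
          animal = animal,
          pixel_noise_sd = cspec$pixel_noise_sd,
          seed = derive_seed(cspec$seed, idx))
        sc <- generate_scene(sp)
        scenes[[idx]] <- list(image = sc$image, masks = sc$masks,
                              individual_id = sprintf("%s_i%02d", species[s], i),
                              species = species[s], defence_class = classes[s],
                              unpalatability = u[s], scene_spec = sp)
      }
    }
    list(scenes = scenes, metadata = metadata)
  })
}

#' Process a cohort into a pattern-record table
#'
#' Runs [distance_profile()] on every scene of a generated cohort.
#'
#' @param cohort output of [generate_cohort()].
#' @param obs an [observer()].
#' @param distances_cm viewing-distance grid (default `c(2, 5, 10, 30)`).
#' @param config processing config forwarded to [distance_profile()].
#' @return A tidy data frame: one row per individual x distance.
#' @export
process_cohort <- function(cohort, obs = observer(),
                           distances_cm = c(2, 5, 10, 30), config = list()) {
  recs <- lapply(cohort$scenes, function(sc)
    distance_profile(sc$image, sc$masks, obs, distances_cm,
                     individual_id = sc$individual_id, species = sc$species,
                     defence_class = sc$defence_class,
                     unpalatability = sc$unpalatability, config = config))
  do.call(rbind, recs)
}
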