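#' Pattern boldness (within-animal edge-contrast CoV)
#'
#' Boldness is the strength of a colour-pattern signal once detection has
#' taken place: the abundance-weighted coefficient of variation of the
#' animal's own local edge contrast, computed separately on the achromatic
#' (`Lum.CoV`) and chromatic (`Col.CoV`) channels and ignoring the
#' background entirely.
#'
#' @param animal_map an [local_edge_map()] built from the animal mask.
#' @return named numeric vector `c(lum_boldness=, col_boldness=)`; either
#'   entry is `NA` (with a warning) when the corresponding CoV is undefined
#'   (flat region).
#' @export
boldness <- function(animal_map) {
  stopifnot(inherits(animal_map, "edge_contrast_map"))
  c(lum_boldness = weighted_cov(animal_map$achromatic, animal_map$weight),
    col_boldness = weighted_cov(animal_map$chromatic, animal_map$weight))
}

#' Pattern detectability (background matching)
#'
#' Detectability is the absolute difference between the abundance-weighted
#' CoV of local edge contrast of the animal and that of its visual
#' background, per channel type: \eqn{|CoV_{animal} - CoV_{background}|}.
#' Low values mean the animal's edge-contrast statistics match the
#' background's, i.e. background matching.
#'
#' @param animal_map,background_map [local_edge_map()]s from the same
#'   processed scene at the same viewing distance.
#' @return named numeric vector `c(lum_detectability=, col_detectability=)`;
#'   `NA` where either CoV is undefined.
#' @export
detectability <- function(animal_map, background_map) {
  stopifnot(inherits(animal_map, "edge_contrast_map"),
            inherits(background_map, "edge_contrast_map"))
  ba <- boldness(animal_map)
  bb <- c(weighted_cov(background_map$achromatic, background_map$weight),
          weighted_cov(background_map$chromatic, background_map$weight))
  c(lum_detectability = abs(unname(ba[1]) - bb[1]),
    col_detectability = abs(unname(ba[2]) - bb[2]))
}

#' Distance profile of one scene
#'
#' Runs the full perceptual chain at every viewing distance in the grid —
#' acuity blur, RNL ranked filtering, LEIA edge maps for the animal and the
#' background ROI — and assembles one pattern record per distance carrying
#' the boldness and detectability statistics. Records whose CoV is undefined
#' (flat region after filtering) are dropped with a warning, not imputed.
#'
#' @param img a [cone_catch_image()] (unprocessed scene).
#' @param masks a [region_masks()] pair for the scene.
#' @param obs an [observer()].
#' @param distances_cm viewing distances in cm (default `c(2, 5, 10, 30)`).
#' @param individual_id,species,defence_class,unpalatability metadata copied
#'   into each record; `defence_class` is one of `"NR"`, `"II"`, `"I_II"`.
#' @param config optional list overriding processing defaults:
#'   `acuity$k_cycle_to_sigma`, `ranked_filter$radius_px`,
#'   `ranked_filter$n_iter`, `ranked_filter$keep_fraction`, `leia$block_px`.
#' @return A data frame (one row per distance that survived) with columns
#'   `individual_id`, `species`, `defence_class`, `unpalatability`,
#'   `distance_cm`, `lum_boldness`, `col_boldness`, `lum_detectability`,
#'   `col_detectability`.
#' @export
distance_profile <- function(img, masks, obs, distances_cm = c(2, 5, 10, 30),
                             individual_id = "ind1", species = "sp1",
                             defence_class = NA_character_,
                             unpalatability = NA_real_,
                             config = list()) {
  stopifnot(inherits(masks, "region_masks"))
  if (any(distances_cm <= 0)) stop("viewing distances must be > 0")
  if (is.unsorted(distances_cm)) stop("viewing distances must be sorted")
  k_sig <- config$acuity$k_cycle_to_sigma %||% 2
  radius <- config$ranked_filter$radius_px %||% 2L
  n_iter <- config$ranked_filter$n_iter %||% 5L
  keep <- config$ranked_filter$keep_fraction %||% 0.5
  block <- config$leia$block_px %||% 2L

  rows <- vector("list", length(distances_cm))
  for (i in seq_along(distances_cm)) {
    d <- distances_cm[i]
    rec <- tryCatch({
      proc <- acuity_blur(img, obs, d, k_cycle_to_sigma = k_sig)
      proc <- rnl_ranked_filter(proc, obs, radius_px = radius,
                                n_iter = n_iter, keep_fraction = keep)
      amap <- local_edge_map(proc, obs, masks$animal, block_px = block,
                             region_label = "animal")
      bmap <- local_edge_map(proc, obs, masks$background, block_px = block,
                             region_label = "background")
      bo <- boldness(amap)
      de <- detectability(amap, bmap)
      data.frame(individual_id = individual_id, species = species,
                 defence_class = defence_class,
                 unpalatability = unpalatability, distance_cm = d,
                 lum_boldness = unname(bo[1]), col_boldness = unname(bo[2]),
                 lum_detectability = unname(de[1]),
                 col_detectability = unname(de[2]),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      stop(sprintf("distance %g cm, individual '%s': %s",
                   d, individual_id, conditionMessage(e)), call. = FALSE)
    })
    if (anyNA(rec[c("lum_boldness", "col_boldness",
                    "lum_detectability", "col_detectability")])) {
      warning(sprintf("dropping record for individual '%s' at %g cm: undefined CoV",
                      individual_id, d))
      rows[i] <- list(NULL)
    } else {
      rows[[i]] <- rec
    }
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
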