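#' Construct a cone-catch image stack
#'
#' The unit every perceptual operator consumes: an H x W x (n+1) array of
#' linear receptor stimulation values — n chromatic channels followed by one
#' luminance channel — plus a spatial calibration in pixels per cm. Values
#' must be non-negative; because the RNL model works on log ratios, a
#' positivity floor is applied (dark pixels are clipped to
#' `floor_frac * max(channel)` per channel).
#'
#' @param stack numeric array `H x W x (n_channels)`; the last channel is
#'   luminance.
#' @param pixels_per_cm spatial calibration (> 0).
#' @param floor_frac positivity floor as a fraction of each channel's maximum
#'   (default `1e-6`). Set to `NA` to skip flooring (values must then already
#'   be strictly positive).
#' @return An object of class `cone_catch`: the floored array with attributes
#'   `pixels_per_cm`.
#' @examples
#' img <- cone_catch_image(array(runif(8 * 8 * 4, 0.1, 1), c(8, 8, 4)),
#'                         pixels_per_cm = 10)
#' dim(img)
#' @export
cone_catch_image <- function(stack, pixels_per_cm, floor_frac = 1e-6) {
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stop("stack must be a 3-d array H x W x channels")
  if (dim(stack)[3] < 3L)
    stop("stack needs at least 2 chromatic channels plus a luminance channel")
  if (!is.finite(pixels_per_cm) || pixels_per_cm <= 0)
    stop("pixels_per_cm must be > 0")
  if (any(!is.finite(stack)) || any(stack < 0))
    stop("cone-catch values must be finite and non-negative")
  if (!is.na(floor_frac)) {
    for (ch in seq_len(dim(stack)[3])) {
      mx <- max(stack[, , ch])
      if (mx <= 0)
        stop("channel ", ch, " is identically zero; cannot floor to positivity")
      stack[, , ch] <- pmax(stack[, , ch], floor_frac * mx)
    }
  }
  if (any(stack <= 0))
    stop("cone-catch values must be strictly positive after flooring")
  structure(stack, pixels_per_cm = as.numeric(pixels_per_cm),
            class = "cone_catch")
}

#' @export
print.cone_catch <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("cone-catch stack: %d x %d px, %d chromatic + 1 luminance channel(s), %.3g px/cm\n",
              d[1], d[2], d[3] - 1L, attr(x, "pixels_per_cm")))
  invisible(x)
}

pixels_per_cm <- function(img) attr(img, "pixels_per_cm")

n_chromatic <- function(img) dim(img)[3] - 1L

check_image_observer <- function(img, obs) {
  if (n_chromatic(img) != n_receptors(obs))
    stop(sprintf("image has %d chromatic channels but the observer has %d",
                 n_chromatic(img), n_receptors(obs)))
  invisible(TRUE)
}

#' Pair of region masks for one scene
#'
#' @param animal,background logical matrices (same dimensions as the scene's
#'   image plane); `TRUE`/nonzero marks membership. The two regions must not
#'   overlap and the animal mask must be nonempty.
#' @return An object of class `region_masks` (list with `animal`,
#'   `background`).
#' @export
region_masks <- function(animal, background) {
  animal <- as_mask(animal, "animal")
  background <- as_mask(background, "background")
  if (!identical(dim(animal), dim(background)))
    stop("animal and background masks differ in size")
  if (!any(animal)) stop("animal mask is empty")
  if (!any(background)) stop("background mask is empty")
  if (any(animal & background))
    stop("animal and background masks overlap")
  structure(list(animal = animal, background = background),
            class = "region_masks")
}

as_mask <- function(m, name) {
  if (is.logical(m) && is.matrix(m)) return(m)
  if (is.matrix(m)) return(m != 0)
  stop(name, " mask must be a matrix (logical or numeric)")
}

#' @export
print.region_masks <- function(x, ...) {
  cat(sprintf("region masks %d x %d px: animal %d px, background %d px\n",
              nrow(x$animal), ncol(x$animal), sum(x$animal), sum(x$background)))
  invisible(x)
}
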