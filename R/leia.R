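#' Local Edge Intensity Analysis (LEIA)
#'
#' Computes per-location chromatic and achromatic edge contrast within a
#' masked region. The image is tiled into non-overlapping
#' `block_px x block_px` blocks (channelwise block means, roughly the scale of
#' an edge-detecting receptive field); for every block whose centre pixel lies
#' in the mask, RNL \eqn{\Delta S} is computed against the forward neighbour
#' along each of four axes — horizontal, vertical and the two diagonals —
#' whenever that neighbour's centre also lies in the mask. The per-location
#' value is the mean over available axes and the location's abundance weight
#' is the number of axes that contributed; blocks with no valid axis are
#' excluded.
#'
#' Forward neighbours only are used, so no block pair is counted twice.
#' Trailing rows/columns that do not fill a whole block are ignored.
#'
#' @param img a [cone_catch_image()] (normally after [acuity_blur()] and
#'   [rnl_ranked_filter()]).
#' @param obs an [observer()].
#' @param mask logical matrix, same image plane as `img`; nonzero = member.
#' @param block_px block edge length in pixels (default 2).
#' @param region_label label stored with the map (`"animal"` or
#'   `"background"`).
#' @return An `edge_contrast_map`: a data frame with one row per retained
#'   location and columns `row`, `col` (block indices), `chromatic`,
#'   `achromatic` (mean \eqn{\Delta S} over axes), `weight` (axis count) and
#'   `region`.
#' @seealso [weighted_cov()], [boldness()], [detectability()]
#' @export
local_edge_map <- function(img, obs, mask, block_px = 2L,
                           region_label = "animal") {
  stopifnot(inherits(img, "cone_catch"))
  check_image_observer(img, obs)
  mask <- as_mask(mask, "region")
  if (!identical(dim(mask), dim(img)[1:2]))
    stop("mask dimensions do not match the image plane")
  if (!any(mask)) stop("region mask is empty")
  b <- as.integer(block_px)
  if (b < 1L) stop("block_px must be >= 1")
  nbr <- nrow(mask) %/% b
  nbc <- ncol(mask) %/% b
  if (nbr < 2L || nbc < 2L)
    stop("block_px too large for this region: fewer than 2 blocks per side")

  # mask-aware block means: only in-mask pixels contribute, so the map is a
  # function of the region's own pixels (an animal map cannot depend on
  # background values leaking into rim blocks)
  C <- dim(img)[3]
  counts <- block_sum(mask * 1.0, b, nbr, nbc)
  bm <- array(NA_real_, c(nbr, nbc, C))
  for (ch in seq_len(C)) {
    s <- block_sum(img[, , ch] * mask, b, nbr, nbc)
    bm[, , ch] <- ifelse(counts > 0, s / pmax(counts, 1), NA_real_)
  }

  co <- ceiling(b / 2)
  in_mask <- mask[(seq_len(nbr) - 1L) * b + co, (seq_len(nbc) - 1L) * b + co,
                  drop = FALSE]
  if (!any(in_mask)) stop("no block centres fall inside the mask")

  lf <- log(bm)
  nc <- C - 1L
  A <- rnl_noise_matrix(obs)

  chrom_sum <- matrix(0, nbr, nbc)
  achrom_sum <- matrix(0, nbr, nbc)
  n_axes <- matrix(0L, nbr, nbc)
  # forward neighbour per axis: horizontal, vertical, diagonal, anti-diagonal
  offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (off in offsets) {
    ri <- seq_len(nbr - off[1])
    ci <- if (off[2] >= 0L) seq_len(nbc - off[2]) else seq.int(1L - off[2], nbc)
    rj <- ri + off[1]
    cj <- ci + off[2]
    ok <- in_mask[ri, ci, drop = FALSE] & in_mask[rj, cj, drop = FALSE]
    if (!any(ok)) next
    df <- matrix(0, length(ri) * length(ci), nc)
    for (ch in seq_len(nc))
      df[, ch] <- as.vector(lf[ri, ci, ch] - lf[rj, cj, ch])
    chrom <- sqrt(pmax(0, rowSums((df %*% A) * df)))
    achrom <- abs(as.vector(lf[ri, ci, C] - lf[rj, cj, C])) / obs$luminance_weber
    chrom <- matrix(chrom, length(ri), length(ci))
    achrom <- matrix(achrom, length(ri), length(ci))
    chrom[!ok] <- 0
    achrom[!ok] <- 0
    chrom_sum[ri, ci] <- chrom_sum[ri, ci] + chrom
    achrom_sum[ri, ci] <- achrom_sum[ri, ci] + achrom
    n_axes[ri, ci] <- n_axes[ri, ci] + ok
  }

  keep <- in_mask & n_axes > 0L
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(
    row = idx[, 1], col = idx[, 2],
    chromatic = chrom_sum[keep] / n_axes[keep],
    achromatic = achrom_sum[keep] / n_axes[keep],
    weight = n_axes[keep],
    region = region_label,
    stringsAsFactors = FALSE)
  class(out) <- c("edge_contrast_map", class(out))
  attr(out, "block_px") <- b
  attr(out, "grid") <- c(nbr, nbc)
  out
}

block_sum <- function(x, b, nbr, nbc) {
  y <- x[seq_len(nbr * b), seq_len(nbc * b), drop = FALSE]
  z <- colSums(array(y, c(b, nbr * nbc * b)))        # sum within-block rows
  z <- array(z, c(nbr, b, nbc))
  zz <- colSums(aperm(z, c(2L, 1L, 3L)))             # sum within-block cols
  matrix(zz, nbr, nbc)
}

#' Abundance-weighted coefficient of variation
#'
#' Weighted CoV = weighted population standard deviation / weighted mean,
#' using frequency-style weights: \eqn{\mu = \sum w x / \sum w},
#' \eqn{\sigma^2 = \sum w (x-\mu)^2 / \sum w}. The population (biased)
#' variance convention is used deliberately and is scale-free in the weights
#' (doubling every weight changes nothing).
#'
#' A flat region (weighted mean 0, e.g. a uniform animal whose edge map is
#' all zeros) has no defined CoV: the function warns and returns `NA_real_`,
#' the flagged-undefined value that downstream record assembly drops.
#'
#' @param values non-negative values (edge \eqn{\Delta S} per location).
#' @param weights non-negative abundance weights, same length.
#' @return The CoV (dimensionless scalar), or `NA_real_` with a warning for a
#'   zero-mean input.
#' @examples
#' weighted_cov(c(1, 3), c(1, 1)) # mean 2, population sd 1 -> 0.5
#' @export
weighted_cov <- function(values, weights = rep(1, length(values))) {
  if (length(values) != length(weights))
    stop("values and weights differ in length")
  pos <- weights > 0
  if (sum(pos) < 2L)
    stop("need at least 2 locations with positive weight")
  v <- values[pos]; w <- weights[pos]
  if (any(!is.finite(v)) || any(v < 0)) stop("values must be finite and >= 0")
  m <- sum(w * v) / sum(w)
  if (m <= 0) {
    warning("weighted mean is 0 (flat region); CoV undefined, returning NA")
    return(NA_real_)
  }
  sqrt(sum(w * (v - m)^2) / sum(w)) / m
}
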