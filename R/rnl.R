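#' @useDynLib distsig, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Receptor-noise quadratic form. For log-contrasts df_i = ln(q_a,i / q_b,i),
# the chromatic distance satisfies dS^2 = df' A df with
#   A = W - w w' / s,   W = diag(1/e_i^2),  w = W 1,  s = 1' W 1.
# This is algebraically identical to the classical n-receptor ratio of sums
# (pairwise (df_i - df_j)^2 form) but is O(n^2) and vectorizes over pixels.
rnl_noise_matrix <- function(obs) {
  e2 <- obs$weber_fractions^2
  w <- 1 / e2
  diag(w, nrow = length(w)) - tcrossprod(w) / sum(w)
}

# (n-1) x n factor B with A = B'B; rows are an orthogonal noise-scaled
# log-opponent basis. Any orthonormal choice is fine: only distances are
# consumed downstream.
rnl_basis <- function(obs) {
  A <- rnl_noise_matrix(obs)
  ev <- eigen(A, symmetric = TRUE)
  k <- length(obs$weber_fractions) - 1L
  vals <- ev$values[seq_len(k)]
  t(ev$vectors[, seq_len(k), drop = FALSE]) * sqrt(vals)
}

check_catch <- function(q, obs, arg = "q") {
  q <- as.numeric(q)
  if (length(q) != n_receptors(obs))
    stop(sprintf("catch vector '%s' has length %d but the observer has %d chromatic channels",
                 arg, length(q), n_receptors(obs)))
  bad <- which(!is.finite(q) | q <= 0)
  if (length(bad))
    stop(sprintf("catch vector '%s' must be strictly positive; offending channel(s): %s",
                 arg, paste(bad, collapse = ", ")))
  q
}

#' Chromatic contrast between two stimuli (RNL \eqn{\Delta S})
#'
#' Perceptual chromatic distance between two cone-catch vectors under the
#' log-linear receptor-noise-limited model, in just-noticeable-difference
#' units. With per-channel log contrasts \eqn{\Delta f_i = \ln(q_{a,i}/q_{b,i})}
#' and Weber fractions \eqn{e_i}, the n-receptor distance is
#' \deqn{\Delta S^2 = \frac{\sum_{i<j} (\Delta f_i-\Delta f_j)^2 \prod_{k \ne i,j} e_k^2}
#'                         {\sum_i \prod_{k \ne i} e_k^2},}
#' evaluated here through the equivalent noise-weighted quadratic form.
#' \eqn{\Delta S} is symmetric, non-negative, invariant under a common scaling
#' of both stimuli, and zero exactly when the catches are channelwise equal up
#' to a common factor.
#'
#' @param q_a,q_b strictly positive catch vectors, one value per chromatic
#'   channel of `obs`.
#' @param obs an [observer()].
#' @return \eqn{\Delta S} in jnd units (scalar >= 0).
#' @examples
#' obs2 <- observer(weber_fractions = c(0.05, 0.05))
#' chromatic_delta_s(c(0.2, 0.4), c(0.4, 0.4), obs2) # = |ln 0.5|/sqrt(2*0.05^2)
#' @export
chromatic_delta_s <- function(q_a, q_b, obs) {
  q_a <- check_catch(q_a, obs, "q_a")
  q_b <- check_catch(q_b, obs, "q_b")
  df <- log(q_a / q_b)
  A <- rnl_noise_matrix(obs)
  sqrt(max(0, drop(df %*% A %*% df)))
}

#' Achromatic contrast between two luminances (RNL \eqn{\Delta S})
#'
#' Log-Weber luminance contrast: \eqn{\Delta S = |\ln(l_a/l_b)| / \omega}
#' where \eqn{\omega} is the observer's luminance Weber fraction.
#'
#' @param l_a,l_b strictly positive luminance (luminance-channel catch) values.
#' @param obs an [observer()].
#' @return \eqn{\Delta S} in jnd units (scalar >= 0). Vectorized over
#'   `l_a`/`l_b`.
#' @examples
#' achromatic_delta_s(2, 1, observer(luminance_weber = 0.05)) # ln(2)/0.05
#' @export
achromatic_delta_s <- function(l_a, l_b, obs) {
  if (any(!is.finite(l_a)) || any(l_a <= 0) || any(!is.finite(l_b)) || any(l_b <= 0))
    stop("luminances must be strictly positive")
  abs(log(l_a / l_b)) / obs$luminance_weber
}

#' Coordinates of a stimulus in RNL chromaticity space
#'
#' Maps a catch vector to a point in the (n-1)-dimensional receptor-noise
#' chromaticity space such that the Euclidean distance between the coordinates
#' of any two stimuli equals their [chromatic_delta_s()]. The basis is an
#' orthogonal noise-scaled log-opponent decomposition; its orientation is
#' arbitrary (only distances are meaningful) but fixed for a given observer.
#'
#' @param q a strictly positive catch vector, or a matrix with one stimulus
#'   per row.
#' @param obs an [observer()].
#' @return A numeric vector of length `n_receptors(obs) - 1`, or a matrix with
#'   one coordinate row per stimulus.
#' @export
rnl_coords <- function(q, obs) {
  B <- rnl_basis(obs)
  if (is.matrix(q)) {
    if (ncol(q) != n_receptors(obs))
      stop("stimulus matrix must have one column per chromatic channel")
    if (any(!is.finite(q)) || any(q <= 0))
      stop("catch values must be strictly positive")
    t(B %*% t(log(q)))
  } else {
    q <- check_catch(q, obs)
    drop(B %*% log(q))
  }
}
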