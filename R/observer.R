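#' Define a receptor-noise-limited observer
#'
#' An observer bundles everything the perceptual operators need to know about
#' the receiver of a visual signal: per-channel chromatic receptor noise
#' (Weber fractions \eqn{e_i}), luminance-channel noise \eqn{\omega}, and
#' spatial acuity in cycles per degree (cpd). Discrimination thresholds in the
#' RNL model are set entirely by the Weber fractions; acuity sets the scale of
#' the distance-dependent Gaussian blur.
#'
#' The default observer is a trichromat with chromatic Weber fractions
#' (0.05, 0.05, 0.05), luminance Weber fraction 0.05 and an acuity of 3 cpd,
#' in line with values commonly used for the triggerfish
#' \emph{Rhinecanthus aculeatus} in the visual-ecology literature. These are
#' literature-derived defaults, not measurements made by this package; every
#' field is overridable here or via [read_observer()].
#'
#' @param weber_fractions numeric vector of per-channel chromatic Weber
#'   fractions \eqn{e_i} (dimensionless, all > 0); its length defines the
#'   number of chromatic receptor channels (must be >= 2).
#' @param luminance_weber luminance-channel Weber fraction \eqn{\omega} (> 0).
#' @param acuity_cpd spatial acuity in cycles/degree (> 0).
#' @return An object of class `rnl_observer`.
#' @seealso [weber_from_abundance()] to derive \eqn{e_i} from relative
#'   receptor abundances, [chromatic_delta_s()], [acuity_blur()].
#' @examples
#' obs <- observer()
#' obs
#' dichromat <- observer(weber_fractions = c(0.05, 0.05))
#' @export
observer <- function(weber_fractions = c(0.05, 0.05, 0.05),
                     luminance_weber = 0.05,
                     acuity_cpd = 3) {
  weber_fractions <- as.numeric(weber_fractions)
  if (length(weber_fractions) < 2L)
    stop("an RNL observer needs at least 2 chromatic receptor channels")
  if (any(!is.finite(weber_fractions)) || any(weber_fractions <= 0))
    stop("all chromatic Weber fractions must be finite and > 0")
  if (!is.finite(luminance_weber) || luminance_weber <= 0)
    stop("luminance Weber fraction must be finite and > 0")
  if (!is.finite(acuity_cpd) || acuity_cpd <= 0)
    stop("acuity_cpd must be finite and > 0")
  structure(
    list(weber_fractions = weber_fractions,
         luminance_weber = as.numeric(luminance_weber),
         acuity_cpd = as.numeric(acuity_cpd)),
    class = "rnl_observer")
}

#' @export
print.rnl_observer <- function(x, ...) {
  cat("RNL observer:", length(x$weber_fractions), "chromatic channels\n")
  cat("  Weber fractions e_i :", paste(format(x$weber_fractions), collapse = ", "), "\n")
  cat("  luminance Weber w   :", format(x$luminance_weber), "\n")
  cat("  spatial acuity      :", format(x$acuity_cpd), "cpd\n")
  invisible(x)
}

#' Number of chromatic channels of an observer
#' @param obs an [observer()].
#' @return integer channel count.
#' @export
n_receptors <- function(obs) {
  stopifnot(inherits(obs, "rnl_observer"))
  length(obs$weber_fractions)
}

#' Weber fractions from relative receptor abundances
#'
#' Under the standard noise model, the Weber fraction of channel i scales with
#' the noise of a single receptor \eqn{\nu} and the relative abundance
#' \eqn{\eta_i} of that receptor type as \eqn{e_i = \nu / \sqrt{\eta_i}}.
#' The stored observer quantity is always \eqn{e_i}; this helper only performs
#' the conversion for users who parameterize via cone ratios.
#'
#' @param abundances relative receptor abundances \eqn{\eta_i} (> 0); only
#'   ratios matter.
#' @param noise single-receptor noise \eqn{\nu} (> 0).
#' @param reference_channel channel whose abundance is used to normalize, so
#'   that the reference channel gets \eqn{e = \nu}. Default: the most abundant.
#' @return numeric vector of Weber fractions, same length as `abundances`.
#' @examples
#' # classic 1:2:2 cone ratio, most-abundant channel at e = 0.05
#' weber_from_abundance(c(1, 2, 2), noise = 0.05)
#' @export
weber_from_abundance <- function(abundances, noise = 0.05,
                                 reference_channel = which.max(abundances)) {
  abundances <- as.numeric(abundances)
  if (any(!is.finite(abundances)) || any(abundances <= 0))
    stop("abundances must be finite and > 0")
  if (!is.finite(noise) || noise <= 0)
    stop("noise must be finite and > 0")
  rel <- abundances / abundances[reference_channel]
  noise / sqrt(rel)
}

#' Read an observer definition from a config file
#'
#' Reads the `observer` section of a YAML or JSON configuration file with keys
#' `observer.weber_fractions`, `observer.luminance_weber`,
#' `observer.acuity_cpd`. Keys missing from the file keep the package
#' defaults (see [observer()]).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return An `rnl_observer`.
#' @export
read_observer <- function(path) {
  cfg <- read_config(path)
  observer_from_config(cfg)
}

observer_from_config <- function(cfg) {
  o <- cfg$observer
  if (is.null(o)) return(observer())
  defaults <- observer()
  observer(
    weber_fractions = o$weber_fractions %||% defaults$weber_fractions,
    luminance_weber = o$luminance_weber %||% defaults$luminance_weber,
    acuity_cpd      = o$acuity_cpd %||% defaults$acuity_cpd)
}
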