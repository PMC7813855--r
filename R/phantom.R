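#' Reflector phantoms
#'
#' A reflector phantom is the sample model of the forward simulator: a set
#' of discrete partial reflectors at optical path depths `z` [m] with
#' intensity reflectivities `reflectivity` in [0, 1] and an optional
#' interferometric phase (0 or pi encodes the folded scatterer phase as a
#' signed field amplitude). Depths beyond the comb ambiguity range are
#' permitted -- depth folding of such reflectors is precisely what the
#' subsampled reconstruction is designed to exhibit.
#'
#' @param z Optical path depths [m], non-negative.
#' @param reflectivity Intensity reflectivities in [0, 1].
#' @param phase Interferometric phase per reflector [rad] (default 0).
#' @param n_tissue Refractive index, metadata for geometric-depth reporting.
#' @return Object of class `reflector_phantom`: data frame `reflectors`
#'   (columns `z`, `reflectivity`, `phase`) plus `n_tissue`.
#' @examples
#' reflector_phantom(c(30e-6, 80e-6), c(1e-4, 5e-5))
#' @export
reflector_phantom <- function(z, reflectivity, phase = 0, n_tissue = 1) {
  check_nonnegative(z, "z")
  if (any(reflectivity < 0) || any(reflectivity > 1)) {
    stop("`reflectivity` must lie in [0, 1]", call. = FALSE)
  }
  if (length(reflectivity) != length(z)) {
    stop("`z` and `reflectivity` must have equal length", call. = FALSE)
  }
  phase <- rep_len(phase, length(z))
  if (n_tissue < 1) stop("`n_tissue` must be >= 1", call. = FALSE)
  structure(
    list(reflectors = data.frame(z = z, reflectivity = reflectivity,
                                 phase = phase),
         n_tissue = n_tissue),
    class = "reflector_phantom")
}

#' @exportS3Method print reflector_phantom
print.reflector_phantom <- function(x, ...) {
  cat(sprintf("<reflector_phantom: %d reflectors, n_tissue = %.3g>\n",
              nrow(x$reflectors), x$n_tissue))
  invisible(x)
}

#' Single-mirror phantom
#'
#' The calibration sample: one reflector at depth `z`, as used to measure
#' the axial point spread function and sensitivity roll-off.
#'
#' @param z Optical path depth of the mirror [m].
#' @param reflectivity Intensity reflectivity (default 1).
#' @inheritParams reflector_phantom
#' @export
make_mirror <- function(z, reflectivity = 1, n_tissue = 1) {
  if (length(z) != 1L || z < 0) {
    stop("`z` must be a single non-negative depth", call. = FALSE)
  }
  reflector_phantom(z, reflectivity, n_tissue = n_tissue)
}

#' Layered phantom
#'
#' One reflector per layer at distinct depths; exercises multi-reflector
#' linearity and, with a strong layer beyond the ambiguity range, the
#' folded artifacts produced by reflections from optics or a coverslide
#' below the sample.
#'
#' @param depths Distinct layer depths [m].
#' @param reflectivities Per-layer reflectivities in [0, 1].
#' @inheritParams reflector_phantom
#' @export
make_layered <- function(depths, reflectivities, n_tissue = 1) {
  if (anyDuplicated(depths)) {
    stop("`depths` must be distinct", call. = FALSE)
  }
  reflector_phantom(depths, reflectivities, n_tissue = n_tissue)
}

#' Stochastic speckle-tissue phantom
#'
#' Emulates weakly scattering tissue as Poisson-positioned random-phase
#' point scatterers per lateral position (A-line), with optional bright
#' linear inclusions spanning the lateral field (fibre-like structures over
#' dim background). Scatterer phases, uniform on \eqn{[0, 2\pi)}, are
#' folded into signed field amplitudes via the per-reflector `phase` field
#' (0 or \eqn{\pi}).
#'
#' @param depth_extent Axial extent of the scattering slab [m].
#' @param scatterer_density Expected scatterers per metre of depth per
#'   A-line.
#' @param reflectivity_scale Mean intensity reflectivity of a scatterer
#'   (exponentially distributed).
#' @param n_lateral Number of lateral positions (A-lines).
#' @param fiber_inclusions Optional data frame with columns `z` and
#'   `reflectivity`: bright reflectors inserted at every lateral position.
#' @param z_offset Depth of the slab surface [m].
#' @param seed Integer seed; generation is fully reproducible.
#' @return Object of class `speckle_phantom`: a list of
#'   `reflector_phantom`s (one per A-line) with attributes `seed` and
#'   `ground_truth`.
#' @export
make_speckle_tissue <- function(depth_extent, scatterer_density,
                                reflectivity_scale = 1e-5, n_lateral = 64,
                                fiber_inclusions = NULL, z_offset = 10e-6,
                                seed = NULL) {
  check_positive(depth_extent, "depth_extent")
  check_positive(scatterer_density, "scatterer_density")
  check_positive(reflectivity_scale, "reflectivity_scale")
  lam <- scatterer_density * depth_extent
  phantoms <- with_local_seed(seed, {
    lapply(seq_len(n_lateral), function(i) {
      k <- stats::rpois(1, lam)
      z <- z_offset + sort(stats::runif(k, 0, depth_extent))
      r <- pmin(1, stats::rexp(k, rate = 1 / reflectivity_scale))
      ph <- ifelse(stats::runif(k) < 0.5, 0, pi)
      if (!is.null(fiber_inclusions)) {
        z <- c(z, fiber_inclusions$z)
        r <- c(r, fiber_inclusions$reflectivity)
        ph <- c(ph, rep(0, nrow(fiber_inclusions)))
      }
      if (length(z) == 0) {
        z <- z_offset; r <- 0; ph <- 0  # empty A-line: dark reflector
      }
      reflector_phantom(z, r, ph)
    })
  })
  structure(phantoms, class = "speckle_phantom", seed = seed,
            ground_truth = list(depth_extent = depth_extent,
                                scatterer_density = scatterer_density,
                                reflectivity_scale = reflectivity_scale,
                                z_offset = z_offset,
                                fiber_inclusions = fiber_inclusions,
                                seed = seed))
}

#' @exportS3Method print speckle_phantom
print.speckle_phantom <- function(x, ...) {
  counts <- vapply(x, function(p) nrow(p$reflectors), integer(1))
  cat(sprintf("<speckle_phantom: %d A-lines, %.1f scatterers/line on average>\n",
              length(x), mean(counts)))
  invisible(x)
}
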