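# Forward model: source spectrum + reflector phantom -> spectrometer counts.
#
# Every source is decomposed into narrow spectral components (comb lines, or
# a fine uniform-wavenumber sampling of a continuous density). Each
# component carries the interferometric modulation evaluated at its exact
# wavenumber and is then spread over neighbouring pixels by the Gaussian
# pixel response of FWHM delta_k_ccd. Comb lines are spectrally unresolved
# (linewidth << delta_k_ccd), so the fringe does not decay within a line --
# the physical origin of the comb's immunity to pixel-response roll-off.

# Decompose a source into spectral components within the spectrometer band.
source_components <- function(source, sp, oversample = 2L) {
  margin <- 4 * sp$delta_k_ccd
  k_lo <- min(sp$pixel_wavenumbers) - margin
  k_hi <- max(sp$pixel_wavenumbers) + margin
  if (inherits(source, "comb_spectrum")) {
    k <- source$line_frequencies / .c0
    keep <- k >= k_lo & k <= k_hi
    if (!any(keep)) {
      stop("source spectrum does not overlap the spectrometer band",
           call. = FALSE)
    }
    list(wavenumber = k[keep], power = source$line_powers[keep],
         line_index = source$line_index[keep], discrete = TRUE)
  } else if (inherits(source, "continuous_spectrum")) {
    lam_src <- source$wavelength_grid
    k_src_lo <- max(k_lo, 1 / max(lam_src))
    k_src_hi <- min(k_hi, 1 / min(lam_src))
    if (k_src_hi <= k_src_lo) {
      stop("source spectrum does not overlap the spectrometer band",
           call. = FALSE)
    }
    n_comp <- oversample * sp$n_pixels
    k <- seq(k_src_lo, k_src_hi, length.out = n_comp)
    dk <- k[2] - k[1]
    lam <- 1 / k
    dens <- stats::approx(lam_src, source$power_density, xout = lam,
                          yleft = 0, yright = 0)$y
    # P = integral of dens dlambda ; dlambda = lambda^2 dk
    p <- dens * lam^2 * dk
    keep <- p > 0
    list(wavenumber = k[keep], power = p[keep],
         line_index = rep(NA_integer_, sum(keep)), discrete = FALSE)
  } else {
    stop("unsupported source type", call. = FALSE)
  }
}

# Pixel response matrix: n_pixels x n_components, Gaussian in wavenumber
# truncated at +/- 4 FWHM, column-normalized so each component's power is
# conserved on the grid. Sparse: each component only reaches the few
# pixels within its response footprint.
pixel_response_matrix <- function(sp, k_comp) {
  dk <- sp$delta_k_ccd
  kp <- sp$pixel_wavenumbers
  o <- order(kp)
  kps <- kp[o]
  half <- 4 * dk
  lo <- findInterval(k_comp - half, kps) + 1L
  hi <- findInterval(k_comp + half, kps)
  seg <- pmax(hi - lo + 1L, 0L)
  idx <- sequence(seg) + rep(lo - 1L, seg)
  rows <- o[idx]
  cols <- rep.int(seq_along(k_comp), seg)
  vals <- exp(-4 * log(2) * ((kp[rows] - k_comp[cols]) / dk)^2)
  tot <- rep.int(1, length(k_comp))
  sums <- rowsum(vals, cols)
  tot[as.integer(rownames(sums))] <- ifelse(sums == 0, 1, sums)
  Matrix::sparseMatrix(i = rows, j = cols, x = vals / tot[cols],
                       dims = c(length(kp), length(k_comp)))
}

# Interferometric modulation of each spectral component for a phantom.
component_modulation <- function(k_comp, phantom, reference_reflectivity) {
  rs <- phantom$reflectors
  m <- rep(reference_reflectivity + sum(rs$reflectivity), length(k_comp))
  for (i in seq_len(nrow(rs))) {
    m <- m + 2 * sqrt(reference_reflectivity * rs$reflectivity[i]) *
      cos(4 * pi * k_comp * rs$z[i] + rs$phase[i])
  }
  m
}

#' Source-power gain placing the reference DC at half full well
#'
#' The camera operating point of the simulator: the source power is scaled
#' by a gain such that the brightest pixel of the reference-arm-only
#' spectrum sits at 50 % of the full-well capacity. Computed once per
#' acquisition geometry so that repeated acquisitions share an exposure.
#'
#' @param source A `comb_spectrum` or `continuous_spectrum`.
#' @param sp A [spectrometer()].
#' @param reference_reflectivity Effective reference-arm reflectivity.
#' @return Dimensionless gain factor.
#' @export
exposure_gain <- function(source, sp, reference_reflectivity = 0.05) {
  comps <- source_components(source, sp)
  w <- pixel_response_matrix(sp, comps$wavenumber)
  e_fac <- sp$integration_time * sp$quantum_efficiency /
    (.h_planck * .c0 * sp$pixel_wavenumbers)
  ref <- e_fac * as.numeric(w %*% (comps$power * reference_reflectivity))
  0.5 * sp$full_well_capacity / max(ref)
}

#' Simulate a B-scan of spectrometer interferograms
#'
#' Forward model of SD-OCT acquisition. Per spectral component of
#' wavenumber \eqn{\tilde\nu} and power \eqn{S}, the detected spectral
#' power is
#' \deqn{I(\tilde\nu) = S(\tilde\nu)\Big[R_r + \textstyle\sum_s R_s +
#'   2 \sum_s \sqrt{R_r R_s}\cos(4\pi\tilde\nu z_s + \phi_s)\Big],}
#' spread over pixels by the Gaussian response of FWHM
#' \eqn{\delta k_{\mathrm{CCD}}}, converted to photoelectrons with the
#' integration time and quantum efficiency, and clipped at the full-well
#' capacity. Source intensity noise enters through a [noise_model()] as one
#' common-mode multiplicative draw per acquisition plus independent
#' per-line (per-component, for continuous sources) draws; detector shot
#' noise (Gaussian approximation of Poisson) and read noise are added when
#' a noise model is supplied. With `model = NULL` the acquisition is fully
#' deterministic.
#'
#' @param source A `comb_spectrum` or `continuous_spectrum`.
#' @param phantom A `reflector_phantom` (static across the B-scan), a
#'   `speckle_phantom`, or a list of `reflector_phantom`s, one per A-scan.
#' @param sp A [spectrometer()].
#' @param n_ascans Number of A-scans (acquisitions) in the B-scan.
#' @param reference_reflectivity Effective reference-arm reflectivity.
#' @param model Optional [noise_model()].
#' @param seed Integer seed for all stochastic terms.
#' @param gain Source-power gain; defaults to [exposure_gain()] so the
#'   reference DC sits at half full well.
#' @return Object of class `bscan`: `counts` (pixels x A-scans, electrons),
#'   `wavelength`, `wavenumber`, `spectrometer`, and `meta` (gain, seed,
#'   saturation flag, source FSR when discrete).
#' @examples
#' comb <- make_dks_spectrum(229e12, fsr = 1e12, n_lines = 41,
#'                           bandwidth_3db = 8.3e12, total_power = 2e-3)
#' b <- simulate_bscan(comb, make_mirror(30e-6, 1e-3), spectrometer(),
#'                     n_ascans = 4)
#' @export
simulate_bscan <- function(source, phantom, sp, n_ascans = 1L,
                           reference_reflectivity = 0.05, model = NULL,
                           seed = NULL, gain = NULL) {
  stopifnot(inherits(sp, "spectrometer"))
  check_positive(reference_reflectivity, "reference_reflectivity")
  n_ascans <- as.integer(n_ascans)
  if (n_ascans < 1) stop("`n_ascans` must be >= 1", call. = FALSE)
  phantoms <- if (inherits(phantom, "reflector_phantom")) {
    rep(list(phantom), n_ascans)
  } else if (inherits(phantom, "speckle_phantom") || is.list(phantom)) {
    if (length(phantom) != n_ascans) {
      stop("list phantom must supply one `reflector_phantom` per A-scan",
           call. = FALSE)
    }
    phantom
  } else {
    stop("unsupported phantom type", call. = FALSE)
  }
  comps <- source_components(source, sp)
  w <- pixel_response_matrix(sp, comps$wavenumber)
  e_fac <- sp$integration_time * sp$quantum_efficiency /
    (.h_planck * .c0 * sp$pixel_wavenumbers)
  if (is.null(gain)) {
    ref <- e_fac * as.numeric(w %*% (comps$power * reference_reflectivity))
    gain <- 0.5 * sp$full_well_capacity / max(ref)
  }
  n_comp <- length(comps$wavenumber)
  static <- inherits(phantom, "reflector_phantom")
  m_static <- if (static) {
    component_modulation(comps$wavenumber, phantoms[[1]],
                         reference_reflectivity)
  } else NULL
  tau <- sp$integration_time
  if (is.null(seed) && !is.null(model)) seed <- model$seed
  counts <- with_local_seed(seed, {
    pm <- matrix(0, n_comp, n_ascans)
    for (i in seq_len(n_ascans)) {
      m <- if (static) m_static else {
        component_modulation(comps$wavenumber, phantoms[[i]],
                             reference_reflectivity)
      }
      base <- comps$power * m
      if (!is.null(model)) {
        bw <- 1 / (2 * tau)
        xc <- stats::rnorm(1, sd = sqrt(model$common_mode_rin_psd * bw))
        xi <- if (model$per_line_rin_psd > 0) {
          stats::rnorm(n_comp, sd = sqrt(model$per_line_rin_psd * bw))
        } else 0
        base <- base * (1 + xc + xi)
      }
      pm[, i] <- base
    }
    e <- as.matrix(w %*% pm) * gain * e_fac
    if (!is.null(model)) {
      if (model$include_shot_noise) {
        e <- e + stats::rnorm(length(e), sd = sqrt(pmax(e, 0)))
      }
      if (sp$read_noise > 0) {
        e <- e + stats::rnorm(length(e), sd = sp$read_noise)
      }
    }
    e
  })
  saturated <- any(counts > sp$full_well_capacity)
  counts <- pmin(pmax(counts, 0), sp$full_well_capacity)
  counts <- matrix(counts, sp$n_pixels, n_ascans)
  structure(
    list(counts = counts,
         wavelength = sp$pixel_wavelengths,
         wavenumber = sp$pixel_wavenumbers,
         spectrometer = sp,
         meta = list(tau = tau, gain = gain, seed = seed,
                     saturated = saturated,
                     reference_reflectivity = reference_reflectivity,
                     fsr = if (inherits(source, "comb_spectrum"))
                       source$fsr else NULL)),
    class = "bscan")
}

#' Simulate a single spectrometer interferogram
#'
#' Convenience wrapper around [simulate_bscan()] for one acquisition.
#'
#' @inheritParams simulate_bscan
#' @return Object of class `interferogram`: `counts` (electron vector),
#'   `wavelength`, `wavenumber`, `spectrometer`, `meta`.
#' @export
simulate_interferogram <- function(source, phantom, sp,
                                   reference_reflectivity = 0.05,
                                   model = NULL, seed = NULL, gain = NULL) {
  b <- simulate_bscan(source, phantom, sp, n_ascans = 1L,
                      reference_reflectivity = reference_reflectivity,
                      model = model, seed = seed, gain = gain)
  as_interferogram(b$counts[, 1], b$wavelength, b$wavenumber,
                   b$spectrometer, b$meta)
}

as_interferogram <- function(counts, wavelength, wavenumber, sp, meta) {
  structure(
    list(counts = counts, wavelength = wavelength, wavenumber = wavenumber,
         spectrometer = sp, meta = meta),
    class = "interferogram")
}

#' @exportS3Method print interferogram
print.interferogram <- function(x, ...) {
  cat(sprintf("<interferogram: %d pixels, max %.3g e-%s>\n",
              length(x$counts), max(x$counts),
              if (isTRUE(x$meta$saturated)) ", SATURATED" else ""))
  invisible(x)
}

#' @exportS3Method print bscan
print.bscan <- function(x, ...) {
  cat(sprintf("<bscan: %d pixels x %d A-scans%s>\n",
              nrow(x$counts), ncol(x$counts),
              if (isTRUE(x$meta$saturated)) ", SATURATED" else ""))
  invisible(x)
}
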