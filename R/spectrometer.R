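#' Define a grating-spectrometer measurement operator
#'
#' Describes the CCD spectrometer of an SD-OCT system: a pixel grid uniform
#' in wavelength (the standard grating geometry; uniform wavenumber is
#' obtained downstream by [resample_to_k()]), a Gaussian spectral response
#' per pixel of full width `delta_k_ccd` in spectroscopic wavenumber
#' \eqn{\tilde\nu = 1/\lambda}, a full-well capacity, integration time,
#' quantum efficiency and read noise.
#'
#' @param n_pixels Number of detector pixels (default 2048).
#' @param lambda_min,lambda_max Wavelength span [m]; ignored when
#'   `pixel_wavelengths` is given.
#' @param pixel_wavelengths Optional explicit, strictly monotone pixel
#'   wavelength axis [m].
#' @param delta_k_ccd Spectral response FWHM \eqn{\delta k_{\mathrm{CCD}}}
#'   in wavenumber [1/m]. The default 125 1/m yields a single-sided imaging
#'   range of 2 mm (see [max_imaging_depth()]).
#' @param full_well_capacity Pixel full-well capacity [electrons].
#' @param integration_time Camera integration time \eqn{\tau} [s]; the
#'   default corresponds to a 46 kHz A-scan rate.
#' @param quantum_efficiency Detector quantum efficiency (0-1).
#' @param read_noise RMS read noise [electrons].
#' @return Object of class `spectrometer`.
#' @examples
#' sp <- spectrometer()
#' max_imaging_depth(sp)  # 2 mm
#' @export
spectrometer <- function(n_pixels = 2048, lambda_min = 1235e-9,
                         lambda_max = 1385e-9, pixel_wavelengths = NULL,
                         delta_k_ccd = 125, full_well_capacity = 2e5,
                         integration_time = 1 / 46e3,
                         quantum_efficiency = 0.8, read_noise = 20) {
  check_positive(delta_k_ccd, "delta_k_ccd")
  check_positive(full_well_capacity, "full_well_capacity")
  check_positive(integration_time, "integration_time")
  check_positive(quantum_efficiency, "quantum_efficiency")
  check_nonnegative(read_noise, "read_noise")
  if (is.null(pixel_wavelengths)) {
    if (n_pixels < 2) stop("`n_pixels` must be at least 2", call. = FALSE)
    check_positive(lambda_min, "lambda_min")
    if (lambda_max <= lambda_min) {
      stop("`lambda_max` must exceed `lambda_min`", call. = FALSE)
    }
    pixel_wavelengths <- seq(lambda_min, lambda_max, length.out = n_pixels)
  } else {
    if (length(pixel_wavelengths) < 2 ||
        is.unsorted(pixel_wavelengths, strictly = TRUE)) {
      stop("`pixel_wavelengths` must be strictly increasing with >= 2 pixels",
           call. = FALSE)
    }
    n_pixels <- length(pixel_wavelengths)
  }
  structure(
    list(n_pixels = as.integer(n_pixels),
         pixel_wavelengths = pixel_wavelengths,
         pixel_wavenumbers = 1 / pixel_wavelengths,
         delta_k_ccd = delta_k_ccd,
         full_well_capacity = full_well_capacity,
         integration_time = integration_time,
         quantum_efficiency = quantum_efficiency,
         read_noise = read_noise),
    class = "spectrometer")
}

#' Construct a spectrometer with pixels uniform in wavenumber
#'
#' Convenience constructor for idealized analyses in which no k-space
#' resampling is wanted: pixels are placed on a uniform grid of
#' spectroscopic wavenumber \eqn{\tilde\nu = 1/\lambda}.
#'
#' @param k_min,k_max Wavenumber span [1/m].
#' @inheritParams spectrometer
#' @export
spectrometer_uniform_k <- function(n_pixels = 2048, k_min, k_max, ...) {
  if (k_max <= k_min) stop("`k_max` must exceed `k_min`", call. = FALSE)
  k <- seq(k_min, k_max, length.out = n_pixels)
  spectrometer(pixel_wavelengths = rev(1 / k), ...)
}

#' @exportS3Method print spectrometer
print.spectrometer <- function(x, ...) {
  cat("<spectrometer>\n")
  cat(sprintf("  %d pixels, %.1f-%.1f nm, delta_k = %.3g 1/m\n",
              x$n_pixels, min(x$pixel_wavelengths) * 1e9,
              max(x$pixel_wavelengths) * 1e9, x$delta_k_ccd))
  cat(sprintf("  FWC %.3g e-, tau %.3g us, QE %.2f, read noise %.3g e-\n",
              x$full_well_capacity, x$integration_time * 1e6,
              x$quantum_efficiency, x$read_noise))
  cat(sprintf("  max imaging depth %.3g mm\n", max_imaging_depth(x) * 1e3))
  invisible(x)
}

#' Maximum single-sided imaging depth of a spectrometer
#'
#' The Nyquist-limited single-sided depth window of SD-OCT,
#' \deqn{\pm z_{\max} = \pm \frac{1}{4\,\delta k_{\mathrm{CCD}}},}
#' set by the spectrometer's spectral resolution \eqn{\delta k_{\mathrm{CCD}}}
#' expressed in spectroscopic wavenumber.
#'
#' @param x A `spectrometer`, or a numeric `delta_k_ccd` value [1/m].
#' @return Depth \eqn{z_{\max}} in metres.
#' @examples
#' max_imaging_depth(125)  # 2 mm
#' @export
max_imaging_depth <- function(x) {
  dk <- if (inherits(x, "spectrometer")) x$delta_k_ccd else x
  check_positive(dk, "delta_k_ccd")
  1 / (4 * dk)
}

#' Ambiguity range of a comb-illuminated OCT system
#'
#' Discrete comb illumination makes the tomogram periodic in depth with
#' period
#' \deqn{z_{\mathrm{ambiguity}} = \frac{c}{2 n_{\mathrm{tissue}}
#'   f_{\mathrm{rep}}},}
#' the basis of optical-domain subsampling (circular ranging). Because the
#' magnitude tomogram of a real interferogram cannot distinguish a depth
#' from its complex-conjugate mirror, the unambiguous single-sided window
#' is half this period; set `halve_for_conjugate = TRUE` to report that
#' convention instead.
#'
#' @param f_rep Comb repetition rate / free spectral range [Hz].
#' @param n_tissue Refractive index used to convert optical to geometric
#'   depth (default 1, i.e. optical path).
#' @param halve_for_conjugate Report the conjugate-resolved half window.
#' @return Depth period in metres.
#' @examples
#' ambiguity_range(1e12) * 1e6     # ~150 um
#' ambiguity_range(100e9) * 1e3    # ~1.5 mm
#' @export
ambiguity_range <- function(f_rep, n_tissue = 1, halve_for_conjugate = FALSE) {
  check_positive(f_rep, "f_rep")
  if (n_tissue < 1) stop("`n_tissue` must be >= 1", call. = FALSE)
  check_flag(halve_for_conjugate, "halve_for_conjugate")
  z <- .c0 / (2 * n_tissue * f_rep)
  if (halve_for_conjugate) z <- z / 2
  z
}

#' Photon degeneracy factor of a spectrometer channel
#'
#' The classical design requirement of SD-OCT with thermal-like sources is
#' a large photon degeneracy factor
#' \deqn{\delta = \frac{\mathrm{FWC}}{\delta\nu \cdot \tau},}
#' the number of detectable photons per optical mode within one integration:
#' excess photon noise is negligible only when \eqn{\delta \gg 1}. For a
#' comb source each line is a narrowband laser with Poissonian statistics,
#' so this requirement does not apply.
#'
#' @param full_well_capacity Full-well capacity [electrons].
#' @param delta_nu Spectral resolution of one channel in optical frequency
#'   [Hz].
#' @param tau Integration time [s].
#' @return Dimensionless degeneracy factor.
#' @examples
#' photon_degeneracy(2e5, 20e9, 21.7e-6)  # ~0.46
#' @export
photon_degeneracy <- function(full_well_capacity, delta_nu, tau) {
  check_positive(full_well_capacity, "full_well_capacity")
  check_positive(delta_nu, "delta_nu")
  check_positive(tau, "tau")
  full_well_capacity / (delta_nu * tau)
}

#' Depth-dependent sensitivity roll-off of a spectrometer
#'
#' The finite spectral response of each pixel (Gaussian of FWHM
#' \eqn{\delta k}) washes out high-frequency fringes, attenuating the
#' reconstructed amplitude with depth as the Fourier transform of the
#' response evaluated at the fringe frequency \eqn{2z} (a depth-\eqn{z}
#' reflector fringes at \eqn{2z} cycles per unit wavenumber):
#' \deqn{a(z) = \exp\!\left(-\frac{\pi^2 \delta k^2 z^2}{\ln 2}\right),}
#' normalized to 1 at zero depth and monotone non-increasing. Comb
#' illumination evades this roll-off: each line is far narrower than
#' \eqn{\delta k}, so its fringe survives unattenuated.
#'
#' @param x A `spectrometer` or a numeric `delta_k_ccd` [1/m].
#' @param depth_grid Depths at which to evaluate [m]; must not exceed
#'   \eqn{z_{\max}}.
#' @return Amplitude attenuation factors in (0, 1].
#' @export
sensitivity_rolloff <- function(x, depth_grid) {
  dk <- if (inherits(x, "spectrometer")) x$delta_k_ccd else x
  check_positive(dk, "delta_k_ccd")
  check_nonnegative(depth_grid, "depth_grid")
  if (any(depth_grid > max_imaging_depth(dk) * (1 + 1e-12))) {
    stop("`depth_grid` exceeds the maximum imaging depth", call. = FALSE)
  }
  exp(-pi^2 * dk^2 * depth_grid^2 / log(2))
}
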