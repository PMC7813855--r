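#' Shot-noise floor of the relative intensity noise
#'
#' The fundamental RIN floor of a coherent source detected at mean power
#' \eqn{P} is set by photon shot noise,
#' \deqn{\mathrm{RIN}_{\mathrm{shot}} = \frac{2 h \nu}{P},}
#' returned here in dBc/Hz. The floor improves (decreases) with optical
#' power at 3 dB per doubling, in contrast to the beat-noise floor of
#' incoherent sources which is power-independent
#' (see [beat_noise_rin_floor()]).
#'
#' @param mean_power Mean detected optical power [W].
#' @param optical_frequency Optical carrier frequency \eqn{\nu} [Hz].
#' @return Shot-noise RIN floor in dBc/Hz.
#' @examples
#' shot_noise_rin_floor(100e-6, 299792458 / 1300e-9)  # about -145 dBc/Hz
#' shot_noise_rin_floor(20e-6, 299792458 / 1300e-9)   # about -138 dBc/Hz
#' @export
shot_noise_rin_floor <- function(mean_power, optical_frequency) {
  check_positive(mean_power, "mean_power")
  check_positive(optical_frequency, "optical_frequency")
  10 * log10(2 * .h_planck * optical_frequency / mean_power)
}

#' Excess-photon (spontaneous-emission beat) noise floor
#'
#' For a broadband incoherent source of rectangular optical bandwidth
#' \eqn{B_0}, spontaneous-emission beat noise limits the RIN to
#' \deqn{\mathrm{RIN}_{\mathrm{beat}} = 1/B_0} (unpolarized light, two
#' independent polarization modes), independent of detected power. This is
#' the floor that caps the dynamic-range gain of SLD-based SD-OCT at high
#' reference powers.
#'
#' @param optical_bandwidth Rectangular optical bandwidth \eqn{B_0} [Hz].
#' @return Beat-noise RIN floor in dBc/Hz.
#' @examples
#' beat_noise_rin_floor(45e12)  # about -136.5 dBc/Hz
#' @seealso [simulate_thermal_intensity()] for a Monte-Carlo check of this
#'   closed form.
#' @export
beat_noise_rin_floor <- function(optical_bandwidth) {
  check_positive(optical_bandwidth, "optical_bandwidth")
  10 * log10(1 / optical_bandwidth)
}

#' Simulate the intensity of band-limited thermal light
#'
#' Monte-Carlo model of an incoherent (thermal/ASE-like) source: each
#' polarization mode is a circular complex Gaussian field with a flat
#' (rectangular) optical spectrum of width `optical_bandwidth`; the detected
#' power is the summed squared magnitude over modes. The low-frequency RIN
#' plateau of the resulting trace is \eqn{2/(n_{\mathrm{modes}} B_0)}, i.e.
#' \eqn{1/B_0} for unpolarized light (`n_modes = 2`), providing an
#' independent simulation oracle for [beat_noise_rin_floor()].
#'
#' @param optical_bandwidth Rectangular optical bandwidth \eqn{B_0} [Hz].
#' @param sampling_rate Sampling rate of the intensity trace [Sa/s]; must be
#'   at least \eqn{2 B_0} so the rectangular optical band is representable.
#'   The RIN plateau is read at frequencies well below \eqn{B_0}.
#' @param n_samples Number of intensity samples to generate.
#' @param mean_power Mean detected power [W].
#' @param n_modes Number of independent polarization/spatial modes (2 =
#'   unpolarized).
#' @param seed Integer seed.
#' @return A numeric vector of detected power samples [W] with attribute
#'   `sampling_rate`.
#' @export
simulate_thermal_intensity <- function(optical_bandwidth, sampling_rate,
                                       n_samples, mean_power = 1e-3,
                                       n_modes = 2, seed = NULL) {
  check_positive(optical_bandwidth, "optical_bandwidth")
  check_positive(sampling_rate, "sampling_rate")
  check_positive(mean_power, "mean_power")
  if (n_samples < 64) stop("`n_samples` must be at least 64", call. = FALSE)
  if (sampling_rate < 2 * optical_bandwidth) {
    stop("`sampling_rate` must be at least twice `optical_bandwidth`",
         call. = FALSE)
  }
  n <- as.integer(n_samples)
  n_keep <- max(2L, round(optical_bandwidth / sampling_rate * n))
  with_local_seed(seed, {
    intens <- numeric(n)
    for (m in seq_len(n_modes)) {
      spec <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
      mask <- rep(0, n)
      mask[seq_len(n_keep)] <- 1  # rectangular optical band
      field <- stats::fft(spec * mask, inverse = TRUE) / sqrt(n)
      intens <- intens + Mod(field)^2
    }
    intens <- intens / mean(intens) * mean_power
    attr(intens, "sampling_rate") <- sampling_rate
    intens
  })
}
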