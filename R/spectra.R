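#' Construct a dissipative-Kerr-soliton comb spectrum
#'
#' Builds the discrete line spectrum of a single-soliton Kerr comb. Line
#' frequencies follow the resonator dispersion expansion
#' \deqn{\nu_\mu = \nu_0 + f_{\mathrm{rep}}\,\mu + \tfrac{1}{2} d_2 \mu^2,}
#' where \eqn{\mu} is the integer mode offset from the pumped line,
#' \eqn{f_{\mathrm{rep}}} the repetition rate (equal to the resonator free
#' spectral range) and \eqn{d_2} the second-order dispersion per mode
#' (\eqn{D_2/2\pi}). Line powers follow the characteristic sech-squared
#' soliton envelope
#' \deqn{P_\mu \propto \mathrm{sech}^2\!\big((\nu_\mu - \nu_0)/\Delta\nu_S\big),}
#' scaled so that the total power before pump suppression equals
#' `total_power`. The pump line is then attenuated by `pump_suppression_db`,
#' modelling the fibre Bragg grating used to reject residual pump light.
#'
#' @param center_frequency Optical frequency of the pumped line \eqn{\nu_0} [Hz].
#' @param fsr Free spectral range / repetition rate [Hz].
#' @param d2 Second-order dispersion per mode, \eqn{D_2/2\pi} [Hz]. Default 0
#'   gives an exactly equidistant comb.
#' @param n_lines Odd number of comb lines (pump plus symmetric sidebands).
#' @param bandwidth_3db Full width at half maximum of the power envelope [Hz];
#'   must exceed `fsr`.
#' @param total_power Total optical power summed over lines, before pump
#'   suppression [W].
#' @param pump_suppression_db Attenuation applied to the pump line [dB].
#' @param line_linewidth Optical linewidth of each comb line [Hz]; metadata
#'   only (comb lines are treated as spectrally unresolved by any realistic
#'   spectrometer).
#'
#' @return An object of class `comb_spectrum` with fields `center_frequency`,
#'   `line_index`, `line_frequencies`, `line_powers`, `line_linewidth`,
#'   `envelope_kind` and `fsr`.
#'
#' @examples
#' comb <- make_dks_spectrum(229e12, fsr = 1e12, n_lines = 41,
#'                           bandwidth_3db = 8.3e12, total_power = 2e-3)
#' sum(comb$line_powers)
#' @seealso [make_mi_spectrum()], [make_sld_spectrum()],
#'   [transform_limited_duration()]
#' @export
make_dks_spectrum <- function(center_frequency, fsr, d2 = 0, n_lines,
                              bandwidth_3db, total_power,
                              pump_suppression_db = 0,
                              line_linewidth = 1e5) {
  check_positive(center_frequency, "center_frequency")
  check_positive(fsr, "fsr")
  check_positive(bandwidth_3db, "bandwidth_3db")
  check_positive(total_power, "total_power")
  check_nonnegative(pump_suppression_db, "pump_suppression_db")
  if (n_lines < 3 || n_lines %% 2 == 0) {
    stop("`n_lines` must be odd and at least 3", call. = FALSE)
  }
  if (bandwidth_3db <= fsr) {
    stop("`bandwidth_3db` must exceed `fsr` (envelope wider than one line)",
         call. = FALSE)
  }
  mu <- seq.int(-(n_lines - 1L) / 2L, (n_lines - 1L) / 2L)
  nu <- center_frequency + fsr * mu + 0.5 * d2 * mu^2
  # sech^2 half-power points sit at +/- acosh(sqrt(2)) * dnu_s
  dnu_s <- bandwidth_3db / (2 * acosh(sqrt(2)))
  p <- 1 / cosh((nu - center_frequency) / dnu_s)^2
  p <- p / sum(p) * total_power
  p[mu == 0L] <- p[mu == 0L] * 10^(-pump_suppression_db / 10)
  new_comb_spectrum(center_frequency, mu, nu, p, line_linewidth,
                    "sech2", fsr)
}

#' Construct a chaotic modulation-instability comb spectrum
#'
#' Phenomenological model of a chaotic (modulation-instability, MI) Kerr
#' comb: a nominally flat envelope with seeded, log-uniform per-line power
#' deviations of at most `ripple_db`, emulating the local power variations
#' caused by avoided mode crossings. Only the mean spectrum is modelled
#' here; the strongly elevated, per-line-independent intensity noise of the
#' MI state is supplied separately through [noise_model()]
#' (see [mi_noise_model()]).
#'
#' @inheritParams make_dks_spectrum
#' @param ripple_db Maximum per-line deviation from flat, in dB (one-sided).
#' @param seed Integer seed making the ripple reproducible.
#' @return A `comb_spectrum` with `envelope_kind = "flat_chaotic"`.
#' @examples
#' mi <- make_mi_spectrum(229e12, fsr = 1e12, n_lines = 41,
#'                        total_power = 2e-3, ripple_db = 3, seed = 1)
#' diff(range(10 * log10(mi$line_powers)))  # <= 6 dB peak-to-peak
#' @export
make_mi_spectrum <- function(center_frequency, fsr, n_lines, total_power,
                             ripple_db = 3, seed = NULL,
                             line_linewidth = NA_real_) {
  check_positive(center_frequency, "center_frequency")
  check_positive(fsr, "fsr")
  check_positive(total_power, "total_power")
  check_nonnegative(ripple_db, "ripple_db")
  if (n_lines < 3 || n_lines %% 2 == 0) {
    stop("`n_lines` must be odd and at least 3", call. = FALSE)
  }
  mu <- seq.int(-(n_lines - 1L) / 2L, (n_lines - 1L) / 2L)
  nu <- center_frequency + fsr * mu
  dev_db <- with_local_seed(seed, stats::runif(n_lines, -ripple_db, ripple_db))
  p <- 10^(dev_db / 10)
  p <- p / sum(p) * total_power
  new_comb_spectrum(center_frequency, mu, nu, p, line_linewidth,
                    "flat_chaotic", fsr)
}

new_comb_spectrum <- function(center_frequency, mu, nu, p, linewidth,
                              kind, fsr) {
  stopifnot(!is.unsorted(nu, strictly = TRUE), all(p >= 0))
  structure(
    list(center_frequency = center_frequency,
         line_index = as.integer(mu),
         line_frequencies = nu,
         line_powers = p,
         line_linewidth = linewidth,
         envelope_kind = kind,
         fsr = fsr),
    class = "comb_spectrum")
}

#' @exportS3Method print comb_spectrum
print.comb_spectrum <- function(x, ...) {
  cat(sprintf("<comb_spectrum: %s>\n", x$envelope_kind))
  cat(sprintf("  %d lines, FSR %.4g GHz, pump at %.6g THz (%.1f nm)\n",
              length(x$line_index), x$fsr / 1e9, x$center_frequency / 1e12,
              .c0 / x$center_frequency * 1e9))
  cat(sprintf("  total power %.4g mW\n", sum(x$line_powers) * 1e3))
  invisible(x)
}

#' Construct a Gaussian superluminescent-diode spectrum
#'
#' Continuous broadband source with a Gaussian power density in wavelength,
#' the standard model for the SLD sources used in 1300-nm SD-OCT.
#'
#' @param center_wavelength Centre wavelength \eqn{\lambda_0} [m].
#' @param bandwidth_fwhm Full width at half maximum in wavelength
#'   \eqn{\delta\lambda} [m].
#' @param total_power Integrated optical power [W].
#' @param grid Optional wavelength grid [m]; must extend at least two FWHM
#'   either side of the centre. Defaults to \eqn{\lambda_0 \pm 2.5\,
#'   \delta\lambda} with 4096 samples.
#' @return An object of class `continuous_spectrum` with fields
#'   `wavelength_grid` [m], `power_density` (spectral power density per unit
#'   wavelength, W/m), `center_wavelength` and `bandwidth`.
#' @examples
#' sld <- make_sld_spectrum(1310e-9, 150e-9, 9.15e-3)
#' @export
make_sld_spectrum <- function(center_wavelength, bandwidth_fwhm, total_power,
                              grid = NULL) {
  check_positive(center_wavelength, "center_wavelength")
  check_positive(bandwidth_fwhm, "bandwidth_fwhm")
  check_positive(total_power, "total_power")
  if (is.null(grid)) {
    grid <- seq(center_wavelength - 2.5 * bandwidth_fwhm,
                center_wavelength + 2.5 * bandwidth_fwhm,
                length.out = 4096L)
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("`grid` must be strictly increasing", call. = FALSE)
  }
  if (min(grid) > center_wavelength - 2 * bandwidth_fwhm ||
      max(grid) < center_wavelength + 2 * bandwidth_fwhm) {
    stop("`grid` too narrow: must cover at least +/- 2 x FWHM around the centre",
         call. = FALSE)
  }
  dens <- exp(-4 * log(2) * (grid - center_wavelength)^2 / bandwidth_fwhm^2)
  # trapezoidal normalization so the integral equals total_power exactly
  area <- sum(diff(grid) * (head(dens, -1) + tail(dens, -1)) / 2)
  dens <- dens / area * total_power
  structure(
    list(wavelength_grid = grid,
         power_density = dens,
         center_wavelength = center_wavelength,
         bandwidth = bandwidth_fwhm),
    class = "continuous_spectrum")
}

#' @exportS3Method print continuous_spectrum
print.continuous_spectrum <- function(x, ...) {
  cat("<continuous_spectrum>\n")
  cat(sprintf("  lambda0 = %.1f nm, FWHM = %.1f nm, power = %.4g mW\n",
              x$center_wavelength * 1e9, x$bandwidth * 1e9,
              spectrum_total_power(x) * 1e3))
  invisible(x)
}

#' Total optical power of a source spectrum
#'
#' Sum of line powers for a comb, trapezoidal integral of the spectral
#' density for a continuous source.
#'
#' @param spectrum A `comb_spectrum` or `continuous_spectrum`.
#' @return Power in watts.
#' @export
spectrum_total_power <- function(spectrum) {
  if (inherits(spectrum, "comb_spectrum")) return(sum(spectrum$line_powers))
  if (inherits(spectrum, "continuous_spectrum")) {
    g <- spectrum$wavelength_grid
    d <- spectrum$power_density
    return(sum(diff(g) * (head(d, -1) + tail(d, -1)) / 2))
  }
  stop("unsupported spectrum type", call. = FALSE)
}

#' Transform-limited pulse duration of a source spectrum
#'
#' Assumes flat spectral phase, inverse-Fourier-transforms the field
#' amplitude (the square root of the spectral power) on an oversampled
#' frequency grid, and returns the full width at half maximum of the
#' resulting temporal intensity profile, with the half-power crossings
#' located by linear interpolation between time samples. For a comb the
#' result is the duration of one pulse of the repetitive train; for a
#' continuous spectrum it is the coherence-limited pulse duration. The
#' frequency grid oversamples the envelope bandwidth at least 16-fold and
#' is zero-padded to at least 2^16 samples.
#'
#' A sech-squared envelope of 3-dB bandwidth \eqn{\Delta\nu} gives
#' \eqn{0.315/\Delta\nu}; a Gaussian gives \eqn{0.441/\Delta\nu}
#' (time-bandwidth products of the respective transform-limited pulses).
#'
#' @param spectrum A `comb_spectrum` or `continuous_spectrum` with at least
#'   three non-zero spectral samples.
#' @return Pulse intensity FWHM in seconds.
#' @examples
#' comb <- make_dks_spectrum(229e12, fsr = 1e12, n_lines = 41,
#'                           bandwidth_3db = 8.3e12, total_power = 2e-3)
#' transform_limited_duration(comb) * 1e15  # ~38 fs
#' @export
transform_limited_duration <- function(spectrum) {
  if (inherits(spectrum, "comb_spectrum")) {
    nu <- spectrum$line_frequencies
    amp <- sqrt(spectrum$line_powers)
    if (sum(amp > 0) < 3) {
      stop("spectrum must contain at least 3 non-zero lines", call. = FALSE)
    }
    env_bw <- envelope_bandwidth(nu, amp^2)
    # grid step divides the FSR so equidistant lines land exactly on bins
    m <- max(1L, ceiling(16 * spectrum$fsr / max(env_bw, spectrum$fsr)))
    df <- spectrum$fsr / m
  } else if (inherits(spectrum, "continuous_spectrum")) {
    lam <- spectrum$wavelength_grid
    nu_raw <- rev(.c0 / lam)
    # density per unit optical frequency: P_nu = P_lambda * lambda^2 / c
    dens_nu <- rev(spectrum$power_density * lam^2 / .c0)
    if (sum(dens_nu > 0) < 3) {
      stop("spectrum must contain at least 3 non-zero samples", call. = FALSE)
    }
    env_bw <- envelope_bandwidth(nu_raw, dens_nu)
    df <- env_bw / 64
    nu <- seq(min(nu_raw), max(nu_raw), by = df)
    amp <- sqrt(pmax(0, stats::approx(nu_raw, dens_nu, xout = nu)$y))
  } else {
    stop("unsupported spectrum type", call. = FALSE)
  }
  if (all(amp == 0)) stop("spectrum is identically zero", call. = FALSE)
  if (inherits(spectrum, "comb_spectrum")) {
    idx <- as.integer(round((nu - min(nu)) / df))
  } else {
    idx <- seq_along(nu) - 1L
  }
  span_bins <- max(idx) + 1L
  n <- 2^max(16L, ceiling(log2(16 * span_bins)))
  field <- complex(real = numeric(n))
  field[idx + 1L] <- field[idx + 1L] + amp
  et <- stats::fft(field, inverse = TRUE)
  intens <- Mod(et)^2
  # centre the (periodic) pulse before measuring its width
  shift <- (n %/% 2L) - (which.max(intens) - 1L)
  intens <- intens[((seq_len(n) - 1L - shift) %% n) + 1L]
  t_axis <- (seq_len(n) - 1L - n %/% 2L) / (n * df)
  # the rotation placed the measured pulse exactly at the centre bin; pin
  # the search there (a comb's periodic pulse train repeats within the
  # window, so the global argmax is ambiguous)
  fwhm_interp(t_axis, intens, i0 = n %/% 2L + 1L)
}

# 3-dB full width of a sampled power envelope (linear interpolation)
envelope_bandwidth <- function(nu, power) {
  fwhm_interp(nu, power)
}
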