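#' Specify the intensity-noise composition of a source
#'
#' Decomposes the classical intensity noise of a multi-line source into a
#' common-mode component, shared by every comb line and modulating the full
#' spectral envelope, and a per-line-independent component, uncorrelated
#' between lines. Both are white relative (multiplicative) fluctuations
#' specified by their one-sided power spectral densities. Photon shot noise
#' can additionally be injected at the detector. Common-mode noise affects
#' only the DC term of a Fourier-domain tomogram, whereas per-line
#' independent noise raises the background at every depth -- the central
#' dichotomy between coherent soliton combs and chaotic/incoherent sources.
#'
#' @param common_mode_rin_psd One-sided PSD of the common-mode relative
#'   fluctuation [1/Hz].
#' @param per_line_rin_psd One-sided PSD of the per-line-independent
#'   relative fluctuation [1/Hz].
#' @param include_shot_noise Add photon shot noise at the detector.
#' @param common_mode_bandwidth_hz Optional band limit of the common-mode
#'   component [Hz]; `NULL` means white up to Nyquist.
#' @param seed Integer seed used by simulators consuming this model.
#' @return An object of class `noise_model`.
#' @examples
#' nm <- noise_model(common_mode_rin_psd = 1e-11, per_line_rin_psd = 0)
#' @seealso [simulate_line_traces()], [noise_model_sigma()],
#'   [mi_noise_model()]
#' @export
noise_model <- function(common_mode_rin_psd = 0, per_line_rin_psd = 0,
                        include_shot_noise = FALSE,
                        common_mode_bandwidth_hz = NULL, seed = NULL) {
  check_nonnegative(common_mode_rin_psd, "common_mode_rin_psd")
  check_nonnegative(per_line_rin_psd, "per_line_rin_psd")
  check_flag(include_shot_noise, "include_shot_noise")
  if (!is.null(common_mode_bandwidth_hz)) {
    check_positive(common_mode_bandwidth_hz, "common_mode_bandwidth_hz")
  }
  structure(
    list(common_mode_rin_psd = common_mode_rin_psd,
         per_line_rin_psd = per_line_rin_psd,
         include_shot_noise = include_shot_noise,
         common_mode_bandwidth_hz = common_mode_bandwidth_hz,
         seed = seed),
    class = "noise_model")
}

#' Build a noise model from per-acquisition standard deviations
#'
#' Convenience constructor converting relative fluctuation standard
#' deviations, defined over a detection bandwidth of \eqn{1/(2\tau)} for an
#' integration time \eqn{\tau}, into the white one-sided PSDs stored in a
#' [noise_model()]. Useful when specifying e.g. "1 % common-mode intensity
#' noise per camera acquisition".
#'
#' @param sigma_common Relative standard deviation of the common-mode
#'   fluctuation per acquisition.
#' @param sigma_line Relative standard deviation of the per-line-independent
#'   fluctuation per acquisition.
#' @param tau Integration time defining the acquisition bandwidth [s].
#' @inheritParams noise_model
#' @export
noise_model_sigma <- function(sigma_common = 0, sigma_line = 0, tau,
                              include_shot_noise = FALSE, seed = NULL) {
  check_nonnegative(sigma_common, "sigma_common")
  check_nonnegative(sigma_line, "sigma_line")
  check_positive(tau, "tau")
  bw <- 1 / (2 * tau)
  noise_model(common_mode_rin_psd = sigma_common^2 / bw,
              per_line_rin_psd = sigma_line^2 / bw,
              include_shot_noise = include_shot_noise, seed = seed)
}

#' Noise model for a chaotic modulation-instability comb
#'
#' The chaotic MI comb state carries intensity noise that is nearly 20 dB
#' above the soliton state and essentially uncorrelated between comb lines.
#' This helper builds the corresponding phenomenological model: purely
#' per-line-independent noise with a PSD `excess_db` above a reference
#' level.
#'
#' @param reference_psd One-sided RIN PSD of the coherent (soliton)
#'   reference state [1/Hz].
#' @param excess_db Noise excess of the chaotic state [dB].
#' @inheritParams noise_model
#' @export
mi_noise_model <- function(reference_psd, excess_db = 20,
                           include_shot_noise = FALSE, seed = NULL) {
  check_positive(reference_psd, "reference_psd")
  noise_model(common_mode_rin_psd = 0,
              per_line_rin_psd = reference_psd * 10^(excess_db / 10),
              include_shot_noise = include_shot_noise, seed = seed)
}

#' @exportS3Method print noise_model
print.noise_model <- function(x, ...) {
  cat("<noise_model>\n")
  cat(sprintf("  common-mode PSD : %.3g /Hz%s\n", x$common_mode_rin_psd,
              if (is.null(x$common_mode_bandwidth_hz)) "" else
                sprintf(" (band-limited to %.3g Hz)",
                        x$common_mode_bandwidth_hz)))
  cat(sprintf("  per-line PSD    : %.3g /Hz\n", x$per_line_rin_psd))
  cat(sprintf("  shot noise      : %s\n",
              if (x$include_shot_noise) "on" else "off"))
  invisible(x)
}

# Fraction of classical (non-shot) relative variance that is common mode,
# within a Nyquist band fs/2.
common_mode_fraction <- function(model, fs) {
  bw_c <- if (is.null(model$common_mode_bandwidth_hz)) fs / 2 else
    min(model$common_mode_bandwidth_hz, fs / 2)
  vc <- model$common_mode_rin_psd * bw_c
  vi <- model$per_line_rin_psd * fs / 2
  if (vc + vi == 0) return(0)
  vc / (vc + vi)
}

#' Simulate detected power traces of individual comb lines
#'
#' Generates the per-line photodetector power traces
#' \deqn{P_\mu(t) = \bar{P}_\mu \left(1 + x_c(t) + x_\mu(t)\right) +
#'   n_{\mathrm{shot}}(t),}
#' where \eqn{x_c} is a common-mode relative fluctuation shared by all lines
#' and \eqn{x_\mu} are independent per-line fluctuations, both white with
#' the PSDs of the supplied [noise_model()] (the common-mode term
#' optionally band-limited). Shot noise, when enabled, is added as a
#' Gaussian term with one-sided PSD \eqn{2 h \nu \bar{P}_\mu}. Traces are
#' band-limited by construction to the Nyquist frequency of the requested
#' sampling rate, mirroring a digitizer with an anti-alias low-pass.
#'
#' @param comb A `comb_spectrum`; one trace per line is produced. Use
#'   `lines` to restrict to a subset.
#' @param model A [noise_model()].
#' @param sampling_rate Samples per second of the recorded traces.
#' @param duration Trace duration [s]; `duration * sampling_rate` must be at
#'   least 16.
#' @param lines Optional integer vector of line indices \eqn{\mu} to
#'   simulate (default: all).
#' @param seed Integer seed (overrides the model's seed if given).
#' @return An object of class `line_traces`: list with `traces` (samples x
#'   lines matrix, watts), `sampling_rate`, `duration`, `line_ids` and
#'   `mean_powers`.
#' @examples
#' comb <- make_dks_spectrum(229e12, fsr = 1e12, n_lines = 5,
#'                           bandwidth_3db = 8.3e12, total_power = 1e-3)
#' nm <- noise_model(common_mode_rin_psd = 1e-10)
#' tr <- simulate_line_traces(comb, nm, 5e5, 0.01, seed = 1)
#' @export
simulate_line_traces <- function(comb, model, sampling_rate, duration,
                                 lines = NULL, seed = NULL) {
  stopifnot(inherits(comb, "comb_spectrum"), inherits(model, "noise_model"))
  check_positive(sampling_rate, "sampling_rate")
  check_positive(duration, "duration")
  n <- floor(duration * sampling_rate)
  if (n < 16) {
    stop("`duration` x `sampling_rate` must give at least 16 samples",
         call. = FALSE)
  }
  if (is.null(lines)) lines <- comb$line_index
  sel <- match(lines, comb$line_index)
  if (anyNA(sel)) stop("unknown line index in `lines`", call. = FALSE)
  pbar <- comb$line_powers[sel]
  nu <- comb$line_frequencies[sel]
  if (is.null(seed)) seed <- model$seed
  nyq <- sampling_rate / 2
  sig_c <- sqrt(model$common_mode_rin_psd *
                  if (is.null(model$common_mode_bandwidth_hz)) nyq else
                    min(model$common_mode_bandwidth_hz, nyq))
  sig_i <- sqrt(model$per_line_rin_psd * nyq)
  traces <- with_local_seed(seed, {
    xc <- stats::rnorm(n, sd = sig_c)
    if (!is.null(model$common_mode_bandwidth_hz) &&
        model$common_mode_bandwidth_hz < nyq) {
      xc <- brickwall_lowpass(xc, sampling_rate, model$common_mode_bandwidth_hz)
      # renormalize: the brickwall keeps the variance at psd * bandwidth
      if (stats::sd(xc) > 0) xc <- xc * sig_c / stats::sd(xc)
    }
    out <- matrix(0, n, length(sel))
    for (j in seq_along(sel)) {
      xi <- if (sig_i > 0) stats::rnorm(n, sd = sig_i) else 0
      tr <- pbar[j] * (1 + xc + xi)
      if (model$include_shot_noise) {
        sd_shot <- sqrt(.h_planck * nu[j] * pbar[j] * sampling_rate)
        tr <- tr + stats::rnorm(n, sd = sd_shot)
      }
      out[, j] <- tr
    }
    out
  })
  structure(
    list(traces = traces, sampling_rate = sampling_rate,
         duration = n / sampling_rate, line_ids = lines,
         mean_powers = pbar),
    class = "line_traces")
}

#' @exportS3Method print line_traces
print.line_traces <- function(x, ...) {
  cat(sprintf("<line_traces: %d lines x %d samples at %.4g Sa/s>\n",
              ncol(x$traces), nrow(x$traces), x$sampling_rate))
  invisible(x)
}

# Zero-phase FFT brickwall low-pass used for band-limited common-mode noise.
brickwall_lowpass <- function(x, fs, cutoff) {
  n <- length(x)
  f <- (seq_len(n) - 1L) / n * fs
  f <- pmin(f, fs - f)  # two-sided frequency magnitude
  xf <- stats::fft(x)
  xf[f > cutoff] <- 0
  Re(stats::fft(xf, inverse = TRUE)) / n
}

#' Relative intensity noise spectrum of a power trace
#'
#' Estimates the relative intensity noise
#' \deqn{\mathrm{RIN}(f) = S_{\delta P}(f) / \langle P \rangle^2}
#' with \eqn{S_{\delta P}} the one-sided Welch PSD (Hann-windowed averaged
#' modified periodograms) of the power fluctuations. The resolution
#' bandwidth is `sampling_rate / segment_length`. Integrating the linear
#' RIN over frequency recovers the relative power variance (within
#' estimator scatter).
#'
#' @param trace Numeric vector of detected power samples, or a
#'   `line_traces` object (first line used unless `line` given).
#' @param sampling_rate Samples per second; taken from the object when
#'   `trace` is a `line_traces`.
#' @param segment_length Welch segment length (samples).
#' @param overlap Fractional segment overlap in [0, 1).
#' @param line For `line_traces` input: which column to analyse.
#' @return Object of class `rin_spectrum`: `frequency` [Hz], `rin` [1/Hz],
#'   `rin_dbc_hz`, `resolution_bandwidth` [Hz], `n_segments`.
#' @examples
#' p <- 1e-3 * (1 + 0.01 * rnorm(4096))
#' r <- rin_spectrum(p, sampling_rate = 1e6, segment_length = 256)
#' @export
rin_spectrum <- function(trace, sampling_rate = NULL, segment_length = 256,
                         overlap = 0.5, line = 1L) {
  if (inherits(trace, "line_traces")) {
    sampling_rate <- trace$sampling_rate
    trace <- trace$traces[, line]
  }
  if (is.null(sampling_rate)) {
    sampling_rate <- attr(trace, "sampling_rate")
  }
  check_positive(sampling_rate, "sampling_rate")
  mp <- mean(trace)
  if (abs(mp) < .Machine$double.eps * max(1, stats::sd(trace))) {
    stop("RIN is undefined for a zero-mean trace", call. = FALSE)
  }
  w <- welch_spectra(trace - mp, fs = sampling_rate,
                     segment_length = segment_length, overlap = overlap)
  rin <- w$sxx / mp^2
  structure(
    list(frequency = w$frequency, rin = rin,
         rin_dbc_hz = 10 * log10(pmax(rin, .Machine$double.xmin)),
         resolution_bandwidth = w$rbw, n_segments = w$n_segments,
         mean_power = mp),
    class = "rin_spectrum")
}

#' @exportS3Method print rin_spectrum
print.rin_spectrum <- function(x, ...) {
  cat(sprintf(
    "<rin_spectrum: %d bins, RBW %.4g Hz, %d segments, median %.1f dBc/Hz>\n",
    length(x$frequency), x$resolution_bandwidth, x$n_segments,
    stats::median(x$rin_dbc_hz)))
  invisible(x)
}

#' @exportS3Method plot rin_spectrum
plot.rin_spectrum <- function(x, ...) {
  graphics::plot(x$frequency, x$rin_dbc_hz, type = "l", log = "x",
                 xlab = "offset frequency [Hz]", ylab = "RIN [dBc/Hz]", ...)
  invisible(x)
}

#' Stitch RIN spectra estimated at several resolution bandwidths
#'
#' Mirrors the instrument practice of sweeping resolution bandwidth and
#' span logarithmically: the trace is analysed once per requested segment
#' length, and each estimate contributes the frequency decade it resolves
#' best (longer segments at low offset frequencies, shorter at high).
#'
#' @inheritParams rin_spectrum
#' @param segment_lengths Decreasing vector of Welch segment lengths.
#' @return A `rin_spectrum` whose `resolution_bandwidth` is a vector
#'   (one value per retained bin).
#' @export
rin_spectrum_stitched <- function(trace, sampling_rate = NULL,
                                  segment_lengths = c(16384, 1024, 64),
                                  overlap = 0.5) {
  segment_lengths <- sort(unique(as.integer(segment_lengths)),
                          decreasing = TRUE)
  spans <- lapply(segment_lengths, function(l) {
    rin_spectrum(trace, sampling_rate, segment_length = l, overlap = overlap)
  })
  rbws <- vapply(spans, function(s) s$resolution_bandwidth, numeric(1))
  # span i covers [4 * rbw_i, 4 * rbw_{i+1}) ; the last runs to Nyquist
  lower <- 4 * rbws
  upper <- c(lower[-1], Inf)
  freq <- numeric(0); rin <- numeric(0); rbw <- numeric(0)
  for (i in seq_along(spans)) {
    keep <- spans[[i]]$frequency >= lower[i] & spans[[i]]$frequency < upper[i]
    freq <- c(freq, spans[[i]]$frequency[keep])
    rin <- c(rin, spans[[i]]$rin[keep])
    rbw <- c(rbw, rep(rbws[i], sum(keep)))
  }
  o <- order(freq)
  structure(
    list(frequency = freq[o], rin = rin[o],
         rin_dbc_hz = 10 * log10(pmax(rin[o], .Machine$double.xmin)),
         resolution_bandwidth = rbw[o],
         n_segments = spans[[length(spans)]]$n_segments,
         mean_power = spans[[1]]$mean_power),
    class = "rin_spectrum")
}

#' Integrated relative power variance of a RIN spectrum
#'
#' Trapezoid-free rectangular integration of the linear RIN over its
#' frequency grid, optionally restricted to a band.
#'
#' @param x A `rin_spectrum`.
#' @param band Optional `c(fmin, fmax)` restriction [Hz].
#' @return Integrated relative variance (dimensionless).
#' @export
integrate_rin <- function(x, band = NULL) {
  stopifnot(inherits(x, "rin_spectrum"))
  keep <- rep(TRUE, length(x$frequency))
  if (!is.null(band)) {
    keep <- x$frequency >= band[1] & x$frequency <= band[2]
  }
  df <- if (length(x$resolution_bandwidth) == 1L) {
    rep(x$resolution_bandwidth, length(x$frequency))
  } else x$resolution_bandwidth
  sum(x$rin[keep] * df[keep])
}
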