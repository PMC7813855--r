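# Shared fixtures: small, fast objects reused across test files.

# 1-THz-FSR soliton comb centred on an exact FSR multiple (229 THz,
# ~1309 nm) so that equidistant comb phases recur exactly over one
# ambiguity range.
fixture_comb <- function(n_lines = 41L, d2 = 0, pump_suppression_db = 0,
                         total_power = 2e-3) {
  make_dks_spectrum(229e12, fsr = 1e12, d2 = d2, n_lines = n_lines,
                    bandwidth_3db = 8.3e12, total_power = total_power,
                    pump_suppression_db = pump_suppression_db)
}

fixture_sld <- function(total_power = 9.15e-3) {
  make_sld_spectrum(1310e-9, 150e-9, total_power)
}

# Default imaging spectrometer: 2048 pixels over 1235-1385 nm, 2 mm range.
fixture_spectrometer <- function(...) {
  spectrometer(...)
}

# Wide, fine spectrometer resolving the full SLD spectrum, for PSF work.
fixture_fine_spectrometer <- function() {
  spectrometer(n_pixels = 8192, lambda_min = 1010e-9, lambda_max = 1610e-9,
               delta_k_ccd = 5, read_noise = 0)
}

# Mean non-DC background power (dB) of a tomogram, excluding the
# DC/autocorrelation ridge (whose width in depth bins is set by the
# envelope bandwidth, here ~3 bins) and the dominant-peak neighbourhood.
tomogram_floor_db <- function(tomo, guard = 2L, dc_guard = 3L) {
  a <- tomo$amplitude
  n <- nrow(a)
  dc_bins <- c(seq_len(dc_guard + 1L), (n - dc_guard + 1L):n)
  ma <- rowMeans(a)
  ma[dc_bins] <- -Inf  # find the signal peak away from the DC ridge
  pk <- which.max(ma)
  excl <- unique(pmin(pmax(c(dc_bins,
                             (pk - guard):(pk + guard),
                             (n + 2L - pk - guard):(n + 2L - pk + guard)),
                           1L), n))
  10 * log10(mean(a[-excl, ]^2))
}
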