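# Reconstruction pipelines: background subtraction algebra, k-space
# resampling, both A-scan methods with the folding oracle, comb-tone
# detection, display post-processing and image metrics.

fake_bscan <- function(counts, sp = fixture_spectrometer(), fsr = 1e12) {
  structure(
    list(counts = counts, wavelength = sp$pixel_wavelengths,
         wavenumber = sp$pixel_wavenumbers, spectrometer = sp,
         meta = list(tau = sp$integration_time, fsr = fsr)),
    class = "bscan")
}

test_that("background subtraction removes the B-scan mean exactly", {
  sp <- fixture_spectrometer()
  base <- as.numeric(scale(rnorm(sp$n_pixels), center = FALSE))
  b <- fake_bscan(matrix(base, sp$n_pixels, 8))
  out <- background_subtract(b)
  expect_equal(max(abs(out$counts)), 0)
  # one bright A-line among N is attenuated by (1 - 1/N)
  n <- 16L
  m <- matrix(0, sp$n_pixels, n)
  m[, 5] <- base
  out2 <- background_subtract(fake_bscan(m))
  expect_equal(out2$counts[, 5], base * (1 - 1 / n), tolerance = 1e-12)
  expect_error(background_subtract(fake_bscan(matrix(base))), "2 A-scans")
})

test_that("the B-scan mean acts as a high-pass at line_rate / N", {
  # the characteristic frequency of per-B-scan mean removal: 46 kHz line
  # rate and 512-line B-scans give ~90 Hz
  expect_equal(46e3 / 512, 89.84, tolerance = 1e-3)
})

test_that("k-space resampling is idempotent on uniform input and removes chirp", {
  sp <- spectrometer_uniform_k(n_pixels = 512, k_min = 7.3e5, k_max = 8e5)
  v <- cos(seq(0, 40 * pi, length.out = 512))
  r <- resample_to_k(v, sp$pixel_wavelengths)
  expect_equal(r$counts, v, tolerance = 1e-10)
  # constant spectrum stays constant
  rc <- resample_to_k(rep(2, 512), fixture_spectrometer(n_pixels = 512)$pixel_wavelengths)
  expect_equal(rc$counts, rep(2, 512), tolerance = 1e-9)
  # pure fringe sampled uniformly in wavelength: resampling restores a
  # transform-limited peak; skipping it leaves a chirp-broadened one
  spl <- fixture_spectrometer()
  k_span <- max(spl$pixel_wavenumbers) - min(spl$pixel_wavenumbers)
  z <- 100 / (2 * k_span)  # an integer number of fringe cycles across the band
  v2 <- cos(4 * pi * spl$pixel_wavenumbers * z)
  res <- resample_to_k(v2, spl$pixel_wavelengths)
  peak_res <- max(Mod(stats::fft(res$counts))[2:1024])
  peak_raw <- max(Mod(stats::fft(v2))[2:1024])
  expect_gt(peak_res, 0.9 * 2048 / 2)   # within 10% of the transform limit
  expect_lt(peak_raw, 0.5 * peak_res)   # chirped: strongly broadened
  expect_error(resample_to_k(v2, sample(spl$pixel_wavelengths)), "monotone")
})

test_that("full A-scan places a mirror at the right depth bin and is unitary", {
  sp <- spectrometer_uniform_k(n_pixels = 1024, k_min = 7.3e5, k_max = 8e5,
                               read_noise = 0)
  sld <- fixture_sld()
  z <- 0.7e-3
  ig <- simulate_interferogram(sld, make_mirror(z, 1e-4), sp)
  ref <- simulate_interferogram(sld, reflector_phantom(numeric(0), numeric(0)),
                                sp, gain = ig$meta$gain)
  ig$counts <- ig$counts - ref$counts
  tomo <- ascan_full(ig)
  pk <- which.max(tomo$amplitude[-1, 1]) + 1L
  expect_lt(abs(tomo$depth_axis[pk] - z), diff(tomo$depth_axis)[1])
  # Parseval under the unitary convention: full |DFT|^2 equals sum of squares
  v <- ig$counts
  expect_equal(sum(Mod(stats::fft(v))^2) / length(v), sum(v^2))
})

test_that("comb tones are recovered exactly without noise and robustly with jitter", {
  spacing <- 40L
  n <- 2048L
  true_px <- seq(25L, n - 25L, by = spacing)
  spec <- numeric(n)
  spec[true_px] <- 1
  map <- detect_comb_pixels(spec, expected_fsr_pixels = spacing)
  expect_identical(map$pixel, true_px)
  # +/- 1 pixel jitter and 20 dB SNR: >= 99% of lines within 1 pixel
  set.seed(9)
  hits <- 0L; total <- 0L
  for (rep in 1:5) {
    jit <- true_px + sample(-1:1, length(true_px), replace = TRUE)
    spec2 <- abs(rnorm(n, sd = 0.1))  # 20 dB below the unit tones
    spec2[jit] <- spec2[jit] + 1
    m2 <- detect_comb_pixels(spec2, expected_fsr_pixels = spacing)
    near <- vapply(m2$pixel, function(p) min(abs(p - jit)), numeric(1))
    hits <- hits + sum(near <= 1)
    total <- total + nrow(m2)
  }
  expect_gte(hits / total, 0.99)
  # a smooth SLD spectrum must be rejected
  sp <- fixture_spectrometer(read_noise = 0)
  ig <- simulate_interferogram(fixture_sld(), make_mirror(30e-6, 1e-4), sp)
  expect_error(detect_comb_pixels(ig, expected_fsr_pixels = 78),
               "comb structure")
})

test_that("subsampled A-scans fold depths modulo the ambiguity range", {
  sp <- fixture_spectrometer(read_noise = 0)
  comb <- fixture_comb()
  g <- exposure_gain(comb, sp)
  z_amb <- ambiguity_range(1e12)
  z0 <- 42e-6
  ref <- simulate_interferogram(comb, reflector_phantom(numeric(0), numeric(0)),
                                sp, gain = g)
  map <- detect_comb_pixels(ref, expected_fsr_pixels = 78)
  recon <- function(z) {
    ig <- simulate_interferogram(comb, make_mirror(z, 1e-3), sp, gain = g)
    ig$counts <- ig$counts - ref$counts
    ascan_subsampled(ig, map)
  }
  base <- recon(z0)
  expect_equal(base$ambiguity_depth, z_amb, tolerance = 1e-3)
  expect_identical(nrow(base$amplitude), nrow(map))
  for (m in 1:2) {
    folded <- recon(z0 + m * z_amb)
    expect_lt(max(abs(folded$amplitude - base$amplitude)) /
                max(base$amplitude), 1e-6)
  }
  # two reflectors separated by exactly one ambiguity range merge into a
  # single peak whose fringe is the coherent sum
  both <- simulate_interferogram(
    comb, make_layered(c(z0, z0 + z_amb), c(1e-3, 1e-3)), sp, gain = g)
  both$counts <- both$counts - ref$counts
  tb <- ascan_subsampled(both, map)
  pk <- which.max(base$amplitude[-1, 1]) + 1L
  expect_equal(tb$amplitude[pk, 1], 2 * base$amplitude[pk, 1],
               tolerance = 1e-3)
})

test_that("subsampled equals the alias-folded full reconstruction", {
  # one line per illuminated pixel: uniform-k spectrometer whose pixel
  # spacing divides the comb spacing exactly
  fsr <- 1e12
  s <- 16L  # pixels per comb period
  dk_pix <- fsr / 299792458 / s
  n_lines <- 24L
  k0 <- 229e12 / 299792458
  k_grid <- k0 + dk_pix * seq.int(-s * n_lines / 2, s * n_lines / 2 - 1)
  sp <- spectrometer(pixel_wavelengths = rev(1 / k_grid), delta_k_ccd = 1e-3,
                     read_noise = 0)
  comb <- make_dks_spectrum(229e12, fsr = fsr, n_lines = 41,
                            bandwidth_3db = 8.3e12, total_power = 2e-3)
  g <- exposure_gain(comb, sp)
  ref <- simulate_interferogram(comb, reflector_phantom(numeric(0), numeric(0)),
                                sp, gain = g)
  ig <- simulate_interferogram(comb, make_mirror(55e-6, 1e-3), sp, gain = g)
  ig$counts <- ig$counts - ref$counts
  # every illuminated pixel is known by construction: build the map
  # explicitly so dim edge lines are kept too
  in_band <- comb$line_frequencies / 299792458
  in_band <- in_band[in_band >= min(k_grid) - 1e-6 &
                     in_band <= max(k_grid) + 1e-6]
  px <- vapply(in_band, function(k) which.min(abs(ig$wavenumber - k)),
               integer(1))
  px <- sort(px)
  map <- structure(
    data.frame(line = seq_along(px), pixel = px,
               wavenumber = ig$wavenumber[px]),
    class = c("comb_pixel_map", "data.frame"))
  sub <- ascan_subsampled(ig, map)
  m <- nrow(sub$amplitude)
  # folding oracle: the full-length DFT magnitude of a comb-pixel-sparse
  # interferogram is periodic with period m and each period equals the
  # subsampled A-scan up to the unitary normalization
  v <- ig$counts
  full_mag <- Mod(stats::fft(v)) / sqrt(length(v))
  folds <- matrix(full_mag, nrow = m)
  for (j in 2:ncol(folds)) {
    expect_equal(folds[, j], folds[, 1], tolerance = 1e-6)
  }
  expect_equal(sub$amplitude[, 1] * sqrt(m / length(v)), folds[, 1],
               tolerance = 1e-6)
})

test_that("log-clip-filter compresses, despeckles and clips at the percentiles", {
  const <- matrix(5, 32, 32)
  out <- log_clip_filter(const)
  expect_equal(as.numeric(out), rep(10 * log10(25), 1024))
  # single hot pixel removed by the median filter
  hot <- const
  hot[16, 16] <- 500
  out2 <- log_clip_filter(hot)
  expect_equal(as.numeric(out2), rep(10 * log10(25), 1024))
  # clip bounds equal brute-force order statistics of the filtered plane
  set.seed(10)
  plane <- matrix(rexp(64 * 64), 64, 64)
  out3 <- log_clip_filter(plane)
  filt <- comboct:::median_filter_3x3(10 * log10(pmax(plane, max(plane) * 1e-12)^2))
  expected <- stats::quantile(filt, c(1e-4, 0.999), names = FALSE)
  expect_equal(attr(out3, "clip_bounds"), expected)
  expect_equal(range(out3), expected)
  # degenerate all-zero plane flagged
  expect_true(isTRUE(attr(log_clip_filter(matrix(0, 8, 8)), "degenerate")))
})

test_that("axial resolution of a Gaussian SLD matches the coherence-length formula", {
  sp <- fixture_fine_spectrometer()
  sld <- fixture_sld()
  ig <- simulate_interferogram(sld, make_mirror(100e-6, 1e-4), sp)
  ref <- simulate_interferogram(sld, reflector_phantom(numeric(0), numeric(0)),
                                sp, gain = ig$meta$gain)
  ig$counts <- ig$counts - ref$counts
  tomo <- ascan_full(resample_to_k(ig))
  fwhm <- axial_resolution(tomo)
  expected <- 2 * log(2) / pi * 1310e-9^2 / 150e-9
  expect_equal(fwhm, expected, tolerance = 0.05)
  # halving the bandwidth doubles the width
  sld2 <- make_sld_spectrum(1310e-9, 75e-9, 9.15e-3)
  ig2 <- simulate_interferogram(sld2, make_mirror(100e-6, 1e-4), sp)
  ref2 <- simulate_interferogram(sld2, reflector_phantom(numeric(0), numeric(0)),
                                 sp, gain = ig2$meta$gain)
  ig2$counts <- ig2$counts - ref2$counts
  fwhm2 <- axial_resolution(ascan_full(resample_to_k(ig2)))
  expect_equal(fwhm2 / fwhm, 2, tolerance = 0.05)
  # featureless input rejected
  expect_error(axial_resolution(rep(1, 256), depth_axis = seq_len(256) * 1e-6),
               "no peak")
})

test_that("dynamic range is the peak-to-floor power ratio in dB", {
  plane <- c(rep(1, 100), sqrt(200))
  expect_equal(dynamic_range(plane, noise_region = 1:100), 10 * log10(200))
  expect_equal(dynamic_range(rep(3, 50), noise_region = 1:10), 0)
  expect_error(dynamic_range(plane, noise_region = 101), "overlaps")
})
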