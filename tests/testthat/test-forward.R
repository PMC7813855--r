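# Spectrometer forward model: closed-form range/degeneracy formulas and
# properties of simulated interferograms (fringe frequency, linearity,
# comb sparsity, depth folding, roll-off).

test_that("imaging depth and ambiguity range follow the closed forms", {
  expect_equal(max_imaging_depth(125), 2e-3)
  expect_equal(max_imaging_depth(1), 0.25)
  expect_equal(max_imaging_depth(spectrometer(delta_k_ccd = 250)), 1e-3)
  expect_equal(ambiguity_range(1e12) * 1e6, 149.9, tolerance = 1e-4)
  expect_equal(ambiguity_range(100e9) * 1e3, 1.499, tolerance = 1e-4)
  # conjugate-halved window at the device FSR reconciles the ~71 um figure
  expect_equal(ambiguity_range(1.05e12, halve_for_conjugate = TRUE) * 1e6,
               71.4, tolerance = 1e-3)
  expect_equal(ambiguity_range(1e12, n_tissue = 1.35),
               ambiguity_range(1e12) / 1.35)
})

test_that("photon degeneracy factor is FWC / (dnu tau)", {
  expect_equal(photon_degeneracy(2e5, 20e9, 21.7e-6), 0.46, tolerance = 0.01)
  expect_equal(photon_degeneracy(1e5, 1e9, 1e-4), 1)
  expect_equal(photon_degeneracy(2e5, 20e9, 43.4e-6),
               photon_degeneracy(2e5, 20e9, 21.7e-6) / 2)
})

test_that("an SLD fringe oscillates at 1/(2z) in wavenumber", {
  sp <- fixture_spectrometer(read_noise = 0)
  z <- 0.5e-3
  ig <- simulate_interferogram(fixture_sld(), make_mirror(z, 1e-3), sp)
  ku <- resample_to_k(ig)
  v <- ku$counts - mean(ku$counts)
  n <- length(v)
  sp_amp <- Mod(stats::fft(v))[2:(n / 2)]
  dk <- diff(ku$wavenumber)[1]
  f_peak <- (which.max(sp_amp)) / (n * dk)  # cycles per unit wavenumber
  expect_equal(f_peak, 2 * z, tolerance = 2 / (n * dk * 2 * z))
})

test_that("interferograms are linear in the reflector set", {
  sp <- fixture_spectrometer(read_noise = 0)
  comb <- fixture_comb()
  g <- exposure_gain(comb, sp)
  one <- simulate_interferogram(comb, make_mirror(40e-6, 1e-4), sp, gain = g)
  two <- simulate_interferogram(comb, make_mirror(90e-6, 2e-4), sp, gain = g)
  both <- simulate_interferogram(
    comb, make_layered(c(40e-6, 90e-6), c(1e-4, 2e-4)), sp, gain = g)
  ref <- simulate_interferogram(
    comb, reflector_phantom(numeric(0), numeric(0)), sp, gain = g)
  expect_equal(both$counts, one$counts + two$counts - ref$counts,
               tolerance = 1e-9)
})

test_that("non-illuminated pixels carry no signal under comb illumination", {
  sp <- fixture_spectrometer(read_noise = 0)
  comb <- fixture_comb()
  ig <- simulate_interferogram(comb, make_mirror(30e-6, 1e-3), sp)
  line_px <- vapply(comb$line_frequencies / 299792458, function(k) {
    which.min(abs(ig$wavenumber - k))
  }, integer(1))
  dark <- setdiff(seq_along(ig$counts),
                  as.vector(outer(line_px, -13:13, "+")))
  dark <- dark[dark >= 1 & dark <= length(ig$counts)]
  expect_lt(max(ig$counts[dark]), max(ig$counts) * 1e-6)
})

test_that("noiseless comb interferograms fold exactly over the ambiguity range", {
  sp <- fixture_spectrometer(read_noise = 0)
  comb <- fixture_comb()  # D2 = 0, nu0 an exact FSR multiple
  g <- exposure_gain(comb, sp)
  z <- 42e-6
  z_amb <- ambiguity_range(1e12)
  a <- simulate_interferogram(comb, make_mirror(z, 1e-3), sp, gain = g)
  b <- simulate_interferogram(comb, make_mirror(z + z_amb, 1e-3), sp, gain = g)
  expect_lt(max(abs(a$counts - b$counts)) / max(a$counts), 1e-6)
})

test_that("saturation is flagged in metadata, not raised", {
  sp <- fixture_spectrometer(read_noise = 0)
  ig <- simulate_interferogram(fixture_comb(), make_mirror(30e-6, 1), sp,
                               reference_reflectivity = 0.5, gain = 1e10)
  expect_true(ig$meta$saturated)
  expect_lte(max(ig$counts), sp$full_well_capacity)
})

test_that("sources outside the spectrometer band are rejected", {
  sp <- fixture_spectrometer()
  far <- make_dks_spectrum(400e12, fsr = 1e12, n_lines = 5,
                           bandwidth_3db = 4e12, total_power = 1e-3)
  expect_error(simulate_interferogram(far, make_mirror(0), sp), "overlap")
})

test_that("sensitivity roll-off matches the Gaussian closed form", {
  dk <- 125
  z <- seq(0, 0.8 * max_imaging_depth(dk), length.out = 5)
  expect_equal(sensitivity_rolloff(dk, 0), 1)
  expect_true(all(diff(sensitivity_rolloff(dk, z)) < 0))
  expect_equal(sensitivity_rolloff(1e-9, z), rep(1, 5), tolerance = 1e-12)
  expect_error(sensitivity_rolloff(dk, 3e-3), "maximum imaging depth")
})

test_that("simulated mirror sweep reproduces the roll-off curve within 2%", {
  # uniform-wavenumber pixels isolate the pixel-response physics from
  # resampling interpolation error; on-bin depths avoid scalloping
  sp <- spectrometer_uniform_k(n_pixels = 2048, k_min = 1 / 1385e-9,
                               k_max = 1 / 1235e-9, read_noise = 0)
  sld <- fixture_sld()
  g <- exposure_gain(sld, sp)
  n <- sp$n_pixels
  dk_pix <- (max(sp$pixel_wavenumbers) - min(sp$pixel_wavenumbers)) / (n - 1)
  bin <- 1 / (2 * n * dk_pix)
  depths <- bin * c(20, 80, 140, 200, 240, 280)  # up to ~0.8 z_max
  ref <- simulate_interferogram(sld, reflector_phantom(numeric(0), numeric(0)),
                                sp, gain = g)
  peaks <- vapply(depths, function(z) {
    ig <- simulate_interferogram(sld, make_mirror(z, 1e-4), sp, gain = g)
    ig$counts <- ig$counts - ref$counts  # remove the DC/autocorrelation ridge
    tomo <- ascan_full(ig)
    max(tomo$amplitude[-1, 1])
  }, numeric(1))
  rel <- peaks / peaks[1]
  expected <- sensitivity_rolloff(sp, depths)
  expected <- expected / expected[1]
  expect_equal(rel, expected, tolerance = 0.02)
})

test_that("the lambda-uniform pipeline tracks the roll-off after resampling", {
  sp <- fixture_spectrometer(read_noise = 0)
  sld <- fixture_sld()
  g <- exposure_gain(sld, sp)
  k_span <- max(sp$pixel_wavenumbers) - min(sp$pixel_wavenumbers)
  depths <- c(40, 200) / (2 * k_span)
  ref <- simulate_interferogram(sld, reflector_phantom(numeric(0), numeric(0)),
                                sp, gain = g)
  peaks <- vapply(depths, function(z) {
    ig <- simulate_interferogram(sld, make_mirror(z, 1e-4), sp, gain = g)
    ig$counts <- ig$counts - ref$counts
    max(ascan_full(resample_to_k(ig))$amplitude[-1, 1])
  }, numeric(1))
  expected <- sensitivity_rolloff(sp, depths)
  # cubic-spline interpolation adds a small extra high-frequency loss
  expect_equal(peaks[2] / peaks[1], expected[2] / expected[1],
               tolerance = 0.04)
})
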