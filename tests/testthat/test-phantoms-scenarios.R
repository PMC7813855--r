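# Phantom generators, scenario round-trips and the pipeline driver.

test_that("mirror and layered phantoms validate their inputs", {
  m <- make_mirror(30e-6)
  expect_equal(nrow(m$reflectors), 1L)
  expect_error(make_mirror(-1e-6), "non-negative")
  expect_error(make_layered(c(1e-6, 1e-6), c(0.1, 0.2)), "distinct")
  expect_error(reflector_phantom(1e-6, 1.5), "reflectivity")
})

test_that("speckle phantom scatterer counts follow the Poisson mean", {
  density <- 2e5
  extent <- 50e-6
  ph <- make_speckle_tissue(extent, density, n_lateral = 400, seed = 40)
  counts <- vapply(ph, function(p) nrow(p$reflectors), integer(1))
  lam <- density * extent  # expected 10 per A-line
  expect_equal(mean(counts), lam, tolerance = 3 / sqrt(400 * lam) * lam / 10)
  expect_lt(abs(mean(counts) - lam) / sqrt(lam / 400), 3)
  # same seed regenerates the identical volume
  ph2 <- make_speckle_tissue(extent, density, n_lateral = 400, seed = 40)
  expect_identical(lapply(ph, `[[`, "reflectors"),
                   lapply(ph2, `[[`, "reflectors"))
})

test_that("bright inclusions stand out of the speckle background", {
  incl <- data.frame(z = 25e-6, reflectivity = 1e-3)  # 20 dB above scale
  ph <- make_speckle_tissue(50e-6, 2e5, reflectivity_scale = 1e-5,
                            n_lateral = 24, fiber_inclusions = incl,
                            seed = 41)
  sp <- fixture_spectrometer(read_noise = 0)
  comb <- fixture_comb()
  b <- simulate_bscan(comb, ph, sp, n_ascans = 24)
  # background subtraction would cancel the laterally invariant inclusion
  # along with the DC; keep the raw spectra and judge depth contrast
  tomo <- reconstruct_bscan(b, "subsampled", background = FALSE)
  bin <- diff(tomo$depth_axis)[1]
  incl_bin <- which.min(abs(tomo$depth_axis - 25e-6))
  others <- setdiff(seq(4L, nrow(tomo$amplitude) - 2L),
                    (incl_bin - 1L):(incl_bin + 1L))
  contrast <- mean(tomo$amplitude[incl_bin, ]) /
    mean(tomo$amplitude[others, ])
  expect_gt(contrast, 3)
})

test_that("scenarios carry complete ground truth and regenerate bit-identically", {
  sc <- make_scenario("dks_correlated_noise", seed = 5)
  expect_equal(sc$ground_truth$common_mode_fraction, 1)
  expect_equal(sc$geometry$line_rate, 46e3)
  a <- generate_acquisition(sc)
  b <- generate_acquisition(make_scenario("dks_correlated_noise", seed = 5))
  expect_identical(a$counts, b$counts)
  gt <- attr(a, "ground_truth")
  expect_false(is.null(gt$stage_seeds))
  expect_equal(gt$parameters$sigma_common, 0.01)
  # tissue scenario geometry: 512-line B-scans at the 46 kHz line rate
  sc2 <- make_scenario("dks_tissue", seed = 1)
  expect_equal(sc2$geometry$n_ascans, 512L)
  # SLD scenario: 1310 nm / 150 nm source
  sc3 <- make_scenario("sld_mirror", seed = 1)
  expect_equal(sc3$source$center_wavelength, 1310e-9)
  expect_equal(sc3$source$bandwidth, 150e-9)
  expect_error(make_scenario("nope"), "unknown scenario")
  # comb pushed outside the spectrometer band is rejected with named keys
  expect_error(make_scenario("dks_mirror", seed = 1,
                             overrides = list(nu0 = 400e12)),
               "outside the spectrometer band")
})

test_that("mirror scenarios round-trip depths through both pipelines", {
  # common-mode acquisition noise leaves a residual mirror peak after
  # per-B-scan mean removal; the recovered depth must match ground truth
  sc <- make_scenario("dks_correlated_noise", seed = 2,
                      overrides = list(n_ascans = 32L, mirror_z = 45e-6))
  acq <- generate_acquisition(sc)
  z_true <- attr(acq, "ground_truth")$true_depths
  tomo <- reconstruct_bscan(acq, "subsampled")
  bin <- diff(tomo$depth_axis)[1]
  z_amb <- tomo$ambiguity_depth
  circ <- function(a, b) {
    d <- abs(a - b) %% z_amb
    pmin(d, z_amb - d)
  }
  # the comb envelope's DC ridge occupies the few bins around zero depth
  # (width set by the envelope bandwidth); the mirror is the strongest
  # feature away from it
  m <- nrow(tomo$amplitude)
  ma <- rowMeans(tomo$amplitude)
  ma[c(1:4, (m - 2L):m)] <- 0
  pk <- which.max(ma)
  err <- min(circ(tomo$depth_axis[pk], z_true),
             circ(tomo$depth_axis[pk], z_amb - z_true))  # conjugate mirror
  expect_lte(err, bin)
  # full pipeline: the comb's DC replica train sits at multiples of the
  # ambiguity range; away from it the mirror (and its replicas) dominate,
  # recovering the depth modulo the ambiguity range
  full <- reconstruct_bscan(acq, "full")
  binf <- diff(full$depth_axis)[1]
  mf <- rowMeans(full$amplitude)
  dc_dist <- circ(full$depth_axis, 0)
  mf[dc_dist <= 3 * binf] <- 0
  pkf <- full$depth_axis[which.max(mf)]
  errf <- min(circ(pkf, z_true), circ(pkf, z_amb - z_true))
  expect_lte(errf, 2 * binf)
})

test_that("line-noise scenarios encode the soliton/chaotic dichotomy", {
  dks <- generate_acquisition(make_scenario("line_noise_dks", seed = 3),
                              sampling_rate = 5e5)
  r <- cross_correlate(dks$traces[, 1], dks$traces[, 2])
  expect_lt(abs(r$r0 - 0.95), 0.03)
  mi <- generate_acquisition(make_scenario("line_noise_mi", seed = 3),
                             sampling_rate = 5e5)
  r2 <- cross_correlate(mi$traces[, 1], mi$traces[, 2])
  expect_lt(abs(r2$r0), 0.03)
})

test_that("run_pipeline writes outputs and a reproducible manifest", {
  out1 <- file.path(tempdir(), "run1")
  out2 <- file.path(tempdir(), "run2")
  cfg <- list(scenario = "dks_mirror", seed = 4,
              overrides = list(n_ascans = 6L))
  m1 <- run_pipeline(cfg, out1)
  m2 <- run_pipeline(cfg, out2)
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_identical(m1$config_hash, m2$config_hash)
  t1 <- utils::read.csv(file.path(out1, "tomogram_subsampled.csv"))
  t2 <- utils::read.csv(file.path(out2, "tomogram_subsampled.csv"))
  expect_identical(t1, t2)
  gt <- jsonlite::read_json(file.path(out1, "ground_truth.json"))
  expect_equal(gt$parameters$mirror_z, 30e-6)
  # empty stage list: manifest only
  out3 <- file.path(tempdir(), "run3")
  m3 <- run_pipeline(list(scenario = "dks_mirror", stages = list()), out3)
  expect_true(file.exists(file.path(out3, "manifest.json")))
  expect_length(m3$outputs, 0)
  expect_error(run_pipeline(list(scenario = "dks_mirror",
                                 stages = "frobnicate"), out3),
               "unknown stage")
})

test_that("compare_methods reports matched peaks and floors", {
  sc <- make_scenario("dks_correlated_noise", seed = 6,
                      overrides = list(n_ascans = 32L))
  acq <- generate_acquisition(sc)
  tf <- reconstruct_bscan(acq, "full")
  ts <- reconstruct_bscan(acq, "subsampled")
  rep <- compare_methods(tf, ts)
  bin <- diff(ts$depth_axis)[1]
  d <- abs(rep$peak_depth_full_mod_amb_m - rep$peak_depth_subsampled_m)
  expect_lte(min(d, rep$ambiguity_range_m - d), 2 * bin)
  expect_error(compare_methods(ts, tf), "full and subsampled")
})

test_that("serialization round-trips spectra, phantoms and traces", {
  comb <- fixture_comb(n_lines = 7L)
  f <- tempfile(fileext = ".csv")
  write_spectrum_csv(comb, f)
  back <- read_spectrum_csv(f)
  expect_equal(back$line_frequencies, comb$line_frequencies)
  expect_equal(back$line_powers, comb$line_powers)
  expect_equal(back$fsr, comb$fsr)
  ph <- make_layered(c(20e-6, 60e-6), c(1e-4, 2e-4))
  f2 <- tempfile(fileext = ".csv")
  write_phantom_csv(ph, f2)
  expect_equal(read_phantom_csv(f2)$reflectors, ph$reflectors)
  tr <- simulate_line_traces(fixture_comb(n_lines = 5L),
                             noise_model(common_mode_rin_psd = 1e-9),
                             1e5, 0.005, seed = 50)
  f3 <- tempfile(fileext = ".csv")
  write_traces_csv(tr, f3)
  back3 <- read_traces_csv(f3)
  expect_equal(back3$traces, tr$traces, tolerance = 1e-12)
  expect_equal(back3$sampling_rate, 1e5)
  expect_equal(back3$line_ids, tr$line_ids)
})
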