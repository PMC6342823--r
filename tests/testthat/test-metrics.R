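# Minimal A-scan stand-in for the fit-based metrics.
fake_ascan <- function(depth_um, magnitude) {
  structure(list(magnitude = magnitude, depth_um = depth_um,
                 db = 20 * log10(pmax(magnitude, 1e-300) /
                                 max(median(magnitude), 1e-300)),
                 noise_floor = max(median(magnitude), 1e-12),
                 zero_pad_factor = 4L, window = "none"),
            class = "oct_ascan")
}

test_that("the Gaussian fit recovers a known peak width", {
  z <- seq(0, 400, by = 0.5)
  fwhm <- 9
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  a <- fake_ascan(z, 100 * exp(-(z - 150)^2 / (2 * sig^2)) + 0.5)
  expect_equal(as.numeric(axial_resolution(a, 150)), 9, tolerance = 0.05 / 9)

  # an ambiguous double peak is rejected, never silently fitted
  b <- fake_ascan(z, 100 * exp(-(z - 150)^2 / (2 * sig^2)) +
                      90 * exp(-(z - 165)^2 / (2 * sig^2)) + 0.5)
  expect_error(axial_resolution(b, 155), "ambiguous|peak")
  # no peak above the floor
  flat <- fake_ascan(z, rep(1, length(z)))
  expect_error(axial_resolution(flat), "floor")
})

test_that("the flat-spectrum point response matches the analytic sinc width", {
  a <- tst_mirror_ascan(100, window = "none")
  fw <- as.numeric(axial_resolution(a, 100, method = "halfmax"))
  expect_equal(fw, sinc_fwhm_um(), tolerance = 0.02)
})

test_that("axial resolution is stable against further zero padding", {
  f4 <- as.numeric(axial_resolution(
    tst_mirror_ascan(100, window = "hanning", zero_pad_factor = 4), 100))
  f8 <- as.numeric(axial_resolution(
    tst_mirror_ascan(100, window = "hanning", zero_pad_factor = 8), 100))
  expect_equal(f8 / f4, 1, tolerance = 0.01)
})

test_that("the simulated roll-off reproduces the instrument's 6 dB pair", {
  ro <- simulate_rolloff(tst_spec(), n_probes = 10)
  expect_false(ro$curve$z6db_is_lower_bound)
  expect_equal(ro$curve$z6db_um / 1000, 1.35, tolerance = 0.02 / 1.35)
  lam0 <- sqrt(3576 * 4625)
  expect_equal(spectral_resolution_from_rolloff(ro$curve$z6db_um, lam0),
               2.7, tolerance = 0.1 / 2.7)
})

test_that("roll-off scales inversely with spectral resolution and can saturate", {
  # near-ideal resolution: curve never drops 6 dB -> lower-bound flag
  spec_fine <- spectrometer_model(resolution_fwhm_nm = 0.1)
  ro_fine <- simulate_rolloff(spec_fine, n_probes = 5)
  expect_true(ro_fine$curve$z6db_is_lower_bound)
  expect_true(all(ro_fine$curve$sensitivity_db > -1))

  # doubling the resolution FWHM halves the 6 dB depth
  ro_a <- simulate_rolloff(spectrometer_model(resolution_fwhm_nm = 2),
                           n_probes = 10, max_opd_um = 2200)
  ro_b <- simulate_rolloff(spectrometer_model(resolution_fwhm_nm = 4),
                           n_probes = 10, max_opd_um = 2200)
  expect_equal(ro_a$curve$z6db_um / ro_b$curve$z6db_um, 2, tolerance = 0.02)

  # model inversion round-trips the injected resolution within 3 percent
  for (res in c(1.5, 2.7, 6)) {
    ro <- simulate_rolloff(spectrometer_model(resolution_fwhm_nm = res),
                           n_probes = 10,
                           max_opd_um = min(2500, 2.2 * log(2) *
                                              sqrt(3576 * 4625)^2 /
                                              (pi * res) / 1000))
    est <- spectral_resolution_from_rolloff(ro$curve$z6db_um,
                                            sqrt(3576 * 4625))
    expect_equal(est, res, tolerance = 0.03)
  }
})

test_that("roll-off inversion identities hold", {
  lam0 <- 4066.8
  expect_equal(spectral_resolution_from_rolloff(1.35e3, lam0), 2.7,
               tolerance = 0.1 / 2.7)
  # unit-consistency: z6 = ln2 lambda0^2 / pi (in nm) gives 1 nm back
  z6_nm <- log(2) * lam0^2 / pi
  expect_equal(spectral_resolution_from_rolloff(z6_nm / 1000, lam0), 1,
               tolerance = 1e-12)
  expect_error(spectral_resolution_from_rolloff(-1, lam0), "> 0")
})

test_that("thickness from OPD divides by the index with sampling uncertainty", {
  t1 <- thickness_from_opd(809.9, 2.138, 4.05)
  expect_equal(t1$thickness_um, 378.8, tolerance = 0.05 / 378.8)
  expect_equal(t1$uncertainty_um, 2 * 4.05 / 2.138)
  t2 <- thickness_from_opd(787.0, 1.675, 4.05)
  expect_equal(t2$thickness_um, 469.9, tolerance = 0.05 / 469.9)
  # vacuum identity
  t3 <- thickness_from_opd(123.4, 1, 2)
  expect_equal(t3$thickness_um, 123.4)
  expect_equal(t3$uncertainty_um, 4)
  # linear in OPD and in 1/n
  for (sc in c(2, 5)) {
    expect_equal(thickness_from_opd(809.9 * sc, 2.138, 1)$thickness_um,
                 sc * t1$thickness_um)
    expect_equal(thickness_from_opd(809.9, 2.138 * sc, 1)$thickness_um,
                 t1$thickness_um / sc)
  }
})

test_that("sampling resolutions reproduce the instrument figures", {
  s <- sampling_resolutions(c(3576, 4625), 2286, 3, 3)
  expect_equal(s$spectral_nm, 0.46, tolerance = 0.005 / 0.46)
  expect_equal(s$lateral_um, 9)
  expect_equal(sampling_resolutions(c(4000, 4000), 100, 1, 1)$spectral_nm, 0)
})
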