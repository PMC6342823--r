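test_that("source envelopes normalize, centre and interpolate as specified", {
  flat <- make_source_spectrum(c(3576, 4625), "flat")
  dk <- flat$k_grid[2] - flat$k_grid[1]
  expect_equal(sum(flat$envelope) * dk, 1, tolerance = 1e-12)
  expect_true(all(flat$envelope[flat$k_grid < wavelength_to_k(4625) - 1e-9] == 0))

  g <- make_source_spectrum(c(3576, 4625), "gaussian")
  k_c <- (wavelength_to_k(3576) + wavelength_to_k(4625)) / 2
  expect_equal(g$k_grid[which.max(g$envelope)], k_c, tolerance = 1e-4)

  # 3-point table: linear interpolation in wavelength matches hand values
  tab <- list(lambda_nm = c(3800, 4000, 4200), value = c(0, 1, 0))
  t3 <- make_source_spectrum(c(3700, 4300), "tabulated", table = tab)
  at <- function(lam) {
    i <- which.min(abs(k_to_wavelength(t3$k_grid) - lam))
    t3$envelope[i]
  }
  expect_equal(at(3900) / at(4000), 0.5, tolerance = 1e-2)
  expect_equal(at(4100) / at(4000), 0.5, tolerance = 1e-2)
  expect_equal(at(3750), 0)
  expect_error(make_source_spectrum(c(4000, 4100), "boxcar"))
})

test_that("dispersion phase reproduces the silicon-wafer GDD products", {
  k <- make_source_spectrum()$k_grid
  expect_equal(dispersion_phase(1576, 0, k)$phase, rep(0, length(k)))
  # 255-um wafer, double pass: 2 x 0.255 x GVD
  expect_equal(dispersion_phase(1576, 0.255, k)$gdd_fs2, 2 * 0.255 * 1576)
  expect_equal(round(dispersion_phase(1576, 0.255, k)$gdd_fs2, 1), 803.8)
  # exact product 196.35 fs^2; printed to one decimal as 196.4
  expect_lte(abs(dispersion_phase(385, 0.255, k)$gdd_fs2 - 196.4), 0.0501)
  expect_equal(dispersion_phase(385, 0.255, k, double_pass = FALSE)$gdd_fs2,
               0.255 * 385)
  expect_error(dispersion_phase(1576, -1, k), ">= 0")
})

test_that("Gaussian roll-off model has the stated 6 dB point", {
  lam0 <- sqrt(3576 * 4625)
  expect_equal(rolloff_attenuation(0, 2.7, lam0), 1)
  z6 <- log(2) * lam0^2 / (pi * 2.7) / 1000   # um
  expect_equal(20 * log10(rolloff_attenuation(z6, 2.7, lam0)), -6.02,
               tolerance = 1e-2 / 6)
  # the printed instrument pair: 2.7 nm resolution <-> 1.35 mm 6 dB depth
  expect_equal(z6 / 1000, 1.35, tolerance = 0.02 / 1.35)
  expect_error(rolloff_attenuation(100, -2, lam0), "> 0")
  expect_error(rolloff_attenuation(-1, 2.7, lam0), ">= 0")
})

test_that("single-mirror fringe has period pi/z in linear wavenumber", {
  spec <- tst_spec(); cal <- tst_cal()
  z <- 400
  fr <- synth_interferogram(reflector_stack(z, 0.05), tst_source(), spec)
  fringe <- preprocess_frames(fr$sample, fr$dark, fr$reference)
  x <- as.numeric(fringe); x[is.na(x)] <- 0
  s <- splinefun(seq_along(x), x)(cal$resample_positions)
  ku <- cal$k_uniform
  keep <- seq(round(0.3 * length(s)), round(0.5 * length(s)))  # well in band
  sl <- s[keep] - mean(s[keep])
  crossings <- which(diff(sign(sl)) != 0)
  period <- 2 * mean(diff(ku[keep][crossings]))
  expect_equal(period, pi / z, tolerance = 0.01)
})

test_that("an empty reflector stack makes sample and reference frames identical", {
  fr <- synth_interferogram(reflector_stack(numeric(0), numeric(0)),
                            tst_source(), tst_spec())
  expect_identical(fr$sample$counts, fr$reference$counts)
})

test_that("pixel counts match a direct Gaussian-summation oracle for two mirrors", {
  spec <- tst_spec()
  source <- tst_source()
  zs <- c(100, 300); rr <- c(0.1, 0.1); rho <- 0.5
  fr <- synth_interferogram(reflector_stack(zs, rr), source, spec,
                            integration_ms = 3)
  # oracle: raw (unconvolved) interference intensity on the dense grid,
  # then an explicit Gaussian-weighted sum evaluated at each pixel's k
  k <- source$k_grid
  raw <- source$envelope * (rho + sum(rr^2))
  for (j in 1:2) raw <- raw + source$envelope * 2 * sqrt(rho) * rr[j] *
    cos(2 * k * zs[j])
  raw_ref <- source$envelope * rho
  lam0 <- sqrt(3576 * 4625)
  sig <- (2 * pi * spec$resolution_fwhm_nm * 1000 / lam0^2) /
    (2 * sqrt(2 * log(2)))
  k_pix <- pixel_k_midir(spec)
  direct <- function(vals, kp) {
    w <- exp(-(k - kp)^2 / (2 * sig^2))
    sum(w * vals) / sum(w)
  }
  sample_or <- vapply(k_pix, direct, 0, vals = raw)
  ref_or <- vapply(k_pix, direct, 0, vals = raw_ref)
  out <- k_pix < min(k) | k_pix > max(k)
  sample_or[out] <- 0; ref_or[out] <- 0
  full <- 2^spec$bit_depth - 1
  gain <- 0.8 * full / (max(ref_or) * spec$full_well_integration_ms)
  dark <- 0.02 * full
  counts_or <- round(pmin(pmax(sample_or * gain * 3 + dark, 0), full))
  expect_lt(max(abs(fr$sample$counts - counts_or)), 1.5)
})

test_that("noise-off synthesis is deterministic and seed-independent", {
  st <- reflector_stack(250, 0.05)
  a <- synth_interferogram(st, tst_source(), tst_spec(), seed = 1)
  b <- synth_interferogram(st, tst_source(), tst_spec(), seed = 999)
  expect_identical(a$sample$counts, b$sample$counts)
  expect_identical(a$dark$counts, b$dark$counts)
  # noise on at fixed seed is reproducible, and differs across seeds
  n1 <- synth_interferogram(st, tst_source(), tst_spec(), noise = TRUE,
                            seed = 7)
  n2 <- synth_interferogram(st, tst_source(), tst_spec(), noise = TRUE,
                            seed = 7)
  n3 <- synth_interferogram(st, tst_source(), tst_spec(), noise = TRUE,
                            seed = 8)
  expect_identical(n1$sample$counts, n2$sample$counts)
  expect_false(identical(n1$sample$counts, n3$sample$counts))
})

test_that("fringe amplitude is linear in reflectivity and counts in integration time", {
  spec <- tst_spec()
  amp <- function(r) {
    fr <- synth_interferogram(reflector_stack(200, r), tst_source(), spec,
                              quantize = FALSE)
    x <- fr$sample$counts - fr$reference$counts
    (max(x) - min(x)) / 2
  }
  expect_equal(amp(0.02) / amp(0.01), 2, tolerance = 0.01)
  # mean counts above dark scale linearly with integration time
  fr1 <- synth_interferogram(reflector_stack(200, 0.01), tst_source(), spec,
                             integration_ms = 1, quantize = FALSE)
  fr2 <- synth_interferogram(reflector_stack(200, 0.01), tst_source(), spec,
                             integration_ms = 2, quantize = FALSE)
  dark <- 0.02 * (2^spec$bit_depth - 1)
  expect_equal(mean(fr2$reference$counts - dark) /
                 mean(fr1$reference$counts - dark), 2, tolerance = 1e-9)
})

test_that("interfaces beyond the unambiguous range are flagged, not dropped", {
  spec <- tst_spec()
  zmax <- unambiguous_range(spec)
  expect_warning(fr <- synth_interferogram(reflector_stack(zmax + 500, 0.05),
                                           tst_source(), spec), "alias")
  expect_true(attr(fr, "aliased"))
})

test_that("calibration frames embed the expected phase structure", {
  spec <- tst_spec()
  expect_error(generate_calibration_frames(spec, opds_um = c(500, 500)),
               "degenerate")
  expect_warning(generate_calibration_frames(
    spec, opds_um = c(500, unambiguous_range(spec) * 0.9)), "samples")
  cf <- generate_calibration_frames(spec, opds_um = c(200, 800))
  # by construction the phase difference is linear in true k: recovering it
  # through the calibration should reproduce the true pixel map
  cal <- build_calibration(cf)
  k_true <- pixel_k_midir(spec)
  idx <- cal$usable[1]:cal$usable[2]
  expect_lt(max(abs(cal$k_of_pixel[idx] - k_true[idx]) / k_true[idx]), 1e-4)
})
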