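test_that("preprocessing yields the normalized zero-mean fringe with masking", {
  spec <- tst_spec()
  # sample identical to reference (empty stack): all-zero signal in band
  fr0 <- synth_interferogram(reflector_stack(numeric(0), numeric(0)),
                             tst_source(), spec)
  f0 <- preprocess_frames(fr0$sample, fr0$dark, fr0$reference)
  expect_true(all(abs(f0[!is.na(f0)]) == 0))
  expect_true(is.integer(attr(f0, "support")) ||
              is.numeric(attr(f0, "support")))

  # closed-form fringe: peak-to-peak 4 r sqrt(rho) / rho
  r <- 0.05; rho <- 0.5
  fr <- synth_interferogram(reflector_stack(150, r), tst_source(), spec,
                            quantize = FALSE)
  f <- preprocess_frames(fr$sample, fr$dark, fr$reference)
  inb <- which(!is.na(f))
  inb <- inb[inb > min(inb) + 50 & inb < max(inb) - 50]
  ptp <- max(f[inb]) - min(f[inb])
  expect_equal(ptp, 4 * r * sqrt(rho) / rho, tolerance = 0.02)

  # saturated pixels are flagged and excluded
  fr2 <- synth_interferogram(reflector_stack(150, 0.4), tst_source(), spec)
  f2 <- preprocess_frames(fr2$sample, fr2$dark, fr2$reference)
  full <- 2^spec$bit_depth - 1
  expect_true(all(is.na(f2[fr2$sample$counts >= full])))

  expect_error(preprocess_frames(fr$sample, fr$dark, fr$dark),
               "calibration error")
})

test_that("two-interferogram calibration recovers linear and distorted pixel maps", {
  # linear map: recovered k(p) linear in p to high accuracy, flat dispersion
  spec <- tst_spec(); cal <- tst_cal()
  k_true <- pixel_k_midir(spec)
  idx <- cal$usable[1]:cal$usable[2]
  expect_lt(max(abs(cal$k_of_pixel[idx] - k_true[idx]) / k_true[idx]), 1e-6)
  dp <- cal$dispersion_phase
  detr <- residuals(lm(dp ~ seq_along(dp)))
  expect_lt(sd(detr), 1e-2)

  # injected cubic pixel-map distortion round-trips within 1e-3 relative
  spec_c <- spectrometer_model(distortion = c(0, 0.02))
  cal_c <- build_calibration(generate_calibration_frames(spec_c))
  k_c <- pixel_k_midir(spec_c)
  idx_c <- cal_c$usable[1]:cal_c$usable[2]
  expect_lt(max(abs(cal_c$k_of_pixel[idx_c] - k_c[idx_c]) / k_c[idx_c]),
            1e-3)

  fa <- generate_calibration_frames(tst_spec())$frame_a
  expect_error(build_calibration(fa, fa, 500, 500), "degenerate")
})

test_that("injected interferometer GDD is recovered as the dispersion phase", {
  spec <- tst_spec()
  gdd <- 800
  cal_g <- build_calibration(generate_calibration_frames(
    spec, dispersion_gdd_fs2 = gdd))
  band <- sort(downconvert_wavelength(spec$lambda_range_nm, spec$pump_nm))
  band <- band + c(-0.005, 0.005) * diff(band)  # calibration source margin
  k0 <- wavelength_to_k(sqrt(band[1] * band[2]))
  ku <- cal_g$k_uniform
  injected <- 0.5 * gdd * (0.299792458 * (ku - k0))^2
  # constant/linear phase components are benign (pure sub-bin depth shift),
  # so compare after removing the best-fit line
  resid <- residuals(lm(I(cal_g$dispersion_phase - injected) ~ ku))
  expect_lt(sqrt(mean(resid^2)), 1e-2)
})

test_that("calibration is a fixed point when frames come from the recovered map", {
  spec <- tst_spec(); cal <- tst_cal()
  lam_up <- pixel_wavelength(spec)
  ok <- !is.na(cal$k_of_pixel)
  lam_up[ok] <- upconvert_wavelength(2000 * pi / cal$k_of_pixel[ok],
                                     spec$pump_nm)
  spec2 <- spectrometer_model(pixel_lambda_nm = lam_up)
  cal2 <- build_calibration(generate_calibration_frames(spec2))
  idx <- max(cal$usable[1], cal2$usable[1]):min(cal$usable[2], cal2$usable[2])
  expect_lt(max(abs(cal2$k_of_pixel[idx] - cal$k_of_pixel[idx]) /
                cal$k_of_pixel[idx]), 1e-4)
})

test_that("a noiseless mirror reconstructs at its OPD with the analytic width", {
  a <- tst_mirror_ascan(100, window = "none")
  pre_bin <- pi / (length(tst_cal()$k_uniform) * tst_cal()$dk_uniform)
  sub <- a$depth_um > 20
  pk <- which(sub)[which.max(a$magnitude[sub])]
  expect_lt(abs(a$depth_um[pk] - 100), pre_bin)
  fw <- axial_resolution(a, 100, method = "halfmax")
  expect_equal(as.numeric(fw), sinc_fwhm_um(), tolerance = 0.02)
  expect_error(reconstruct_ascan(rep(0, 10), tst_cal()), "length")
  expect_error(tst_mirror_ascan(100, zero_pad_factor = 0), ">= 1")
})

test_that("matched-calibration reconstruction undoes an injected GDD", {
  spec <- tst_spec()
  gdd <- 800
  cal_g <- build_calibration(generate_calibration_frames(
    spec, dispersion_gdd_fs2 = gdd))
  fr <- synth_interferogram(reflector_stack(300, 0.05, gdd_fs2 = gdd),
                            tst_source(), spec)
  a_g <- reconstruct_ascan(preprocess_frames(fr$sample, fr$dark,
                                             fr$reference), cal_g,
                           window = "none")
  fw_g <- as.numeric(axial_resolution(a_g, 300, hint_window_um = 60,
                                      method = "halfmax"))
  fw_0 <- as.numeric(axial_resolution(tst_mirror_ascan(300, window = "none"),
                                      300, method = "halfmax"))
  expect_equal(fw_g, fw_0, tolerance = 0.05)
  # and without compensation the peak is visibly broadened
  a_un <- reconstruct_ascan(preprocess_frames(fr$sample, fr$dark,
                                              fr$reference), tst_cal(),
                            window = "none")
  fw_un <- as.numeric(axial_resolution(a_un, 300, hint_window_um = 60,
                                       method = "halfmax"))
  # 800 fs^2 over this band chirps the band-edge phase by ~1.4 rad; the
  # apodized band edges soften the effect, but the broadening must remain
  # clearly measurable
  expect_gt(fw_un, 1.05 * fw_0)
})

test_that("Hanning apodization trades resolution for sidelobe suppression", {
  a <- tst_mirror_ascan(300, window = "none")
  ah <- tst_mirror_ascan(300, window = "hanning")
  fw <- as.numeric(axial_resolution(a, 300, method = "halfmax"))
  fwh <- as.numeric(axial_resolution(ah, 300, method = "halfmax"))
  expect_gte(fwh / fw, 1.4)
  expect_lte(fwh / fw, 1.8)
  first_sidelobe_db <- function(x, z0) {
    m <- x$magnitude; z <- x$depth_um
    w <- which(z > z0 - 30 & z < z0 + 30)
    pk <- w[which.max(m[w])]
    i <- pk; while (m[i + 1] < m[i]) i <- i + 1
    j <- i; while (m[j + 1] > m[j]) j <- j + 1
    20 * log10(m[j] / m[pk])
  }
  expect_gte(first_sidelobe_db(a, 300) - first_sidelobe_db(ah, 300), 18)
})

test_that("the transform stage conserves power (no window, no padding)", {
  a <- tst_mirror_ascan(500, window = "none", zero_pad_factor = 1)
  expect_equal(a$profile_power, a$spectral_power, tolerance = 1e-9)
})

test_that("every interface of a layered stack is recovered within a depth bin", {
  spec <- tst_spec(); cal <- tst_cal()
  st <- ceramic_stack_reflectors(ceramic_stack_spec(gap_c2_c3_um = 30))
  fr <- synth_interferogram(st, tst_source(), spec, integration_ms = 0.7)
  a <- reconstruct_ascan(preprocess_frames(fr$sample, fr$dark, fr$reference),
                         cal)
  pre_bin <- pi / (length(cal$k_uniform) * cal$dk_uniform)
  peak_near <- function(z) {
    w <- which(abs(a$depth_um - z) < 25)
    w[which.max(a$magnitude[w])]
  }
  pk_amp <- numeric(0)
  for (j in seq_along(st$z_um)) {
    pk <- peak_near(st$z_um[j])
    expect_lt(abs(a$depth_um[pk] - st$z_um[j]), pre_bin)
    pk_amp[j] <- a$magnitude[pk]
  }
  # relative peak amplitudes follow the reflectivities once the roll-off
  # attenuation is divided out (several interfaces share the same r, so
  # compare the strict extremes)
  lam0 <- sqrt(3576 * 4625)
  corr <- pk_amp / rolloff_attenuation(st$z_um, spec$resolution_fwhm_nm, lam0)
  expect_equal(which.max(corr), which.max(st$r))
  expect_equal(which.min(corr), which.min(st$r))
})

test_that("scan assembly books lateral spacing and acquisition time correctly", {
  a <- tst_mirror_ascan(200)
  mk <- function(n) replicate(n, a, simplify = FALSE)
  b <- assemble_scan(mk(500), "continuous_x", speed_mm_s = 3,
                     integration_ms = 3)
  expect_equal(b$meta$total_time_s, 1.5)
  expect_equal(diff(b$lateral_um)[1], 9)
  b2 <- assemble_scan(mk(1000), "continuous_x", speed_mm_s = 3,
                      integration_ms = 3)
  expect_equal(b2$meta$total_time_s, 3)
  expect_equal(diff(b2$lateral_um)[1], 9)
  bs <- assemble_scan(mk(4), "stepped_y", step_um = 10)
  expect_equal(diff(bs$lateral_um)[1], 10)
  expect_error(assemble_scan(mk(1), "continuous_x", speed_mm_s = 3,
                             integration_ms = 3), "at least 2")
  vol <- assemble_scan(list(b, b), "stepped_y", step_um = 25)
  expect_s3_class(vol, "oct_volume")
  expect_equal(dim(vol$magnitude)[3], 2)
})
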