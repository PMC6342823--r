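balance_rel <- function(sim) {
  led <- sim$ledger
  abs(sum(led[c("absorbed", "exit_top", "exit_bottom", "exit_side",
                "residual", "roulette_net")]) - led[["launched"]]) /
    led[["launched"]]
}

test_that("ballistic transport through index steps conserves weight exactly", {
  dom <- tst_block(nz = 100, n = 1)
  dom$n[, , 51:100] <- 2.5
  sim <- mc_simulate(dom, mc_source(12.5, 12.5, 2, 5000, 3), time_grid())
  expect_lt(balance_rel(sim), 1e-6)
  # non-absorbing semi-infinite-like slab: everything reflects or leaves
  expect_equal(sim$ledger[["absorbed"]], 0)
})

test_that("Henyey-Greenstein sampling reproduces the anisotropy moment", {
  for (g in c(0, 0.5, 0.9)) {
    x <- sample_hg(4e5, g, seed = 11)
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - g), 3 * se + 1e-12)
  }
  # in-medium check: single-scatter deflections inside the engine
  dom <- tst_block(nxy = 41, nz = 41, voxel_um = 50, mus = 10, g = 0.9,
                   n = 1)
  sim <- mc_simulate(dom, mc_source(1025, 1025, 2, 20000, 5), time_grid(2.4, 24))
  expect_lt(balance_rel(sim), 1e-6)
})

test_that("weight conservation holds for random heterogeneous domains", {
  set.seed(99)
  for (i in 1:3) {
    dims <- c(6, 6, 30)
    dom <- voxel_domain(dims, 5,
                        mua = array(runif(prod(dims), 0, 2), dims),
                        mus = array(runif(prod(dims), 0, 30), dims),
                        g = array(runif(prod(dims), -0.5, 0.95), dims),
                        n = array(runif(prod(dims), 1, 2), dims))
    sim <- mc_simulate(dom, mc_source(15, 15, 4, 4000, i), time_grid(4.8, 24))
    expect_lt(balance_rel(sim), 1e-6)
  }
})

test_that("a fixed seed gives bit-identical exit records", {
  dom <- tst_block(nz = 40, mus = 5, g = 0.8, n = 1.4)
  s1 <- mc_simulate(dom, mc_source(12.5, 12.5, 3, 3000, 42), time_grid(4.8, 24))
  s2 <- mc_simulate(dom, mc_source(12.5, 12.5, 3, 3000, 42), time_grid(4.8, 24))
  expect_identical(s1$exits, s2$exits)
  expect_identical(s1$ledger, s2$ledger)
})

test_that("a ballistic reflector at 500 um returns in the expected time gate", {
  dom <- voxel_domain(c(5, 5, 200), 5, n = 1)
  dom$n[, , 101:200] <- 3.5               # specular step at z = 500 um
  sim <- mc_simulate(dom, mc_source(12.5, 12.5, 2, 10000, 7), time_grid())
  a <- extract_mc_ascan(sim)
  expect_equal(which.max(a$flux), 139)
  # t = 2 * 500 / c = 3.336 ps
  expect_lt(abs(a$depth_um[139] - 500), time_grid()$dz_um)
  # detected weight is the normal-incidence Fresnel reflectance
  expect_equal(max(a$flux), ((3.5 - 1) / (3.5 + 1))^2, tolerance = 1e-6)
})

test_that("the NA gate is monotone and an index-matched medium is silent", {
  dom <- tst_block(nz = 40, mus = 8, g = 0.5, n = 1.3)
  sim <- mc_simulate(dom, mc_source(12.5, 12.5, 3, 5000, 9), time_grid(4.8, 24))
  w_small <- sum(extract_mc_ascan(sim, na = 0.1)$flux)
  w_full <- sum(extract_mc_ascan(sim, na = 1)$flux)
  expect_gte(w_full, w_small)

  # index-matched non-scattering medium: nothing comes back
  dom0 <- tst_block(nz = 40, n = 1)
  sim0 <- mc_simulate(dom0, mc_source(12.5, 12.5, 2, 2000, 1), time_grid(4.8, 24))
  expect_message(a0 <- extract_mc_ascan(sim0), "all-zero")
  expect_true(all(a0$flux == 0))
})

test_that("the confocal overlap factor matches its defining integral", {
  oc <- overlap_config(w0_um = 10, lambda_um = 4, zf_um = 50)
  expect_equal(overlap_correction(50, oc), 1)

  skip_if_not_installed("pracma")
  # quadrature oracle: overlap of the focal-plane Gaussian with the return
  # beam at 2(z - zF) from focus, amplitude width w(d) = w0 sqrt(1 + (d
  # lambda / (pi w0^2))^2)
  overlap_quad <- function(z, w0, lam, zf) {
    d <- 2 * (z - zf)
    w2 <- w0 * sqrt(1 + (d * lam / (pi * w0^2))^2)
    u1 <- function(x, y) exp(-(x^2 + y^2) / w0^2)
    u2 <- function(x, y) exp(-(x^2 + y^2) / w2^2)
    L <- 6 * max(w0, w2)
    ii <- function(f) pracma::quad2d(f, -L, L, -L, L, n = 128)
    num <- ii(function(x, y) u1(x, y) * u2(x, y))
    d1 <- ii(function(x, y) u1(x, y)^2)
    d2 <- ii(function(x, y) u2(x, y)^2)
    num^2 / (d1 * d2)
  }
  expect_equal(overlap_correction(150, oc), overlap_quad(150, 10, 4, 50),
               tolerance = 1e-6)

  # far-from-focus asymptote: C (z - zF)^2 -> pi^2 w0^4 / lambda^2
  zz <- 50 + c(1e4, 1e5, 1e6)
  lim <- overlap_correction(zz, oc) * (zz - 50)^2
  expect_equal(lim[3], pi^2 * 10^4 / 4^2, tolerance = 1e-3)
  expect_error(overlap_config(-1, 4, 0), "> 0")
})

test_that("roll-off and overlap corrections multiply elementwise", {
  dom <- tst_block(nz = 40, mus = 8, g = 0.5, n = 1.3)
  sim <- mc_simulate(dom, mc_source(12.5, 12.5, 3, 3000, 2), time_grid(4.8, 24))
  a <- extract_mc_ascan(sim)
  expect_equal(apply_corrections(a, rolloff = rep(1, length(a$flux)))$flux,
               a$flux)
  oc <- overlap_config(10, 4, 30)
  ro <- rolloff_attenuation(a$depth_um, 2.7, sqrt(3576 * 4625))^2  # power
  hand <- a$flux * ro * overlap_correction(a$depth_um, oc)
  expect_equal(apply_corrections(a, rolloff = ro, overlap = oc)$flux, hand)
  # constant flux is maximal in focus under the overlap correction
  a2 <- a; a2$flux <- rep(1, length(a$flux))
  cfl <- apply_corrections(a2, overlap = oc)$flux
  expect_equal(a$depth_um[which.max(cfl)], 30, tolerance = 4)
  expect_error(apply_corrections(a, rolloff = rep(1, 3)), "depth range")
})

test_that("B-scan bookkeeping: line count, determinism, lateral axis", {
  dom <- tst_block(nxy = 40, nz = 20, mus = 5, g = 0.5, n = 1.3)  # 200 um wide
  tg <- time_grid(2.4, 24)
  bs <- run_mc_bscan(dom, tg, lateral_step_um = 10, nphoton = 300, seed = 5)
  expect_equal(ncol(bs$flux), 20)
  expect_equal(diff(bs$lateral_um)[1], 10)
  # identical seed per line on a laterally uniform domain: identical lines.
  # The domain is wide enough that no photon can reach a side wall within
  # the time gate (max path c*T = 300 um < 350 um wall distance), so the
  # shared RNG stream cannot diverge between lines.
  domw <- voxel_domain(c(280, 280, 20), 5, mus = 5, g = 0.8, n = 1.3)
  tgs <- time_grid(0.96, 24)
  bs2 <- run_mc_bscan(domw, tgs, lateral_step_um = 700, nphoton = 300,
                      seed = 5, width_um = 3, line_seeds = 123)
  expect_equal(ncol(bs2$flux), 2)
  expect_identical(bs2$flux[, 2], bs2$flux[, 1])
  expect_error(run_mc_bscan(dom, tg, lateral_step_um = 500), "larger")
})

test_that("a mirrored domain gives a statistically mirrored response", {
  set.seed(4)
  dims <- c(30, 5, 20)
  mus <- array(2, dims)
  mus[1:10, , 5:12] <- 25          # off-centre scattering block
  dom <- voxel_domain(dims, 5, mus = mus, g = 0.6, n = 1.35)
  mus_m <- mus[dims[1]:1, , , drop = FALSE]
  dom_m <- voxel_domain(dims, 5, mus = mus_m, g = 0.6, n = 1.35)
  x0 <- 25; x0_m <- dims[1] * 5 - 25
  tg <- time_grid(2.88, 24)
  s <- mc_simulate(dom, mc_source(x0, 12.5, 3, 20000, 21), tg)
  sm <- mc_simulate(dom_m, mc_source(x0_m, 12.5, 3, 20000, 21), tg)
  w <- sum(extract_mc_ascan(s)$flux)
  wm <- sum(extract_mc_ascan(sm)$flux)
  sig <- function(sim) {
    ex <- sim$exits
    keep <- sqrt(ex[, "ux"]^2 + ex[, "uy"]^2) <= 0.1
    sqrt(sum(ex[keep, "weight"]^2)) / sim$ledger[["launched"]]
  }
  expect_lt(abs(w - wm), 3 * sqrt(sig(s)^2 + sig(sm)^2) + 1e-12)
})
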