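mk_stack <- function(mneg, mpos, offsets = c(-3, 3)) {
  d <- array(c(mneg, mpos), c(length(mneg), 1, 2))
  zspectrum_stack(d, offsets)
}

test_that("MTRasym evaluates the asymmetry ratio and flags bad pixels", {
  m <- compute_mtr_asym(mk_stack(0.80, 0.60))
  expect_equal(m$contrast_pct[1, 1], 25)
  m0 <- compute_mtr_asym(mk_stack(0.7, 0.7))
  expect_equal(m0$contrast_pct[1, 1], 0)
  mbad <- compute_mtr_asym(mk_stack(0, 0.5))
  expect_false(mbad$valid[1, 1])
  expect_true(is.na(mbad$contrast_pct[1, 1]))
})

test_that("MTRasym is zero on symmetric spectra and invariant to global scaling", {
  offs <- two_sided_offsets()
  set.seed(5)
  half <- runif(3, 0.4, 0.9)
  d <- array(rep(c(rev(half), half), each = 4), c(2, 2, 6))
  st <- zspectrum_stack(d, offs)
  expect_equal(compute_mtr_asym(st)$contrast_pct, matrix(0, 2, 2))
  st2 <- zspectrum_stack(0.37 * d, offs)
  da <- array(abs(rnorm(2 * 2 * 6, 0.6, 0.1)), c(2, 2, 6))
  sa <- zspectrum_stack(da, offs)
  sb <- zspectrum_stack(2.9 * da, offs)
  expect_equal(compute_mtr_asym(sa)$contrast_pct,
               compute_mtr_asym(sb)$contrast_pct, tolerance = 1e-12)
})

test_that("MTRasym on a noiseless phantom matches the forward-model oracle", {
  spec <- tiny_phantom(noise = 0)
  spec$b0_hz[] <- 0; spec$b1_scale[] <- 1
  ph <- generate_phantom(spec, fast_scheme())
  m <- compute_mtr_asym(ph$stack)
  ctrl <- spec$region_map == 2
  w <- water_pool(); g <- glutamate_pool(12.3); cr <- creatine_pool()
  z <- simulate_zspectrum(list(w, cr, g), fast_scheme(offsets = c(-3, 3)))
  oracle <- 100 * (z[["-3"]] - z[["3"]]) / z[["-3"]]
  expect_lt(abs(mean(m$contrast_pct[ctrl]) - oracle), 0.1)
  expect_equal(mean(m$contrast_pct[ctrl]),
               mean(ph$truth_glucest[ctrl]), tolerance = 1e-8)
})

test_that("correct_b0 is the identity at zero field and undoes a known shift", {
  spec <- tiny_phantom(noise = 0)
  spec$b0_hz[] <- 0; spec$b1_scale[] <- 1
  sch <- saturation_scheme()  # full +-2.5..3.5 ppm ladder
  ph0 <- generate_phantom(spec, sch)
  st_id <- correct_b0(ph0$stack, matrix(0, 12, 16))
  expect_equal(st_id$data, ph0$stack$data, tolerance = 1e-12)

  # same phantom with a uniform +0.2 ppm shift: corrected map within 0.2 pp
  spec_s <- tiny_phantom(noise = 0)
  spec_s$b0_hz[] <- 0.2 * HZ_PER_PPM_9T4; spec_s$b1_scale[] <- 1
  ph_s <- generate_phantom(spec_s, sch)
  m_ref <- compute_mtr_asym(ph0$stack)
  m_cor <- compute_mtr_asym(correct_b0(ph_s$stack, spec_s$b0_hz))
  tis <- spec$region_map > 0
  expect_lt(max(abs(m_cor$contrast_pct - m_ref$contrast_pct)[tis],
                na.rm = TRUE), 0.2)
  # and the uncorrected map is materially biased in comparison
  m_raw <- compute_mtr_asym(ph_s$stack)
  expect_gt(max(abs(m_raw$contrast_pct - m_ref$contrast_pct)[tis]), 1)
})

test_that("correct_b0 refuses extrapolation and small ladders", {
  spec <- tiny_phantom(grid = c(8, 8), noise = 0)
  spec$b0_hz[] <- 0; spec$b1_scale[] <- 1
  ph <- generate_phantom(spec, saturation_scheme())
  big <- matrix(1.0 * HZ_PER_PPM_9T4, 8, 8)  # 1 ppm pushes 3 ppm to 4 ppm
  st <- correct_b0(ph$stack, big)
  m <- compute_mtr_asym(st)
  expect_true(all(!m$valid[spec$region_map > 0]))
  d2 <- array(0.5, c(2, 2, 4))
  expect_error(correct_b0(zspectrum_stack(d2, c(-3, -2.5, 2.5, 3)),
                          matrix(0, 2, 2)), "3 offsets per side")
})

test_that("correct_b1 rescales linearly and polices the plausibility band", {
  m <- compute_mtr_asym(mk_stack(c(0.8, 0.8, 0.8), c(0.62, 0.62, 0.62)))
  id <- correct_b1(m, matrix(1, 3, 1))
  expect_equal(id$contrast_pct, m$contrast_pct)
  sc <- correct_b1(m, matrix(0.9, 3, 1))
  expect_equal(sc$contrast_pct, m$contrast_pct / 0.9)
  expect_true(sc$corrections[["b1"]])
  bad <- correct_b1(m, matrix(c(1, 0.4, 1.6), 3, 1))
  expect_equal(bad$valid[, 1], c(TRUE, FALSE, FALSE))
  # 22.5% at b1 = 0.9 corrects to 25%
  m1 <- compute_mtr_asym(mk_stack(0.8, 0.8 * (1 - 0.225)))
  expect_equal(correct_b1(m1, matrix(0.9, 1, 1))$contrast_pct[1, 1], 25,
               tolerance = 1e-9)
})

test_that("B1 correction approximately restores region means for a smooth field", {
  spec <- tiny_phantom(noise = 0)
  spec$b0_hz[] <- 0
  ph_ref <- local({ s <- spec; s$b1_scale[] <- 1; generate_phantom(s, fast_scheme()) })
  ph_b1 <- generate_phantom(spec, fast_scheme())  # b1 spans 0.85-1.15
  m_ref <- compute_mtr_asym(ph_ref$stack)
  m_cor <- correct_b1(compute_mtr_asym(ph_b1$stack), spec$b1_scale)
  for (lab in 2:3) {
    r <- spec$region_map == lab
    rel <- abs(mean(m_cor$contrast_pct[r]) - mean(m_ref$contrast_pct[r])) /
      mean(m_ref$contrast_pct[r])
    expect_lt(rel, 0.05)  # first-order correction is approximate
  }
})

test_that("asymmetry_curve summarises ROI spectra and peaks at the amine offset", {
  offs <- zspectrum_offsets(5, 0.5)
  spec <- tiny_phantom(grid = c(8, 8), noise = 0)
  spec$b0_hz[] <- 0; spec$b1_scale[] <- 1
  spec$region_pools <- list(tissue = list(water_pool()),
                            `striatum-control` = brain_pools(12.3),
                            `striatum-lesion` = brain_pools(14.4))
  ph <- generate_phantom(spec, fast_scheme(offs))
  # water-only ROI: MTRasym identically 0
  cw <- asymmetry_curve(ph$stack, spec$region_map == 1)
  expect_equal(cw$mtr_asym_pct, rep(0, nrow(cw)), tolerance = 1e-9)
  # glutamate ROI: a broad amine peak around +2-3 ppm (fast exchange at
  # 5500 /s spreads the apparent maximum upfield of the 3 ppm resonance)
  cg <- asymmetry_curve(ph$stack, spec$region_map == 3)
  pk <- cg$offset[which.max(cg$mtr_asym_pct)]
  expect_gte(pk, 1.5); expect_lte(pk, 3.5)
  at <- function(x) cg$mtr_asym_pct[cg$offset == x]
  expect_gt(at(3), at(1))
  expect_gt(at(3), at(5))
  expect_gt(at(3), 0.75 * max(cg$mtr_asym_pct))
  # one-pixel ROI equals that pixel's spectrum
  px <- which(spec$region_map == 2, arr.ind = TRUE)[1, , drop = FALSE]
  one <- matrix(FALSE, 8, 8); one[px] <- TRUE
  c1 <- asymmetry_curve(ph$stack, one)
  expect_equal(attr(c1, "z_full")$z, ph$stack$data[px[1], px[2], ])
  # asymmetric ladders are rejected
  d <- array(0.5, c(2, 2, 3))
  expect_error(asymmetry_curve(zspectrum_stack(d, c(-3, 2.5, 3)),
                               matrix(TRUE, 2, 2)), "symmetric")
})
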