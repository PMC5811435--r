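test_that("pool and scheme validation rejects unphysical inputs", {
  expect_error(cest_pool("x", 3, 10, 100, T1 = 1, T2 = 2), "T2")
  expect_error(cest_pool("x", 3, -1, 100, 1, 0.1), "proton_concentration")
  expect_error(cest_pool("x", 3, 10, -5, 1, 0.1), "exchange_rate")
  expect_error(cest_pool("x", 3, 10, 5, 0, 0.1), "positive")
  expect_error(saturation_scheme(offsets = c(3, 3)), "unique")
  expect_error(simulate_zspectrum(list(glutamate_pool(10)), fast_scheme()),
               "water")
})

test_that("no saturation gives full signal and water-only spectra are symmetric", {
  offs <- two_sided_offsets()
  z0 <- simulate_zspectrum(brain_pools(), fast_scheme(offs, peak_b1 = 0))
  expect_equal(unname(z0), rep(1, length(offs)))

  zw <- simulate_zspectrum(list(water_pool()), fast_scheme(offs))
  expect_true(all(zw >= 0 & zw <= 1))
  expect_equal(unname(zw[1:3]), unname(rev(zw[4:6])), tolerance = 1e-12)
})

test_that("matrix-exponential integrator matches the RK4 brute-force oracle", {
  w <- water_pool(); g <- glutamate_pool(12.3)
  sch <- fast_scheme(offsets = c(-3, 3))
  z <- simulate_zspectrum(list(w, g), sch)
  expect_lt(z[["3"]], z[["-3"]])  # amine pool at +3 ppm depletes downfield
  zo <- c(rk4_two_pool_z(w, g, -3, 250, dt = 2e-5),
          rk4_two_pool_z(w, g, 3, 250, dt = 2e-5))
  expect_lt(max(abs(unname(z) - zo)), 1e-4)
  # and off the target offset, with a B0/B1 perturbation
  z2 <- simulate_zspectrum(list(w, g), fast_scheme(offsets = 2.75),
                           b0_shift = 0.15, b1_scale = 0.9)
  zo2 <- rk4_two_pool_z(w, g, 2.75, 250 * 0.9, b0_shift = 0.15, dt = 2e-5)
  expect_lt(abs(unname(z2) - zo2), 1e-4)
})

test_that("GluCEST is strictly increasing in glutamate concentration (0-20 mM)", {
  sch <- fast_scheme(offsets = c(-3, 3))
  asym <- vapply(c(0, 5, 10, 15, 20), function(c_mM) {
    pools <- if (c_mM == 0) list(water_pool()) else brain_pools(c_mM)
    z <- simulate_zspectrum(pools, sch)
    100 * (z[["-3"]] - z[["3"]]) / z[["-3"]]
  }, numeric(1))
  expect_true(all(diff(asym) > 0))
  expect_equal(asym[1], 0, tolerance = 1e-10)
})

test_that("pulsed-train integration agrees with CW for negligible gaps and differs for long gaps", {
  pools <- brain_pools()
  z_cw <- simulate_zspectrum(pools, saturation_scheme(inter_pulse_delay = 0,
                                                      offsets = 3))
  z_gap <- simulate_zspectrum(pools, saturation_scheme(inter_pulse_delay = 10e-6,
                                                       offsets = 3))
  expect_equal(unname(z_cw), unname(z_gap), tolerance = 1e-6)
  z_long <- simulate_zspectrum(pools, saturation_scheme(inter_pulse_delay = 0.1,
                                                        offsets = 3))
  expect_gt(abs(unname(z_long) - unname(z_cw)), 1e-4)  # gaps matter when long
  expect_true(z_long >= 0 && z_long <= 1)
})

test_that("phantom generation is deterministic and region-consistent", {
  spec <- tiny_phantom(noise = 0)
  spec$b0_hz[] <- 0
  spec$b1_scale[] <- 1
  sch <- fast_scheme()
  ph <- generate_phantom(spec, sch)
  # zero noise + uniform fields: identical spectra within a region
  for (lab in 1:3) {
    px <- which(spec$region_map == lab, arr.ind = TRUE)
    ref <- ph$stack$data[px[1, 1], px[1, 2], ]
    for (r in seq_len(nrow(px)))
      expect_equal(ph$stack$data[px[r, 1], px[r, 2], ], ref)
  }
  # higher-glutamate region has higher ground-truth contrast
  expect_gt(mean(ph$truth_glucest[spec$region_map == 3]),
            mean(ph$truth_glucest[spec$region_map == 2]))
  # seeded reproducibility with noise on
  spec2 <- tiny_phantom(noise = 0.01)
  ph_a <- generate_phantom(spec2, sch)
  ph_b <- generate_phantom(spec2, sch)
  expect_identical(ph_a$stack$data, ph_b$stack$data)
  expect_true(all(ph_a$stack$data >= 0))
  # unknown region label rejected
  bad <- tiny_phantom()
  bad$region_map[1, 1] <- 9L
  expect_error(generate_phantom(bad, sch), "label")
})

test_that("field-map acquisitions follow the stated phase and sine laws", {
  spec <- tiny_phantom(noise = 0)
  spec$b0_hz[] <- 0
  acq <- generate_fieldmap_acquisitions(spec)
  dph <- acq$phase[, , 2] - acq$phase[, , 1]
  expect_equal(max(abs(dph[spec$region_map > 0])), 0, tolerance = 1e-12)

  spec$b0_hz[] <- 200
  acq <- generate_fieldmap_acquisitions(spec)
  dph <- (acq$phase[, , 2] - acq$phase[, , 1]) %% (2 * pi)
  tis <- spec$region_map > 0
  expect_equal(unique(round(dph[tis], 10)), 2 * pi * 200 * 0.5e-3,
               tolerance = 1e-8)
  # flip-angle pair must be (alpha, 2*alpha)
  expect_error(generate_fieldmap_acquisitions(spec, flip_angles = c(30, 70)),
               "2\\*alpha")
  expect_error(generate_fieldmap_acquisitions(spec, te_list = 3.5e-3),
               "two echo")
})

test_that("cohort generator honours the generating line and its spec", {
  sp0 <- cohort_spec(noise_sd_glucest = 0, rng_seed = 3L)
  coh <- generate_cohort(sp0)
  expect_equal(coh$glucest_pct, 1.31 * coh$glu_mM + 6.81, tolerance = 1e-12)
  expect_identical(coh, generate_cohort(sp0))

  # group-mean GluCEST matches the closed-form expectation within MC error:
  # E[y | group] = 1.31 * mu_group + 6.81 -> 22.92 and 25.67
  sets <- lapply(1:8, function(s)
    generate_cohort(cohort_spec(rng_seed = s)))
  big <- do.call(rbind, sets)
  m <- tapply(big$glucest_pct, big$group, mean)
  se <- 1.31 * 1.1 / sqrt(8 * 16)  # conservative MC standard error
  expect_lt(abs(m[["control"]] - (1.31 * 12.3 + 6.81)), 4 * se)
  expect_lt(abs(m[["lesion"]] - (1.31 * 14.4 + 6.81)), 4 * se)

  # noise-free repeats have zero intra-subject CV
  coh3 <- generate_cohort(cohort_spec(noise_sd_glucest = 0,
                                      n_repeat_scans = 3L))
  rep <- reproducibility_cv(coh3, "glucest_pct")
  expect_equal(rep$intra_cv_mean, 0)
  expect_equal(max(rep$per_subject_cv), 0)
})

test_that("correlated-error mode ties GluCEST noise to the [Glu] draw", {
  sp <- cohort_spec(error_correlation = 0.9, rng_seed = 11L)
  coh <- generate_cohort(sp)
  resid <- coh$glucest_pct - coh$glucest_true
  dev <- ave(coh$glu_mM, coh$group, FUN = function(v) v - mean(v))
  expect_gt(cor(resid, dev), 0.5)
})
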