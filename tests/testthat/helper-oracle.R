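# Independent brute-force oracle for the Bloch-McConnell forward model:
# a fixed-step RK4 explicit time stepper over a hand-written two-pool
# derivative (water pool w, solute pool s exchanging with water). Written
# directly from the exchange-relaxation equations, sharing no code with the
# package's matrix-exponential integrator.
rk4_two_pool_z <- function(water, solute, offset_ppm, b1_hz,
                           t_sat = 1, b0_shift = 0, hz_per_ppm = 400.2,
                           dt = 1e-5) {
  fs <- solute$proton_concentration / water$proton_concentration
  ks <- solute$exchange_rate          # solute -> water
  kw <- ks * fs                       # water -> solute (detailed balance)
  w1 <- 2 * pi * b1_hz
  dw_w <- 2 * pi * hz_per_ppm * (water$chemical_shift + b0_shift - offset_ppm)
  dw_s <- 2 * pi * hz_per_ppm * (solute$chemical_shift + b0_shift - offset_ppm)
  R1w <- 1 / water$T1; R2w <- 1 / water$T2
  R1s <- 1 / solute$T1; R2s <- 1 / solute$T2

  deriv <- function(m) {
    xw <- m[1]; yw <- m[2]; zw <- m[3]
    xs <- m[4]; ys <- m[5]; zs <- m[6]
    c(dw_w * yw - R2w * xw - kw * xw + ks * xs,
      -dw_w * xw + w1 * zw - R2w * yw - kw * yw + ks * ys,
      -w1 * yw - R1w * (zw - 1) - kw * zw + ks * zs,
      dw_s * ys - R2s * xs - ks * xs + kw * xw,
      -dw_s * xs + w1 * zs - R2s * ys - ks * ys + kw * yw,
      -w1 * ys - R1s * (zs - fs) - ks * zs + kw * zw)
  }
  m <- c(0, 0, 1, 0, 0, fs)
  nstep <- ceiling(t_sat / dt)
  h <- t_sat / nstep
  for (i in seq_len(nstep)) {
    k1 <- deriv(m)
    k2 <- deriv(m + h / 2 * k1)
    k3 <- deriv(m + h / 2 * k2)
    k4 <- deriv(m + h * k3)
    m <- m + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  m[3]
}

# small helpers shared across test files
two_sided_offsets <- function() c(-3.5, -3, -2.5, 2.5, 3, 3.5)

fast_scheme <- function(offsets = two_sided_offsets(), peak_b1 = 250)
  saturation_scheme(offsets = offsets, peak_b1 = peak_b1)

brain_pools <- function(glu_mM = 12.3) list(water_pool(), glutamate_pool(glu_mM))

# tiny phantom spec used by image-level tests
tiny_phantom <- function(grid = c(12, 16), noise = 0, seed = 42L, ...)
  phantom_spec(grid_shape = grid, noise_sigma = noise, rng_seed = seed, ...)
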