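# Bloch-McConnell forward model and synthetic-data generators.

# Build the augmented (3n+1) Bloch-McConnell generator matrix for a star
# exchange topology (every solute exchanges with water, pool 1). State is
# (Mx_1, My_1, Mz_1, ..., Mx_n, My_n, Mz_n, 1); the trailing 1 carries the
# R1*M0 recovery terms so the system is homogeneous and a single matrix
# exponential propagates it. M0 is normalised to water = 1.
# offset_ppm: saturation frequency; b0_shift shifts all pool resonances.
bloch_matrix <- function(pools, offset_ppm, omega1, b0_shift = 0,
                         hz_per_ppm = HZ_PER_PPM_9T4) {
  n <- length(pools)
  f <- vapply(pools, `[[`, numeric(1), "proton_concentration")
  f <- f / f[1]
  k <- vapply(pools, `[[`, numeric(1), "exchange_rate")
  shift <- vapply(pools, `[[`, numeric(1), "chemical_shift")
  R1 <- 1 / vapply(pools, `[[`, numeric(1), "T1")
  R2 <- 1 / vapply(pools, `[[`, numeric(1), "T2")
  delta <- 2 * pi * hz_per_ppm * (shift + b0_shift - offset_ppm)

  A <- matrix(0, 3 * n + 1, 3 * n + 1)
  ksum <- if (n > 1) sum(k[-1] * f[-1]) else 0
  for (i in seq_len(n)) {
    ix <- 3 * (i - 1) + 1
    kout <- if (i == 1) ksum else k[i]
    A[ix, ix] <- -R2[i] - kout
    A[ix, ix + 1] <- delta[i]
    A[ix + 1, ix] <- -delta[i]
    A[ix + 1, ix + 1] <- -R2[i] - kout
    A[ix + 1, ix + 2] <- omega1
    A[ix + 2, ix + 1] <- -omega1
    A[ix + 2, ix + 2] <- -R1[i] - kout
    A[ix + 2, 3 * n + 1] <- R1[i] * f[i]
    if (i > 1) {
      # water <- solute i and solute i <- water, per component
      for (d in 0:2) {
        A[1 + d, ix + d] <- k[i]
        A[ix + d, 1 + d] <- k[i] * f[i]
      }
    }
  }
  A
}

#' Simulate a z-spectrum from a multi-pool exchange model
#'
#' Integrates the coupled Bloch-McConnell equations through the saturation
#' pulse train for each offset and returns the normalised water longitudinal
#' magnetization Z = M_sat/M0. The system is piecewise linear time-invariant,
#' so each pulse (and inter-pulse gap, when non-negligible) is propagated by
#' an exact matrix exponential; gaps shorter than 0.1 ms are folded into
#' continuous-wave saturation, which for the default 100% duty-cycle scheme
#' makes the train equivalent to 1 s of continuous saturation.
#'
#' @param pools List of [cest_pool()]s; the first must be water (the pool all
#'   others exchange with).
#' @param scheme A [saturation_scheme()].
#' @param b0_shift Static-field offset at this location, ppm: all pool
#'   resonances (water included) are shifted by this amount, so the observed
#'   spectrum minimum moves to `b0_shift`.
#' @param b1_scale Relative transmit field: multiplies the nominal peak B1.
#' @param hz_per_ppm Hz per ppm conversion (field strength).
#' @param offsets Optional offsets (ppm) overriding `scheme$offsets`.
#' @return Named numeric vector of Z values in \[0, 1\], one per offset.
#' @examples
#' sch <- saturation_scheme(offsets = c(-3, 3))
#' simulate_zspectrum(list(water_pool(), glutamate_pool(12.3)), sch)
#' @export
simulate_zspectrum <- function(pools, scheme, b0_shift = 0, b1_scale = 1,
                               hz_per_ppm = HZ_PER_PPM_9T4, offsets = NULL) {
  if (inherits(pools, "cest_pool")) pools <- list(pools)
  stopifnot(length(pools) >= 1, all(vapply(pools, inherits, TRUE, "cest_pool")),
            inherits(scheme, "saturation_scheme"))
  if (pools[[1]]$exchange_rate != 0)
    stop("first pool must be water (exchange_rate 0)")
  if (!is.finite(b0_shift) || !is.finite(b1_scale) || b1_scale < 0)
    stop("b0_shift must be finite and b1_scale finite, non-negative")
  offs <- if (is.null(offsets)) scheme$offsets else as.numeric(offsets)
  if (any(!is.finite(offs))) stop("offsets must be finite")

  n <- length(pools)
  f <- vapply(pools, `[[`, numeric(1), "proton_concentration")
  f <- f / f[1]
  m0 <- numeric(3 * n + 1)
  m0[3 * (seq_len(n) - 1) + 3] <- f  # equilibrium: Mz = M0, transverse 0
  m0[3 * n + 1] <- 1

  omega1 <- 2 * pi * scheme$peak_b1 * b1_scale
  cw <- scheme$inter_pulse_delay < 1e-4
  z <- vapply(offs, function(off) {
    A_sat <- bloch_matrix(pools, off, omega1, b0_shift, hz_per_ppm)
    m <- m0
    if (cw) {
      tt <- scheme$pulse_count * scheme$pulse_duration
      P <- tryCatch(expm_pade(A_sat * tt), error = function(e)
        stop(sprintf("integration failed at offset %g ppm (%d pools): %s",
                     off, n, conditionMessage(e)), call. = FALSE))
      m <- P %*% m
    } else {
      P_sat <- expm_pade(A_sat * scheme$pulse_duration)
      A_free <- bloch_matrix(pools, off, 0, b0_shift, hz_per_ppm)
      P_free <- expm_pade(A_free * scheme$inter_pulse_delay)
      for (p in seq_len(scheme$pulse_count)) {
        m <- P_sat %*% m
        if (p < scheme$pulse_count) m <- P_free %*% m
      }
    }
    m[3]
  }, numeric(1))
  z <- pmin(pmax(z, 0), 1)
  names(z) <- format(offs, trim = TRUE)
  z
}

#' Phantom specification
#'
#' Describes a synthetic imaging phantom: a label image assigning each pixel
#' a pool set, smooth B0 (Hz) and relative B1 fields, and a magnitude noise
#' level. The default phantom emulates a coronal brain slice with two
#' striatum-like square regions embedded in tissue: a control-like region at
#' 12.3 mM glutamate and a lesioned region at 14.4 mM, over a creatine-bearing
#' tissue background, with a smooth B0 field spanning `b0_amp_ppm` and a B1
#' field spanning `b1_range`.
#'
#' @param grid_shape Image dimensions, pixels (length 2).
#' @param glu_mM Glutamate concentration (mM) of the two striatal regions.
#' @param include_creatine Add a creatine background pool to all tissue?
#' @param b0_amp_ppm Peak-to-mean amplitude of the smooth B0 field, ppm.
#' @param b1_range Range (min, max) of the smooth relative B1 field.
#' @param noise_sigma Gaussian noise SD per complex channel, as a fraction of
#'   the unsaturated signal (magnitude noise is Rician).
#' @param rng_seed Integer seed making the phantom reproducible.
#' @param hz_per_ppm Hz per ppm conversion.
#' @return A `phantom_spec` object with fields `region_map` (integer matrix;
#'   0 = air), `region_pools` (named list of pool lists), `b0_hz`, `b1_scale`
#'   (matrices), `noise_sigma`, `rng_seed`.
#' @export
phantom_spec <- function(grid_shape = c(32, 32),
                         glu_mM = c(12.3, 14.4),
                         include_creatine = TRUE,
                         b0_amp_ppm = 0.3,
                         b1_range = c(0.85, 1.15),
                         noise_sigma = 0,
                         rng_seed = 1L,
                         hz_per_ppm = HZ_PER_PPM_9T4) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 8),
            length(glu_mM) == 2, noise_sigma >= 0,
            length(b1_range) == 2, all(b1_range > 0))
  nx <- grid_shape[1]; ny <- grid_shape[2]
  region_map <- matrix(0L, nx, ny)
  # tissue disc
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  xx <- matrix(seq_len(nx), nx, ny); yy <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  tissue <- ((xx - cx) / (0.45 * nx))^2 + ((yy - cy) / (0.45 * ny))^2 <= 1
  region_map[tissue] <- 1L
  # two square "striata" left/right of centre
  w <- max(2L, floor(min(nx, ny) / 5))
  rx <- floor(cx - w / 2) + seq_len(w) - 1L
  y1 <- floor(cy - w - 1) + seq_len(w) - 1L
  y2 <- ceiling(cy + 1) + seq_len(w) - 1L
  region_map[rx, y1] <- 2L
  region_map[rx, y2] <- 3L

  base <- list(water_pool())
  if (include_creatine) base <- c(base, list(creatine_pool()))
  region_pools <- list(
    tissue = base,
    `striatum-control` = c(base, list(glutamate_pool(glu_mM[1]))),
    `striatum-lesion` = c(base, list(glutamate_pool(glu_mM[2]))))

  # smooth fields: tilted plane plus a gentle bump, scaled to spec
  u <- (xx - cx) / nx; v <- (yy - cy) / ny
  b0 <- u + 0.6 * v + 0.5 * exp(-(u^2 + v^2) / 0.08)
  b0 <- b0 - mean(b0[region_map > 0])
  b0 <- b0 / max(abs(b0[region_map > 0])) * b0_amp_ppm * hz_per_ppm
  b1 <- 0.7 * u - v + exp(-((u - 0.1)^2 + (v + 0.1)^2) / 0.1)
  b1 <- (b1 - min(b1)) / diff(range(b1))
  b1 <- b1_range[1] + b1 * diff(b1_range)

  structure(list(grid_shape = as.integer(grid_shape),
                 region_map = region_map, region_pools = region_pools,
                 b0_hz = b0, b1_scale = b1, noise_sigma = noise_sigma,
                 rng_seed = as.integer(rng_seed), hz_per_ppm = hz_per_ppm),
            class = "phantom_spec")
}

#' Generate a synthetic z-spectrum image stack from a phantom
#'
#' Simulates each pixel's z-spectrum with that pixel's pools, B0 offset and
#' B1 scale via [simulate_zspectrum()], applies Rician magnitude noise, and
#' returns the stack together with ground truth: the noise-free, field-free
#' GluCEST map and the generating fields.
#'
#' @param spec A [phantom_spec()].
#' @param scheme A [saturation_scheme()].
#' @param target_offset Offset (ppm) at which the ground-truth contrast map is
#'   evaluated.
#' @return A list: `stack` (a [zspectrum_stack()]), `truth_glucest` (matrix,
#'   %, NA outside tissue), `b0_hz`, `b1_scale`, `region_map`, `spec`.
#' @export
generate_phantom <- function(spec, scheme, target_offset = 3) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(scheme, "saturation_scheme"))
  labels <- sort(unique(as.vector(spec$region_map)))
  labels <- labels[labels > 0]
  if (any(labels > length(spec$region_pools)))
    stop("region_map contains labels with no defined pool set")
  set.seed(spec$rng_seed)
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]
  noff <- length(scheme$offsets)
  data <- array(0, dim = c(nx, ny, noff))

  uniform <- max(abs(spec$b0_hz)) == 0 && all(spec$b1_scale == spec$b1_scale[1])
  cache <- new.env(parent = emptyenv())
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    lab <- spec$region_map[ix, iy]
    if (lab == 0L) next
    b0p <- spec$b0_hz[ix, iy] / spec$hz_per_ppm
    b1p <- spec$b1_scale[ix, iy]
    if (uniform) {
      key <- as.character(lab)
      if (is.null(cache[[key]]))
        cache[[key]] <- simulate_zspectrum(spec$region_pools[[lab]], scheme,
                                           b0p, b1p, spec$hz_per_ppm)
      data[ix, iy, ] <- cache[[key]]
    } else {
      data[ix, iy, ] <- simulate_zspectrum(spec$region_pools[[lab]], scheme,
                                           b0p, b1p, spec$hz_per_ppm)
    }
  }
  if (spec$noise_sigma > 0) {
    n1 <- array(stats::rnorm(length(data), 0, spec$noise_sigma), dim = dim(data))
    n2 <- array(stats::rnorm(length(data), 0, spec$noise_sigma), dim = dim(data))
    data <- sqrt((data + n1)^2 + n2^2)
  }
  stack <- zspectrum_stack(data, scheme$offsets, scheme,
                           valid = spec$region_map > 0L)

  # ground truth: noise-free, field-free regional contrast
  truth <- matrix(NA_real_, nx, ny)
  for (lab in labels) {
    z <- simulate_zspectrum(spec$region_pools[[lab]], scheme, 0, 1,
                            spec$hz_per_ppm,
                            offsets = c(-target_offset, target_offset))
    truth[spec$region_map == lab] <- 100 * (z[1] - z[2]) / z[1]
  }
  list(stack = stack, truth_glucest = truth, b0_hz = spec$b0_hz,
       b1_scale = spec$b1_scale, region_map = spec$region_map, spec = spec)
}

#' Simulate companion field-mapping acquisitions
#'
#' Generates the acquisitions the B0/B1 reconstruction consumes: multi-echo
#' gradient-echo phase (and magnitude) images whose phase accumulates as
#' 2*pi*B0*TE (wrapped to (-pi, pi]), plus two magnitude images acquired with
#' preparation flip angles alpha and 2*alpha following the sine law scaled by
#' the relative B1 field. Noise is added on the complex channels.
#'
#' @param spec A [phantom_spec()] supplying the B0/B1 fields, tissue mask,
#'   noise level and seed.
#' @param te_list Echo times, s (default 3.5/4.0/4.5 ms).
#' @param flip_angles Two flip angles in degrees; the second must be exactly
#'   double the first (default 30/60).
#' @param phi0 Receiver phase offset at TE = 0, rad.
#' @return List with `phase` and `magnitude` arrays (x, y, TE), `flip_mag`
#'   array (x, y, 2), plus `te_list` and `flip_angles`.
#' @export
generate_fieldmap_acquisitions <- function(spec,
                                           te_list = c(3.5, 4.0, 4.5) * 1e-3,
                                           flip_angles = c(30, 60),
                                           phi0 = 0.3) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(te_list) < 2) stop("need at least two echo times")
  if (length(flip_angles) != 2 || abs(flip_angles[2] - 2 * flip_angles[1]) > 1e-9)
    stop("flip angles must be a (alpha, 2*alpha) pair")
  set.seed(spec$rng_seed + 1L)
  nx <- spec$grid_shape[1]; ny <- spec$grid_shape[2]
  m0 <- ifelse(spec$region_map > 0L, 1, 0)
  noisy <- function(re, im) {
    if (spec$noise_sigma > 0) {
      re <- re + stats::rnorm(length(re), 0, spec$noise_sigma)
      im <- im + stats::rnorm(length(im), 0, spec$noise_sigma)
    }
    list(mag = sqrt(re^2 + im^2), ph = atan2(im, re))
  }
  phase <- array(0, c(nx, ny, length(te_list)))
  mag <- array(0, c(nx, ny, length(te_list)))
  for (j in seq_along(te_list)) {
    ph <- 2 * pi * spec$b0_hz * te_list[j] + phi0
    s <- noisy(m0 * cos(ph), m0 * sin(ph))
    phase[, , j] <- s$ph
    mag[, , j] <- s$mag
  }
  flip_mag <- array(0, c(nx, ny, 2))
  for (j in 1:2) {
    amp <- m0 * abs(sin(flip_angles[j] * pi / 180 * spec$b1_scale))
    s <- noisy(amp, 0 * amp)
    flip_mag[, , j] <- s$mag
  }
  list(phase = phase, magnitude = mag, flip_mag = flip_mag,
       te_list = te_list, flip_angles = flip_angles)
}

#' Cohort specification for the calibration study
#'
#' Parameters of the two-group animal cohort generator. Defaults are the
#' study's printed values: control n = 16 with \[Glu\] 12.3 +/- 1.0 mM,
#' lesioned n = 19 with 14.4 +/- 1.1 mM, generating line
#' GluCEST = 1.31 %/mM x \[Glu\] + 6.81 %, and GluCEST measurement noise SD
#' derived from the target R^2 of 0.86 by [calibration_noise_sd()]
#' (about 0.79 %).
#'
#' @param n_per_group Subjects per group (control, lesion).
#' @param glu_mean_by_group,glu_sd_by_group Group \[Glu\] means/SDs, mM.
#' @param slope_true Generating slope, %/mM.
#' @param intercept_true Generating intercept, %.
#' @param noise_sd_glucest SD of additive Gaussian noise on observed GluCEST,
#'   %, independent per repeat scan.
#' @param glu_meas_sd SD reported for each \[Glu\] value (LCModel-style), mM.
#' @param n_repeat_scans Repeat GluCEST scans per subject.
#' @param error_correlation Correlation between a subject's \[Glu\] draw
#'   deviation and its GluCEST noise (optional correlated-error mode; the
#'   error structure of the original data is unknown). 0 = independent.
#' @param rng_seed Integer seed.
#' @export
cohort_spec <- function(n_per_group = c(16L, 19L),
                        glu_mean_by_group = c(12.3, 14.4),
                        glu_sd_by_group = c(1.0, 1.1),
                        slope_true = 1.31,
                        intercept_true = 6.81,
                        noise_sd_glucest = calibration_noise_sd(),
                        glu_meas_sd = 0.5,
                        n_repeat_scans = 1L,
                        error_correlation = 0,
                        rng_seed = 1L) {
  stopifnot(length(n_per_group) == 2, all(n_per_group >= 2),
            all(glu_sd_by_group >= 0), noise_sd_glucest >= 0,
            n_repeat_scans >= 1, abs(error_correlation) <= 1)
  structure(list(n_per_group = as.integer(n_per_group),
                 glu_mean_by_group = glu_mean_by_group,
                 glu_sd_by_group = glu_sd_by_group,
                 slope_true = slope_true, intercept_true = intercept_true,
                 noise_sd_glucest = noise_sd_glucest,
                 glu_meas_sd = glu_meas_sd,
                 n_repeat_scans = as.integer(n_repeat_scans),
                 error_correlation = error_correlation,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' GluCEST noise SD implied by a target calibration R^2
#'
#' Variance-decomposition oracle: along a line y = b*x + a with predictor
#' variance Var(x), the expected R^2 under additive noise of variance sigma^2
#' is R^2 = s2_fit / (s2_fit + sigma^2) with s2_fit = b^2 * Var(x). Solving
#' for sigma gives the noise level that reproduces a printed R^2. Var(x) for
#' a two-group cohort is the mixture variance of the per-group normals.
#'
#' @param r_squared Target coefficient of determination.
#' @param slope Line slope, %/mM.
#' @param n_per_group,glu_mean_by_group,glu_sd_by_group Cohort composition.
#' @return Noise SD in GluCEST percent units.
#' @examples
#' calibration_noise_sd()  # about 0.79 at the default cohort
#' @export
calibration_noise_sd <- function(r_squared = 0.86, slope = 1.31,
                                 n_per_group = c(16, 19),
                                 glu_mean_by_group = c(12.3, 14.4),
                                 glu_sd_by_group = c(1.0, 1.1)) {
  stopifnot(r_squared > 0, r_squared < 1)
  w <- n_per_group / sum(n_per_group)
  mu <- sum(w * glu_mean_by_group)
  var_x <- sum(w * (glu_sd_by_group^2 + (glu_mean_by_group - mu)^2))
  s2_fit <- slope^2 * var_x
  sqrt(s2_fit * (1 - r_squared) / r_squared)
}

#' Generate a synthetic two-group cohort table
#'
#' Draws per-subject \[Glu\] from the group normals, places true GluCEST on
#' the generating line, and adds Gaussian measurement noise independently per
#' repeat scan. With `error_correlation` non-zero, a subject's GluCEST noise
#' mean is correlated with its \[Glu\] deviation from the group mean.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame (class `cohort_table`) with one row per subject x
#'   scan: `subject_id`, `group`, `scan_index`, `glucest_pct`, `glu_mM`,
#'   `glu_sd_mM`, plus the noise-free `glucest_true`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$rng_seed)
  groups <- c("control", "lesion")
  rows <- list()
  sid <- 0L
  for (g in 1:2) {
    n <- spec$n_per_group[g]
    zg <- stats::rnorm(n)
    glu <- spec$glu_mean_by_group[g] + spec$glu_sd_by_group[g] * zg
    true_cest <- spec$slope_true * glu + spec$intercept_true
    rho <- spec$error_correlation
    for (i in seq_len(n)) {
      sid <- sid + 1L
      eps <- stats::rnorm(spec$n_repeat_scans, 0, spec$noise_sd_glucest)
      if (rho != 0) {
        # shared per-subject component tied to the [Glu] deviation
        eps <- rho * spec$noise_sd_glucest * zg[i] + sqrt(1 - rho^2) * eps
      }
      rows[[sid]] <- data.frame(
        subject_id = sprintf("%s%02d", substr(groups[g], 1, 1), i),
        group = groups[g],
        scan_index = seq_len(spec$n_repeat_scans),
        glucest_pct = true_cest[i] + eps,
        glu_mM = glu[i],
        glu_sd_mM = spec$glu_meas_sd,
        glucest_true = true_cest[i])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_table", "data.frame")
  out
}
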