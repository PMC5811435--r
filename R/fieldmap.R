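# B0 and B1 map reconstruction from companion acquisitions.

# wrap angles to (-pi, pi]
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# unwrap along the last (TE) dimension: successive differences wrapped to
# (-pi, pi], then accumulated. Exact for fields below the delta-TE Nyquist
# limit (|b0| < 1/(2*dTE)).
unwrap_temporal <- function(phase) {
  d <- dim(phase)
  out <- phase
  for (j in 2:d[3]) {
    dd <- wrap_phase(phase[, , j] - phase[, , j - 1])
    out[, , j] <- out[, , j - 1] + dd
  }
  out
}

# simple raster 2-D unwrap of one phase image (rows then columns); adequate
# for smooth fields, used only behind the spatial_unwrap flag.
unwrap_spatial <- function(ph) {
  nx <- nrow(ph); ny <- ncol(ph)
  out <- ph
  # unwrap first column
  for (i in 2:nx)
    out[i, 1] <- out[i - 1, 1] + wrap_phase(ph[i, 1] - ph[i - 1, 1])
  # unwrap each row from its first element
  for (i in seq_len(nx)) for (j in 2:ny)
    out[i, j] <- out[i, j - 1] + wrap_phase(ph[i, j] - ph[i, j - 1])
  out
}

#' Fit a B0 map from multi-echo gradient-echo phase images
#'
#' Per pixel, phase is unwrapped along the echo-time dimension (optionally
#' spatially first) and a least-squares line of phase against TE is fitted;
#' the B0 offset is the slope divided by 2*pi. With evenly smooth fields and
#' echo spacing dTE, any |B0| below 1/(2*dTE) is recovered exactly at zero
#' noise regardless of wrapping.
#'
#' @param phase_images Array (nx, ny, n_TE) of phase, rad.
#' @param te_list Echo times, s; strictly increasing, length >= 2.
#' @param magnitude_images Optional matching magnitude array; pixels with
#'   all-zero magnitude are flagged invalid, and with `weighted = TRUE` the
#'   fit weights each echo by squared magnitude.
#' @param weighted Magnitude-weighted least squares instead of OLS.
#' @param spatial_unwrap Additionally unwrap each echo's image spatially
#'   (raster scan) before the temporal fit.
#' @return List of class `field_maps` pieces: `b0_hz` matrix and
#'   `valid_mask`.
#' @examples
#' te <- c(3.5, 4.0, 4.5) * 1e-3
#' ph <- array(rep(2 * pi * 150 * te, each = 4), c(2, 2, 3))
#' fit_b0_map(ph, te)$b0_hz  # 150 everywhere
#' @export
fit_b0_map <- function(phase_images, te_list, magnitude_images = NULL,
                       weighted = FALSE, spatial_unwrap = FALSE) {
  stopifnot(is.array(phase_images), length(dim(phase_images)) == 3)
  te_list <- as.numeric(te_list)
  if (length(te_list) < 2) stop("need at least 2 echoes")
  if (any(diff(te_list) <= 0)) stop("echo times must be strictly increasing")
  if (dim(phase_images)[3] != length(te_list))
    stop("phase_images third dimension must match te_list")
  d <- dim(phase_images)
  if (spatial_unwrap)
    for (j in seq_len(d[3]))
      phase_images[, , j] <- unwrap_spatial(phase_images[, , j])
  ph <- unwrap_temporal(phase_images)

  valid <- matrix(TRUE, d[1], d[2])
  w <- NULL
  if (!is.null(magnitude_images)) {
    stopifnot(all(dim(magnitude_images) == d))
    valid <- apply(magnitude_images, c(1, 2), function(v) any(v > 0))
    if (weighted) w <- magnitude_images^2
  }
  if (is.null(w)) w <- array(1, d)

  # closed-form weighted least squares slope per pixel, vectorised over TE
  sw <- sx <- sy <- sxx <- sxy <- matrix(0, d[1], d[2])
  for (j in seq_len(d[3])) {
    wj <- w[, , j]; yj <- ph[, , j]; xj <- te_list[j]
    sw <- sw + wj
    sx <- sx + wj * xj
    sy <- sy + wj * yj
    sxx <- sxx + wj * xj^2
    sxy <- sxy + wj * xj * yj
  }
  denom <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / denom
  slope[denom <= 0] <- NA_real_
  b0 <- slope / (2 * pi)
  valid <- valid & is.finite(b0)
  b0[!valid] <- NA_real_
  list(b0_hz = b0, valid_mask = valid)
}

#' Fit a relative B1 map by the double-angle method
#'
#' From two magnitude images acquired with preparation flip angles alpha and
#' 2*alpha, the actual flip is `acos(S_2a / (2 * S_a))` and the relative B1 is
#' its ratio to the nominal angle. Pixels with non-positive `img_alpha` or a
#' magnitude ratio outside the double-angle domain (|S_2a/S_a| > 2) are
#' flagged invalid rather than silently clipped.
#'
#' @param img_alpha,img_2alpha Magnitude images at alpha and 2*alpha.
#' @param nominal_alpha Nominal flip angle, degrees, in (0, 90).
#' @return List with `b1_scale` matrix and `valid_mask`.
#' @examples
#' a <- matrix(1, 2, 2)
#' fit_b1_map(a, 2 * cos(pi / 6) * a, 30)$b1_scale  # 1 everywhere
#' @export
fit_b1_map <- function(img_alpha, img_2alpha, nominal_alpha = 30) {
  stopifnot(all(dim(img_alpha) == dim(img_2alpha)),
            nominal_alpha > 0, nominal_alpha < 90)
  ratio <- img_2alpha / (2 * img_alpha)
  valid <- is.finite(ratio) & img_alpha > 0 & abs(ratio) <= 1
  alpha <- acos(pmin(pmax(ratio, -1), 1)) * 180 / pi
  b1 <- alpha / nominal_alpha
  b1[!valid] <- NA_real_
  list(b1_scale = b1, valid_mask = valid)
}

#' Assemble a field-map pair
#'
#' Bundles B0 and B1 maps with a joint validity mask.
#'
#' @param b0 Result of [fit_b0_map()].
#' @param b1 Result of [fit_b1_map()].
#' @return A `field_maps` object: `b0_hz`, `b1_scale`, `valid_mask`.
#' @export
field_maps <- function(b0, b1) {
  stopifnot(all(dim(b0$b0_hz) == dim(b1$b1_scale)))
  structure(list(b0_hz = b0$b0_hz, b1_scale = b1$b1_scale,
                 valid_mask = b0$valid_mask & b1$valid_mask),
            class = "field_maps")
}
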