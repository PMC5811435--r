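# MTRasym computation and B0/B1 correction.
#
# Pipeline order is fixed: assemble stack -> correct_b0 -> compute_mtr_asym
# -> correct_b1. The B0 correction resamples each pixel's z-spectrum so that
# +/-target ppm refer to the true water frame; the B1 correction is a
# first-order linear rescaling of the contrast map.

# per-pixel spectrum value at `at` ppm, interpolating within the limb
# (same-sign offsets) containing `at`; NA outside the sampled limb range.
interp_limb <- function(offsets, values, at) {
  side <- if (at >= 0) offsets >= 0 else offsets <= 0
  xo <- offsets[side]; yo <- values[side]
  keep <- is.finite(yo)
  xo <- xo[keep]; yo <- yo[keep]
  if (length(xo) < 2 || at < min(xo) || at > max(xo)) return(NA_real_)
  j <- which(abs(xo - at) < 1e-9)
  if (length(j) == 1L) return(yo[j])
  if (length(xo) < 4)
    stats::approx(xo, yo, xout = at)$y
  else
    stats::spline(xo, yo, xout = at, method = "natural")$y
}

#' Compute the MTRasym (GluCEST) contrast map
#'
#' Evaluates, per pixel, the asymmetry of the saturated magnetization about
#' water: `100 * (M(-target) - M(+target)) / M(-target)`, the percent GluCEST
#' contrast when `target_offset = 3` ppm (glutamate amine protons). Values at
#' +/-target are taken from the sampled offsets, interpolating within the
#' same-sign limb when not sampled exactly. Pixels where `M(-target)` is
#' non-positive or unavailable are flagged invalid (NA).
#'
#' @param stack A [zspectrum_stack()] (B0-corrected if a correction is
#'   wanted; see [correct_b0()]).
#' @param target_offset Positive offset, ppm (default 3).
#' @return A `glucest_map`: list with `contrast_pct` matrix (%, NA where
#'   invalid), `target_offset`, `corrections` flags, `valid`.
#' @examples
#' d <- array(c(0.8, 0.6), c(1, 1, 2))
#' m <- compute_mtr_asym(zspectrum_stack(d, c(-3, 3)))
#' m$contrast_pct  # 25
#' @export
compute_mtr_asym <- function(stack, target_offset = 3) {
  stopifnot(inherits(stack, "zspectrum_stack"), target_offset > 0)
  d <- dim(stack$data)
  ineg <- match_offset(stack$offsets, -target_offset)
  ipos <- match_offset(stack$offsets, target_offset)
  contrast <- matrix(NA_real_, d[1], d[2])
  if (!is.na(ineg) && !is.na(ipos)) {
    mneg <- stack$data[, , ineg]
    mpos <- stack$data[, , ipos]
  } else {
    mneg <- mpos <- matrix(NA_real_, d[1], d[2])
    for (iy in seq_len(d[2])) for (ix in seq_len(d[1])) {
      if (!stack$valid[ix, iy]) next
      mneg[ix, iy] <- interp_limb(stack$offsets, stack$data[ix, iy, ], -target_offset)
      mpos[ix, iy] <- interp_limb(stack$offsets, stack$data[ix, iy, ], target_offset)
    }
  }
  ok <- stack$valid & is.finite(mneg) & is.finite(mpos) & mneg > 0
  contrast[ok] <- 100 * (mneg[ok] - mpos[ok]) / mneg[ok]
  corr <- attr(stack, "b0_corrected")
  structure(list(contrast_pct = contrast, target_offset = target_offset,
                 corrections = c(b0 = isTRUE(corr), b1 = FALSE), valid = ok),
            class = "glucest_map")
}

#' @export
print.glucest_map <- function(x, ...) {
  cat(sprintf("<glucest_map> %d x %d at %g ppm; corrections b0=%s b1=%s; mean %.2f%% over %d valid px\n",
              nrow(x$contrast_pct), ncol(x$contrast_pct), x$target_offset,
              x$corrections["b0"], x$corrections["b1"],
              mean(x$contrast_pct[x$valid]), sum(x$valid)))
  invisible(x)
}

#' Correct a z-spectrum stack for B0 inhomogeneity
#'
#' Per pixel, the acquired z-spectrum is interpolated (natural cubic spline
#' within each same-sign limb) and resampled at the acquired offsets shifted
#' by the pixel's B0 offset (converted to ppm), so that values at +/-3 ppm
#' refer to the true water frame. Offsets whose shifted position leaves the
#' sampled limb are set NA — no extrapolation; downstream [compute_mtr_asym()]
#' flags pixels whose target offsets became unavailable.
#'
#' @param stack A [zspectrum_stack()].
#' @param b0_hz Matrix of per-pixel B0 offsets, Hz, aligned with the stack.
#' @param hz_per_ppm Conversion constant.
#' @return A corrected [zspectrum_stack()] (attribute `b0_corrected` set).
#' @export
correct_b0 <- function(stack, b0_hz, hz_per_ppm = HZ_PER_PPM_9T4) {
  stopifnot(inherits(stack, "zspectrum_stack"))
  d <- dim(stack$data)
  stopifnot(all(dim(b0_hz) == d[1:2]))
  pos <- sum(stack$offsets > 0); neg <- sum(stack$offsets < 0)
  if (pos < 3 || neg < 3)
    stop("need at least 3 offsets per side for B0 correction")
  out <- stack
  for (iy in seq_len(d[2])) for (ix in seq_len(d[1])) {
    if (!stack$valid[ix, iy]) next
    shift <- b0_hz[ix, iy] / hz_per_ppm
    if (!is.finite(shift)) { out$valid[ix, iy] <- FALSE; next }
    if (shift == 0) next
    y <- stack$data[ix, iy, ]
    out$data[ix, iy, ] <- vapply(stack$offsets, function(x)
      interp_limb(stack$offsets, y, x + shift), numeric(1))
  }
  attr(out, "b0_corrected") <- TRUE
  out
}

#' Correct a GluCEST map for B1 inhomogeneity
#'
#' First-order linear correction: the contrast is divided by the pixel's
#' relative B1 (ratio of actual to nominal flip). Pixels whose B1 falls
#' outside the plausibility band are flagged invalid rather than corrected.
#'
#' @param map A `glucest_map` from [compute_mtr_asym()].
#' @param b1_scale Matrix of relative B1 per pixel.
#' @param band Plausibility band for `b1_scale` (default 0.5-1.5).
#' @return The corrected `glucest_map` (`corrections["b1"]` set).
#' @export
correct_b1 <- function(map, b1_scale, band = c(0.5, 1.5)) {
  stopifnot(inherits(map, "glucest_map"),
            all(dim(b1_scale) == dim(map$contrast_pct)))
  ok <- map$valid & is.finite(b1_scale) & b1_scale >= band[1] & b1_scale <= band[2]
  out <- map
  out$contrast_pct[!ok] <- NA_real_
  out$contrast_pct[ok] <- map$contrast_pct[ok] / b1_scale[ok]
  out$valid <- ok
  out$corrections["b1"] <- TRUE
  out
}

#' ROI-averaged z-spectrum and asymmetry curve
#'
#' Averages the z-spectrum over an ROI and returns, for each positive offset,
#' the upfield/downfield means and the asymmetry
#' `MTRasym = 100 * (Z(-dw) - Z(+dw)) / Z(-dw)`. Requires a symmetric offset
#' list (every positive offset paired with its negative).
#'
#' @param stack A [zspectrum_stack()].
#' @param roi_mask Logical (or 0/1) matrix selecting ROI pixels.
#' @return data.frame with `offset`, `z_pos`, `z_neg`, `mtr_asym_pct`, plus
#'   attribute `z_full` (ROI-mean Z at every acquired offset).
#' @export
asymmetry_curve <- function(stack, roi_mask) {
  stopifnot(inherits(stack, "zspectrum_stack"))
  roi_mask <- roi_mask & stack$valid
  if (!any(roi_mask)) stop("empty ROI")
  offs <- stack$offsets
  posv <- sort(offs[offs > 0])
  for (x in posv)
    if (is.na(match_offset(offs, -x)))
      stop("offset list is not symmetric about 0")
  zmean <- vapply(seq_along(offs), function(k) {
    sl <- stack$data[, , k]
    mean(sl[roi_mask], na.rm = TRUE)
  }, numeric(1))
  zp <- vapply(posv, function(x) zmean[match_offset(offs, x)], numeric(1))
  zn <- vapply(posv, function(x) zmean[match_offset(offs, -x)], numeric(1))
  out <- data.frame(offset = posv, z_pos = zp, z_neg = zn,
                    mtr_asym_pct = 100 * (zn - zp) / zn)
  attr(out, "z_full") <- data.frame(offset = offs, z = zmean)
  out
}
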