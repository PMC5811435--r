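#' Z-spectrum image stack
#'
#' Container for per-pixel saturated magnetizations over a list of saturation
#' offsets, with acquisition metadata. `data` is normalised to the
#' unsaturated signal when `reference` is absent; otherwise normalisation by
#' `reference` happens on construction.
#'
#' @param data Numeric array (nx, ny, n_offsets), non-negative.
#' @param offsets Saturation offsets, ppm; unique, same length as dim 3.
#' @param scheme Optional [saturation_scheme()] metadata.
#' @param reference Optional unsaturated / far-off-resonance image (nx, ny)
#'   used to normalise `data`.
#' @param valid Optional logical matrix of usable pixels (default all TRUE).
#' @return A `zspectrum_stack` object.
#' @export
zspectrum_stack <- function(data, offsets, scheme = NULL, reference = NULL,
                            valid = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  offsets <- as.numeric(offsets)
  if (length(offsets) != dim(data)[3])
    stop("length(offsets) must match dim(data)[3]")
  if (anyDuplicated(offsets)) stop("offsets must be unique")
  if (any(data < 0, na.rm = TRUE)) stop("data must be non-negative")
  if (!is.null(reference)) {
    stopifnot(all(dim(reference) == dim(data)[1:2]))
    ok <- reference > 0
    for (k in seq_along(offsets))
      data[, , k] <- ifelse(ok, data[, , k] / reference, NA_real_)
  }
  if (is.null(valid)) valid <- matrix(TRUE, dim(data)[1], dim(data)[2])
  stopifnot(all(dim(valid) == dim(data)[1:2]))
  ord <- order(offsets)
  structure(list(data = data[, , ord, drop = FALSE], offsets = offsets[ord],
                 scheme = scheme, valid = valid),
            class = "zspectrum_stack")
}

#' @export
print.zspectrum_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<zspectrum_stack> %d x %d pixels, %d offsets [%g, %g] ppm, %d valid\n",
              d[1], d[2], d[3], min(x$offsets), max(x$offsets), sum(x$valid)))
  invisible(x)
}

# offsets must contain x within tolerance; returns index or NA
match_offset <- function(offsets, x, tol = 1e-9) {
  i <- which(abs(offsets - x) < tol)
  if (length(i) == 1L) i else NA_integer_
}
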