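# Matrix exponential by Pade approximation with scaling and squaring.
# Internal: the Bloch-McConnell system is piecewise linear time-invariant, so
# one expm per (pixel, offset, segment) gives the exact propagator. Matrices
# here are small (3*n_pools + 1 square); a pure-R Pade is an order of
# magnitude faster than S4-dispatched alternatives at this size.
expm_pade <- function(A) {
  nA <- max(colSums(abs(A)))
  j <- if (nA > 0) max(0L, as.integer(ceiling(log2(nA))) + 1L) else 0L
  A <- A / 2^j
  n <- nrow(A)
  I <- diag(n)
  X <- A
  cc <- 0.5
  E <- I + cc * A
  D <- I - cc * A
  q <- 6L
  p <- TRUE
  for (k in 2:q) {
    cc <- cc * (q - k + 1) / (k * (2 * q - k + 1))
    X <- A %*% X
    E <- E + cc * X
    D <- D + if (p) cc * X else -cc * X
    p <- !p
  }
  E <- solve(D, E)
  for (k in seq_len(j)) E <- E %*% E
  E
}
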