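# Four-dimensional Sobol low-discrepancy sequence.
#
# Direction numbers come from the standard primitive-polynomial recurrence
#   m_k = 2 a_1 m_{k-1} xor 4 a_2 m_{k-2} xor ... xor 2^s m_{k-s} xor m_{k-s}
# with the classical initial values for dimensions 2..4; dimension 1 is the
# base-2 van der Corput sequence.  Points are generated directly from the
# binary-reflected Gray code of the index, so any subsequence (skip) can be
# produced without generating its predecessors.

SOBOL_NBITS <- 30L

sobol_direction_numbers <- function(nbits = SOBOL_NBITS) {
  # per dimension: s = polynomial degree, a = interior coefficients,
  # m = initial odd direction integers
  dims <- list(
    list(s = 0L, a = integer(), m = integer()),       # van der Corput
    list(s = 1L, a = integer(), m = c(1L)),
    list(s = 2L, a = c(1L), m = c(1L, 3L)),
    list(s = 3L, a = c(0L, 1L), m = c(1L, 3L, 1L))
  )
  v <- matrix(0L, nbits, 4)
  for (d in seq_along(dims)) {
    s <- dims[[d]]$s
    if (s == 0L) {
      m <- rep(1L, nbits)
    } else {
      m <- integer(nbits)
      m[seq_len(s)] <- dims[[d]]$m
      a <- dims[[d]]$a
      for (k in (s + 1):nbits) {
        acc <- bitwXor(bitwShiftL(m[k - s], s), m[k - s])
        for (q in seq_len(s - 1)) {
          if (a[q] == 1L) acc <- bitwXor(acc, bitwShiftL(m[k - q], q))
        }
        m[k] <- acc
      }
    }
    v[, d] <- bitwShiftL(m, nbits - seq_len(nbits))
  }
  v
}

#' Four-dimensional Sobol sequence points
#'
#' Returns `n` consecutive points of the (unscrambled) 4-D Sobol sequence
#' starting at index `skip`.  Index 0 is the degenerate all-zeros point, so
#' the default `skip = 1` drops it; larger skips select later subsequences
#' for replicate runs.  Deterministic: the same `(n, skip)` always yields the
#' same points.
#'
#' @param n Number of points (>= 1).
#' @param skip Index of the first point returned (>= 0).
#' @return An `n x 4` matrix with entries in `[0, 1)`.
#' @examples
#' sobol_points(3) # (0.5, 0.5, 0.5, 0.5), (0.75, 0.25, ...), ...
#' @export
sobol_points <- function(n, skip = 1L) {
  stopifnot(n >= 1, skip >= 0, skip + n < 2^31)
  v <- sobol_direction_numbers()
  idx <- as.integer(skip + seq_len(n) - 1L)
  gray <- bitwXor(idx, bitwShiftR(idx, 1L))
  out <- matrix(0L, n, 4)
  maxbit <- if (max(idx) > 0) floor(log2(max(idx))) else 0
  for (b in 0:maxbit) {
    sel <- bitwAnd(gray, bitwShiftL(1L, b)) != 0L
    if (any(sel)) {
      for (d in 1:4) out[sel, d] <- bitwXor(out[sel, d], v[b + 1L, d])
    }
  }
  out / 2^SOBOL_NBITS
}
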