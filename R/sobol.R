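# Sobol quasi-random sequence (Joe-Kuo direction numbers, dimensions 1-48),
# with an optional seed-derived digital-shift scramble. 30 bits of
# precision; generation uses the usual Gray-code update.

.SOBOL_BITS <- 30L

# direction integers v_k (already shifted to bit positions) for one
# dimension, given the polynomial encoding and initial m values
.sobol_directions <- function(poly, minit, nbits = .SOBOL_BITS) {
  s <- length(minit)
  m <- integer(nbits)
  if (poly <= 1L) {
    # first dimension: van der Corput, all m_k = 1
    m[] <- 1L
  } else {
    m[seq_len(s)] <- minit
    # interior coefficients a_1..a_{s-1} of the primitive polynomial
    a <- as.integer(intToBits(poly))[seq_len(s + 1)]  # bit0..bit s
    a <- rev(a)[-c(1, s + 1)]                         # drop leading/trailing 1
    for (k in seq(s + 1, nbits)) {
      val <- bitwXor(m[k - s], bitwShiftL(m[k - s], s))
      if (s > 1) {
        for (i in seq_len(s - 1)) {
          if (a[i] == 1L) val <- bitwXor(val, bitwShiftL(m[k - i], i))
        }
      }
      m[k] <- val
    }
  }
  bitwShiftL(m, nbits - seq_len(nbits))
}

#' Sobol low-discrepancy points
#'
#' Generates `n` points of the `d`-dimensional Sobol sequence in the unit
#' hypercube. With `seed = NULL` the raw (unscrambled) sequence is
#' returned, whose first point is the origin. A seed applies a
#' deterministic digital-shift scramble (per-dimension XOR mask drawn from
#' the seed), giving a reproducible, seed-dependent low-discrepancy set.
#'
#' @param n Number of points.
#' @param d Dimension (1-48).
#' @param seed Integer seed for the digital shift, or `NULL` for the raw
#'   sequence.
#' @param skip Number of initial points of the underlying sequence to skip.
#' @return An `n` x `d` numeric matrix with entries in \[0, 1).
#' @export
#' @examples
#' sobol_points(4, 2)
sobol_points <- function(n, d, seed = NULL, skip = 0) {
  stopifnot(n >= 1, d >= 1, d <= length(.sobol_poly), skip >= 0)
  v <- vapply(seq_len(d),
              function(j) .sobol_directions(.sobol_poly[j],
                                            .sobol_minit[[j]]),
              integer(.SOBOL_BITS))           # nbits x d
  shift <- integer(d)
  if (!is.null(seed)) {
    shift <- withr::with_seed(as.integer(seed),
      as.integer(floor(stats::runif(d) * 2^.SOBOL_BITS)))
  }
  x <- integer(d)
  out <- matrix(0, n, d)
  total <- skip + n
  for (i in seq_len(total)) {
    if (i > 1) {
      # Gray code: flip the direction indexed by the lowest zero bit of the
      # previous 0-based point index
      cz <- 0L; ii <- i - 2L
      while (bitwAnd(ii, 1L) == 1L) { cz <- cz + 1L; ii <- bitwShiftR(ii, 1L) }
      x <- bitwXor(x, v[cz + 1L, ])
    }
    if (i > skip) out[i - skip, ] <- bitwXor(x, shift) / 2^.SOBOL_BITS
  }
  out
}
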