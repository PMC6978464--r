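#' Hilbert envelope of region time-series
#'
#' Computes, row by row, the modulus of the analytic signal (the signal plus
#' i times its Hilbert transform), i.e. the instantaneous-amplitude envelope.
#' This is the standard preprocessing step before binarisation and
#' functional-connectivity estimation: it yields a nonnegative series and
#' discards the negative-frequency half of the spectrum.
#'
#' The analytic signal is obtained by FFT: the positive-frequency
#' coefficients are doubled, the negative-frequency ones zeroed, and the
#' result inverse-transformed. No padding or tapering is applied, so edge
#' effects at the first and last few samples are expected and documented
#' rather than mitigated.
#'
#' @param x numeric matrix (regions x timepoints) or a single numeric series.
#'   Each row must have at least 8 samples.
#' @return a nonnegative numeric matrix of the same shape as the input.
#' @examples
#' t <- seq(0, 2 * pi, length.out = 256)
#' env <- hilbert_envelope(matrix(sin(8 * t), nrow = 1))
#' range(env[1, 64:192]) # ~1 away from the edges
#' @export
hilbert_envelope <- function(x) {
  x <- as_roi_matrix(x, min_timepoints = 8L)
  if (any(apply(x, 1L, function(r) diff(range(r)) == 0))) {
    warn("constant row(s): analytic signal degenerates to |constant|")
  }
  n <- ncol(x)
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  # mvfft works column-wise; transpose so each series is a column
  spec <- stats::mvfft(t(x)) * h
  analytic <- stats::mvfft(spec, inverse = TRUE) / n
  t(Mod(analytic))
}

#' Binarise each row about its own mean
#'
#' Each entry becomes 1 if it is greater than or equal to the mean of its own
#' row, 0 otherwise. Ties at the mean map to 1, so a constant row binarises
#' to all ones. The per-row thresholds are kept in the `source_means`
#' attribute.
#'
#' @param x numeric matrix (regions x timepoints).
#' @return integer 0/1 matrix of the same shape, with attribute
#'   `source_means` (the per-row thresholds).
#' @examples
#' binarise_rows(matrix(1:4, nrow = 1)) # 0 0 1 1
#' @export
binarise_rows <- function(x) {
  x <- as_roi_matrix(x)
  mu <- rowMeans(x)
  out <- (x >= mu) * 1L
  storage.mode(out) <- "integer"
  attr(out, "source_means") <- mu
  out
}

#' Flatten a binary activation matrix column-wise
#'
#' Concatenates the columns of the regions-by-time binary matrix in time
#' order, so that each consecutive segment of length `nrow(x)` is one
#' timepoint's spatial activation pattern. This is the vector the Lempel-Ziv
#' parser consumes: its phrases are then patterns over regions, not runs
#' within a single region's series.
#'
#' @param x 0/1 matrix (regions x timepoints).
#' @return integer 0/1 vector of length `nrow(x) * ncol(x)`, with attribute
#'   `segment_length = nrow(x)`.
#' @seealso [unstack_bits()] for the exact inverse.
#' @export
stack_flatten <- function(x) {
  stopifnot(is.matrix(x))
  bits <- as.integer(x) # R matrices are column-major: columns concatenated
  if (!all(bits %in% c(0L, 1L))) abort("matrix must be binary (0/1)")
  attr(bits, "segment_length") <- nrow(x)
  bits
}

#' Inverse of [stack_flatten()]
#'
#' @param bits 0/1 vector produced by [stack_flatten()].
#' @param n_regions number of rows of the original matrix; defaults to the
#'   `segment_length` attribute if present.
#' @return integer 0/1 matrix with `n_regions` rows.
#' @export
unstack_bits <- function(bits, n_regions = attr(bits, "segment_length")) {
  if (is.null(n_regions)) abort("n_regions not given and no segment_length attribute")
  if (length(bits) %% n_regions != 0) abort("length not divisible by n_regions")
  matrix(as.integer(bits), nrow = n_regions)
}

#' Row-shuffled surrogate of a binary activation matrix
#'
#' Independently permutes the entries of every row, conserving each row's
#' number of ones. Used to normalise Lempel-Ziv compressibility: the
#' surrogate has the same marginal activation rates but no temporal
#' structure, so structureless data score close to 1 after normalisation.
#'
#' @param x 0/1 matrix (regions x timepoints).
#' @param seed integer seed; the permutation is fully determined by it.
#' @return integer 0/1 matrix of the same shape.
#' @export
shuffle_surrogate <- function(x, seed = 1L) {
  stopifnot(is.matrix(x))
  local_seed(seed, {
    out <- t(apply(x, 1L, function(r) r[sample.int(length(r))]))
    storage.mode(out) <- "integer"
    out
  })
}
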