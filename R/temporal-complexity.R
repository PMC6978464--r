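#' LZ76 dictionary size of a binary sequence
#'
#' Counts the phrases of the exhaustive-history Lempel-Ziv (1976)
#' factorisation: scanning left to right, the current phrase is extended
#' while it occurs as a substring of all preceding material plus the
#' phrase-so-far minus its last symbol, and closed at the first novelty; the
#' trailing, possibly non-novel phrase counts as one. The count is a
#' computable proxy for Kolmogorov complexity.
#'
#' @param bits 0/1 vector (e.g. from [stack_flatten()]).
#' @return integer phrase count (>= 1 for nonempty input).
#' @examples
#' lz76_dictionary_size(c(0, 1)) # 2
#' @export
lz76_dictionary_size <- function(bits) {
  if (length(bits) == 0L) abort("empty bit sequence")
  bits <- as.integer(bits)
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) abort("sequence must be 0/1")
  .lz76_count(bits)
}

#' Normalised Lempel-Ziv compressibility of a region-by-time matrix
#'
#' The full temporal-compressibility pipeline: Hilbert envelope, per-row
#' mean binarisation, column-wise flattening, LZ76 phrase count; the count is
#' divided by the count of a row-shuffled surrogate of the same binary
#' matrix, so that structureless data score close to 1 and temporally
#' ordered data score below it.
#'
#' @param x numeric matrix (regions x timepoints), raw signals.
#' @param seed integer seed for the surrogate shuffle.
#' @param n_surrogates number of independent surrogates to average the
#'   normalising count over (default 1, i.e. a single shuffled matrix).
#' @param envelope if `FALSE`, `x` is taken to be an already binarised 0/1
#'   matrix and the envelope/binarisation steps are skipped.
#' @return an object of class `lz_result`: a list with `dictionary_size`,
#'   `surrogate_size`, `raw_length`, `normalised` and a `degenerate` flag
#'   (set when the binarised matrix is constant).
#' @export
lzc_normalised <- function(x, seed = 1L, n_surrogates = 1L, envelope = TRUE) {
  if (envelope) {
    x <- as_roi_matrix(x, min_timepoints = 8L)
    bin <- binarise_rows(hilbert_envelope(x))
  } else {
    stopifnot(is.matrix(x))
    bin <- x
    storage.mode(bin) <- "integer"
    if (!all(bin %in% c(0L, 1L))) abort("envelope = FALSE requires a 0/1 matrix")
  }
  degenerate <- length(unique(as.integer(bin))) == 1L
  if (degenerate) {
    warn("binarised matrix is constant; normalised LZ is degenerate")
  }
  d_true <- lz76_dictionary_size(stack_flatten(bin))
  d_surr <- vapply(seq_len(n_surrogates), function(s) {
    surr <- shuffle_surrogate(bin, seed = seed + s - 1L)
    lz76_dictionary_size(stack_flatten(surr))
  }, numeric(1))
  structure(
    list(dictionary_size = d_true,
         surrogate_size = mean(d_surr),
         raw_length = length(bin),
         normalised = d_true / mean(d_surr),
         degenerate = degenerate,
         seed = seed,
         n_surrogates = n_surrogates),
    class = "lz_result"
  )
}

#' Sample entropy of a series
#'
#' SampEn(m, r): the negative log of the conditional probability that two
#' templates of length `m` within Chebyshev distance `r` of each other remain
#' within `r` when extended to length `m + 1`. Matching is non-strict
#' (distance `<= r`) and self-matches are excluded; both template sets run
#' over the same `N - m` starting positions. A perfectly regular series
#' scores 0; entropy rises with disorder.
#'
#' @param x numeric series of length at least `m + 2`.
#' @param m embedding (template) length, default 2.
#' @param r_coef tolerance as a multiple of the series standard deviation;
#'   the tolerance used is `r_coef * sd(x)`.
#' @param r absolute tolerance; overrides `r_coef` when given.
#' @return an object of class `sampen`: `value` (`-log(A/B)`, possibly
#'   `Inf` when no `m+1` templates match, `NA` when no `m` templates match),
#'   ordered-pair counts `match_count_m` (B) and `match_count_m1` (A), and
#'   the parameters.
#' @examples
#' sample_entropy(rep(1, 100))$value # exactly 0
#' @export
sample_entropy <- function(x, m = 2L, r_coef = 0.3, r = NULL) {
  x <- as.numeric(x)
  m <- as.integer(m)
  if (anyNA(x)) abort("series contains missing values")
  if (length(x) < m + 2L) abort("series too short for embedding length m")
  if (is.null(r)) r <- r_coef * sd(x)
  counts <- .sampen_counts(x, m, r)
  b <- counts[1L]; a <- counts[2L]
  value <- if (b == 0) {
    warn("sample entropy undefined: no template matches at length m")
    NA_real_
  } else if (a == 0) {
    warn("sample entropy infinite: no template matches at length m + 1")
    Inf
  } else {
    -log(a / b)
  }
  structure(
    list(value = value, m = m, r = r, r_coef = r_coef,
         match_count_m = b, match_count_m1 = a),
    class = "sampen"
  )
}

#' Rescaled-range (R/S) Hurst exponent
#'
#' Classic rescaled-range estimation: for each window size `n` the series is
#' partitioned into non-overlapping segments; per segment, the cumulative
#' departure from the segment mean is computed, its range divided by the
#' segment standard deviation (R/S), and R/S averaged across segments. The
#' Hurst exponent is the slope of `log(mean R/S)` on `log(n)`: 0.5 for
#' memoryless noise, toward 1 for persistent, predictable signals.
#'
#' Default window sizes are powers of two from `min_window` (8) up to half
#' the series length; at least 3 usable sizes are required. Raising
#' `min_window` drops the shortest windows, which carry most of the
#' estimator's well-known upward small-sample bias.
#'
#' @param x numeric series, length >= 32.
#' @param window_sizes optional explicit window sizes (at least 3 usable).
#' @param min_window smallest default window size.
#' @return an object of class `hurst_fit`: `exponent`, `window_sizes`,
#'   `rs_values`, `fit_r_squared`.
#' @export
hurst_rs <- function(x, window_sizes = NULL, min_window = 8L) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 32L) abort("series too short for R/S estimation (need >= 32)")
  if (is.null(window_sizes)) {
    window_sizes <- 2^(seq.int(ceiling(log2(min_window)), floor(log2(n / 2))))
  }
  window_sizes <- sort(unique(as.integer(window_sizes)))
  rs <- vapply(window_sizes, function(w) {
    nseg <- n %/% w
    if (nseg < 1L) return(NA_real_)
    vals <- vapply(seq_len(nseg), function(s) {
      seg <- x[((s - 1L) * w + 1L):(s * w)]
      sdev <- sd(seg)
      if (sdev == 0) return(NA_real_) # degenerate segment, skipped
      prof <- cumsum(seg - mean(seg))
      (max(prof) - min(prof)) / sdev
    }, numeric(1))
    if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
  }, numeric(1))
  usable <- is.finite(rs) & rs > 0
  if (sum(usable) < 3L) {
    abort("fewer than 3 usable window sizes for the R/S regression")
  }
  fit <- ls_slope(log(window_sizes[usable]), log(rs[usable]))
  structure(
    list(exponent = fit$slope,
         window_sizes = window_sizes[usable],
         rs_values = rs[usable],
         fit_r_squared = fit$r_squared),
    class = "hurst_fit"
  )
}

# fast path used by compute_profile: per-row R/S Hurst exponents of a
# matrix, same mathematics as hurst_rs() but vectorised across rows
hurst_rs_rows <- function(mat, min_window = 8L) {
  n <- ncol(mat)
  ws <- 2^(seq.int(ceiling(log2(min_window)), floor(log2(n / 2))))
  logrs <- matrix(NA_real_, length(ws), nrow(mat))
  for (wi in seq_along(ws)) {
    w <- ws[wi]
    nseg <- n %/% w
    cum_op <- upper.tri(matrix(0, w, w), diag = TRUE) * 1 # running-sum operator
    rs_seg <- matrix(NA_real_, nrow(mat), nseg)
    for (s in seq_len(nseg)) {
      seg <- mat[, ((s - 1L) * w + 1L):(s * w), drop = FALSE]
      dev <- seg - rowMeans(seg)
      prof <- dev %*% cum_op
      pdf_ <- as.data.frame(prof)
      rng <- do.call(pmax, pdf_) - do.call(pmin, pdf_)
      sdev <- sqrt(rowSums(dev^2) / (w - 1))
      rs_seg[, s] <- ifelse(sdev > 0, rng / sdev, NA_real_)
    }
    logrs[wi, ] <- log(rowMeans(rs_seg, na.rm = TRUE))
  }
  lw <- log(ws)
  dx <- lw - mean(lw)
  as.numeric(crossprod(dx, logrs - matrix(colMeans(logrs), nrow(logrs),
                                          ncol(logrs), byrow = TRUE))) /
    sum(dx * dx)
}

# Higuchi curve lengths for every row of a matrix at once.
# Returns list(k = usable k values, logL = length(k) x nrow matrix of
# log mean lengths per row).
higuchi_curve_matrix <- function(mat, k_max) {
  n <- ncol(mat)
  ks <- seq_len(k_max)
  logl <- matrix(NA_real_, length(ks), nrow(mat))
  keep <- logical(length(ks))
  for (k in ks) {
    acc <- numeric(nrow(mat))
    nm <- 0L
    for (m in seq_len(k)) {
      idx <- seq.int(m, n, by = k)
      npts <- length(idx) - 1L # floor((n - m) / k)
      if (npts < 1L) next
      seg <- mat[, idx, drop = FALSE]
      tv <- abs(seg[, -1L, drop = FALSE] - seg[, -ncol(seg), drop = FALSE])
      lm_k <- rowSums(tv) * (n - 1) / (npts * k) / k
      acc <- acc + lm_k
      nm <- nm + 1L
    }
    if (nm == 0L) next
    keep[k] <- TRUE
    logl[k, ] <- log(acc / nm)
  }
  list(k = ks[keep], logl = logl[keep, , drop = FALSE])
}

#' Higuchi fractal dimension
#'
#' Higuchi's (1988) curve-length method: the series is subsampled at lags
#' `k = 1..k_max` and offsets `m = 1..k`; the normalised curve length
#' `L_m(k)` is averaged over offsets, and the fractal dimension is the
#' negative slope of `log<L(k)>` on `log(k)`. Smooth curves score near 1,
#' white noise near 2; for fractional Gaussian noise `D ~ 2 - H`.
#'
#' @param x numeric series of length `N > 2 * k_max`.
#' @param k_max largest subsampling lag.
#' @return an object of class `higuchi_fit`: `dimension`, `k_max`,
#'   `k_values`, `mean_lengths`, `fit_r_squared`.
#' @export
higuchi_fd <- function(x, k_max = 32L) {
  x <- as.numeric(x)
  k_max <- as.integer(k_max)
  if (length(x) <= 2L * k_max) abort("series length must exceed 2 * k_max")
  cur <- higuchi_curve_matrix(matrix(x, nrow = 1L), k_max)
  if (length(cur$k) < length(seq_len(k_max))) {
    warn("some k values dropped (no usable offsets)")
  }
  fit <- ls_slope(log(cur$k), cur$logl[, 1L])
  structure(
    list(dimension = -fit$slope,
         k_max = k_max,
         k_values = cur$k,
         mean_lengths = exp(cur$logl[, 1L]),
         fit_r_squared = fit$r_squared),
    class = "higuchi_fit"
  )
}

# fast path used by compute_profile: per-row Higuchi dimensions of a matrix
higuchi_fd_rows <- function(mat, k_max) {
  cur <- higuchi_curve_matrix(mat, k_max)
  lk <- log(cur$k)
  dx <- lk - mean(lk)
  denom <- sum(dx * dx)
  -as.numeric(crossprod(dx, cur$logl - matrix(colMeans(cur$logl),
                                              nrow(cur$logl), ncol(cur$logl),
                                              byrow = TRUE))) / denom
}

#' Choose a stable Higuchi k_max
#'
#' Evaluates the mean Higuchi dimension of a sample of series at candidate
#' `k_max` values (powers of two by default), drops candidates infeasible
#' for the series length (`N > 2k` required), and returns the smallest
#' candidate in the longest contiguous run over which successive dimension
#' estimates change by less than `tol` — i.e. the start of the stability
#' plateau.
#'
#' @param series_sample list of numeric series (or a matrix, rows = series).
#' @param candidates candidate `k_max` values, default `2, 4, ..., 128`.
#' @param tol stability tolerance between successive estimates.
#' @return the selected `k_max` (integer).
#' @export
select_kmax <- function(series_sample, candidates = 2^(1:7), tol = 0.05) {
  if (is.matrix(series_sample)) {
    series_sample <- lapply(seq_len(nrow(series_sample)),
                            function(i) series_sample[i, ])
  }
  n_min <- min(lengths(series_sample))
  feasible <- candidates[n_min > 2 * candidates]
  if (length(feasible) == 0L) abort("no feasible k_max candidate for these series")
  dims <- vapply(feasible, function(k) {
    mean(vapply(series_sample, function(s) higuchi_fd(s, k)$dimension,
                numeric(1)))
  }, numeric(1))
  if (length(feasible) == 1L) return(as.integer(feasible))
  stable <- abs(diff(dims)) < tol
  # longest contiguous run of stable successive pairs
  runs <- rle(stable)
  if (!any(runs$values)) return(as.integer(feasible[1L]))
  best <- which.max(ifelse(runs$values, runs$lengths, 0L))
  start <- if (best == 1L) 1L else sum(runs$lengths[seq_len(best - 1L)]) + 1L
  as.integer(feasible[start])
}

#' PCA compressibility of a region-by-time matrix
#'
#' Treats timepoints as observations and regions as features, standardises
#' each feature to zero mean and unit variance, and counts how many
#' principal components are needed to cumulatively explain
#' `variance_threshold` of the variance. Fewer components mean a more
#' compressible — less complex — set of signals.
#'
#' @param x numeric matrix (regions x timepoints).
#' @param variance_threshold cumulative explained-variance target (default
#'   0.95).
#' @return an object of class `pca_compress`: `n_components`,
#'   `variance_threshold`, `explained_curve` (cumulative ratios).
#' @export
pca_compressibility <- function(x, variance_threshold = 0.95) {
  x <- as_roi_matrix(x, min_timepoints = 2L)
  if (nrow(x) < 2L) abort("need at least 2 regions")
  obs <- t(x) # timepoints as observations, regions as features
  sds <- apply(obs, 2L, sd)
  if (any(sds == 0)) {
    warn("zero-variance feature(s): centred only, scale left at 1")
    sds[sds == 0] <- 1
  }
  obs <- scale(obs, center = TRUE, scale = sds)
  pc <- prcomp(obs, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  curve <- cumsum(ev) / sum(ev)
  structure(
    list(n_components = which(curve >= variance_threshold)[1L],
         variance_threshold = variance_threshold,
         explained_curve = curve),
    class = "pca_compress"
  )
}
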