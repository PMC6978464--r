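# Independent brute-force oracles, deliberately naive and separate from the
# package's implementations.

# LZ76 exhaustive-history phrase count by naive substring search: extend the
# phrase while it occurs in everything before its last symbol.
bf_lz76 <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  cnt <- 0L; p <- 1L; e <- 1L
  while (e <= n) {
    if (grepl(substr(s, p, e), substr(s, 1L, e - 1L), fixed = TRUE)) {
      e <- e + 1L
    } else {
      cnt <- cnt + 1L
      p <- e + 1L
      e <- p
    }
  }
  if (p <= n) cnt <- cnt + 1L
  cnt
}

# O(n^2 m) sample-entropy pair counter: ordered pairs, Chebyshev distance,
# non-strict tolerance, templates of both lengths starting at 1..n-m.
bf_sampen_counts <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  b <- 0L; a <- 0L
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) next
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) <= r) {
        b <- b + 1L
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) a <- a + 1L
      }
    }
  }
  c(B = b, A = a)
}

# connected components by breadth-first search on an adjacency matrix
bf_n_components <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  ncomp <- 0L
  for (v in seq_len(n)) {
    if (seen[v]) next
    ncomp <- ncomp + 1L
    queue <- v
    seen[v] <- TRUE
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[u, ] != 0 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  ncomp
}

# random symmetric nonnegative weight matrix with zero diagonal
random_weight_matrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m + t(m)
}

# small AR(1)-style scan for fast pipeline tests
tiny_scan <- function(n_regions = 12, n_timepoints = 64, phi = 0.5, seed = 1) {
  set.seed(seed)
  m <- t(replicate(n_regions,
                   as.numeric(stats::filter(rnorm(n_timepoints), phi,
                                            method = "recursive"))))
  m - min(m) + 0.5
}
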