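#' Functional connectivity matrix from envelope series
#'
#' Pairwise Pearson correlation between every pair of region envelope
#' series, filtered to a simple nonnegative weighted graph: the diagonal
#' (self-loops) is zeroed and negative correlations are removed (set to 0),
#' the most common convention in network neuroscience.
#'
#' @param env numeric matrix (regions x timepoints), typically the output of
#'   [hilbert_envelope()]. Needs at least 3 regions and 8 timepoints.
#' @return symmetric nonnegative numeric matrix with zero diagonal and
#'   entries in \[0, 1\].
#' @export
connectivity_matrix <- function(env) {
  env <- as_roi_matrix(env, min_timepoints = 8L)
  if (nrow(env) < 3L) abort("need at least 3 regions")
  sds <- apply(env, 1L, sd)
  m <- suppressWarnings(cor(t(env)))
  if (any(sds == 0)) {
    warn("zero-variance row(s): their correlations set to 0")
    m[sds == 0, ] <- 0
    m[, sds == 0] <- 0
  }
  m[is.na(m)] <- 0
  m[m < 0] <- 0
  diag(m) <- 0
  m
}

#' Proportional threshold binarisation
#'
#' Keeps the strongest `k` per cent of edges: the threshold `P_k` is the
#' `(100 - k)`th percentile of the upper-triangular off-diagonal weights,
#' and an edge is present wherever its weight is `>= P_k`. Ties at the
#' threshold are all included, so the realised density can slightly exceed
#' `k` per cent.
#'
#' @param m symmetric nonnegative weight matrix (e.g. from
#'   [connectivity_matrix()]).
#' @param k percentage of edges to retain, strictly between 0 and 100.
#' @return an object of class `binary_graph`: `adjacency` (0/1 symmetric,
#'   zero diagonal), `threshold_k`, `p_k` (the weight cutoff),
#'   `realised_density`, and a `degenerate` flag (all weights equal).
#' @export
proportional_binarise <- function(m, k) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (k <= 0 || k >= 100) abort("k must be strictly between 0 and 100")
  w <- upper_tri_values(m)
  degenerate <- length(unique(w)) == 1L
  if (degenerate) {
    warn("all edge weights equal: threshold is degenerate (all edges or none)")
  }
  p_k <- as.numeric(quantile(w, probs = 1 - k / 100, names = FALSE))
  adj <- (m >= p_k) * 1L
  adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
  diag(adj) <- 0L
  storage.mode(adj) <- "integer"
  structure(
    list(adjacency = adj,
         threshold_k = k,
         p_k = p_k,
         realised_density = mean(upper_tri_values(adj)),
         degenerate = degenerate),
    class = "binary_graph"
  )
}

#' Algebraic connectivity (Fiedler value)
#'
#' The second-smallest eigenvalue of the graph Laplacian `L = D - A`,
#' computed by dense symmetric eigendecomposition. It is 0 exactly when the
#' graph is disconnected, and bounds both classical vertex connectivity and
#' the graph's synchronisability. Eigenvalues below `1e-9` are reported as 0.
#'
#' @param g a `binary_graph` from [proportional_binarise()], or a symmetric
#'   0/1 adjacency matrix.
#' @return nonnegative scalar, \eqn{\lambda_2}.
#' @examples
#' algebraic_connectivity(gen_benchmark_graph("complete", 5)) # 5
#' @export
algebraic_connectivity <- function(g) {
  adj <- if (inherits(g, "binary_graph")) g$adjacency else g
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  lap <- diag(rowSums(adj)) - adj
  ev <- eigen(lap, symmetric = TRUE, only.values = TRUE)$values
  l2 <- sort(ev)[2L]
  if (l2 < 1e-9) 0 else l2
}

#' Lempel-Ziv compressibility of a graph's adjacency matrix
#'
#' Flattens the binary adjacency matrix row-major into a length-\eqn{X^2}
#' bit vector and returns its LZ76 phrase count — an estimate of the length
#' of a program that reconstructs the graph. Ordered (e.g. modular)
#' topologies compress better and score lower than random ones.
#'
#' @inheritParams algebraic_connectivity
#' @return integer phrase count.
#' @export
graph_lz <- function(g) {
  adj <- if (inherits(g, "binary_graph")) g$adjacency else g
  stopifnot(is.matrix(adj))
  lz76_dictionary_size(as.integer(t(adj)))
}

#' Measure a connectivity matrix across proportional thresholds
#'
#' Evaluates a graph measure on [proportional_binarise()] graphs at each
#' threshold (10%, 20%, ..., 90% by default) and integrates the resulting
#' curve with the trapezoid rule (spacing in threshold-percent units), so
#' that no single threshold choice drives the result.
#'
#' @param m symmetric nonnegative weight matrix.
#' @param measure `"algebraic_connectivity"` or `"graph_lz"`.
#' @param thresholds increasing vector of percentages in (0, 100).
#' @return an object of class `threshold_curve`: a tibble of
#'   `(threshold, value)` in `$curve`, the `$integral`, and the measure name.
#' @export
threshold_curve <- function(m,
                            measure = c("algebraic_connectivity", "graph_lz"),
                            thresholds = seq(10, 90, by = 10)) {
  measure <- match.arg(measure)
  stopifnot(all(thresholds > 0 & thresholds < 100),
            !is.unsorted(thresholds, strictly = TRUE))
  fn <- switch(measure,
               algebraic_connectivity = algebraic_connectivity,
               graph_lz = graph_lz)
  vals <- vapply(thresholds, function(k) {
    fn(proportional_binarise(m, k))
  }, numeric(1))
  structure(
    list(curve = tibble::tibble(threshold = thresholds, value = vals),
         integral = pracma::trapz(thresholds, vals),
         measure = measure),
    class = "threshold_curve"
  )
}
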