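# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. Every stochastic operation in the package goes
# through this so that results are reproducible from (inputs, seed) alone.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Coerce a region-by-time input (matrix or data frame of numbers) to a
# numeric matrix and validate the shared invariants.
as_roi_matrix <- function(x, min_timepoints = 1L) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, nrow = 1L)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("expected a numeric region-by-time matrix")
  }
  if (anyNA(x)) abort("region-by-time matrix contains missing values")
  if (ncol(x) < min_timepoints) {
    abort(sprintf("need at least %d timepoints, got %d", min_timepoints, ncol(x)))
  }
  storage.mode(x) <- "double"
  x
}

upper_tri_values <- function(m) m[upper.tri(m, diag = FALSE)]

# slope + R^2 of a simple least-squares line fit, without lm() overhead
ls_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  dx <- x - mx
  slope <- sum(dx * (y - my)) / sum(dx * dx)
  fitted <- my + slope * dx
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(slope = slope, intercept = my - slope * mx, r_squared = r2)
}
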