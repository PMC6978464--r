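# broom-style tidiers for the package's result objects

#' @export
tidy.hurst_fit <- function(x, ...) {
  tibble::tibble(window_size = x$window_sizes, mean_rs = x$rs_values)
}

#' @export
glance.hurst_fit <- function(x, ...) {
  tibble::tibble(exponent = x$exponent, n_windows = length(x$window_sizes),
                 r_squared = x$fit_r_squared)
}

#' @export
tidy.higuchi_fit <- function(x, ...) {
  tibble::tibble(k = x$k_values, mean_length = x$mean_lengths)
}

#' @export
glance.higuchi_fit <- function(x, ...) {
  tibble::tibble(dimension = x$dimension, k_max = x$k_max,
                 r_squared = x$fit_r_squared)
}

#' @export
glance.sampen <- function(x, ...) {
  tibble::tibble(value = x$value, m = x$m, r = x$r,
                 match_count_m = x$match_count_m,
                 match_count_m1 = x$match_count_m1)
}

#' @export
glance.lz_result <- function(x, ...) {
  tibble::tibble(normalised = x$normalised, dictionary_size = x$dictionary_size,
                 surrogate_size = x$surrogate_size, raw_length = x$raw_length,
                 degenerate = x$degenerate)
}

#' @export
tidy.pca_compress <- function(x, ...) {
  tibble::tibble(component = seq_along(x$explained_curve),
                 cumulative_variance = x$explained_curve)
}

#' @export
glance.pca_compress <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 variance_threshold = x$variance_threshold)
}

#' @export
tidy.threshold_curve <- function(x, ...) x$curve

#' @export
glance.threshold_curve <- function(x, ...) {
  tibble::tibble(measure = x$measure, integral = x$integral)
}

#' @export
tidy.overall_pca <- function(x, ...) {
  tibble::tibble(metric = names(x$loadings),
                 loading = as.numeric(x$loadings))
}

#' @export
glance.overall_pca <- function(x, ...) {
  tibble::tibble(variance_explained = x$variance_explained,
                 n_profiles = nrow(x$scores))
}

#' @export
tidy.group_tests <- function(x, ...) x$pairwise

#' @export
glance.group_tests <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(metric = x$metric), x$omnibus)
}

#' @export
tidy.cohort_result <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$tests, tidy.group_tests),
                   .id = "metric")
}

#' @export
glance.cohort_result <- function(x, ...) {
  tibble::tibble(n_profiles = x$n_profiles,
                 pc1_variance_explained = x$pca$variance_explained)
}

#' @export
print.sampen <- function(x, ...) {
  cat(sprintf("Sample entropy (m = %d, r = %.4g): %.4f  [A = %d, B = %d]\n",
              x$m, x$r, x$value, x$match_count_m1, x$match_count_m))
  invisible(x)
}

#' @export
print.hurst_fit <- function(x, ...) {
  cat(sprintf("R/S Hurst exponent: %.3f (R^2 = %.3f, %d window sizes)\n",
              x$exponent, x$fit_r_squared, length(x$window_sizes)))
  invisible(x)
}

#' @export
print.higuchi_fit <- function(x, ...) {
  cat(sprintf("Higuchi fractal dimension: %.3f (k_max = %d, R^2 = %.3f)\n",
              x$dimension, x$k_max, x$fit_r_squared))
  invisible(x)
}

#' @export
print.lz_result <- function(x, ...) {
  cat(sprintf("Normalised LZ76 compressibility: %.4f (|D| = %d, surrogate %.1f, length %d)\n",
              x$normalised, x$dictionary_size, x$surrogate_size, x$raw_length))
  invisible(x)
}

#' @export
print.overall_pca <- function(x, ...) {
  cat(sprintf("Overall-complexity PC1: %.1f%% of variance over %d profiles\n",
              100 * x$variance_explained, nrow(x$scores)))
  cat("Loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("Cohort analysis of %d profiles\n", x$n_profiles))
  cat(sprintf("  PC1 variance explained: %.1f%%\n",
              100 * x$pca$variance_explained))
  for (nm in names(x$tests)) {
    om <- x$tests[[nm]]$omnibus
    cat(sprintf("  %-9s Kruskal-Wallis H = %.3f, p = %.4g\n",
                nm, om$statistic, om$p_value))
  }
  if (!is.null(x$dose)) {
    cat("Dose correlations (sedated scans):\n")
    print(as.data.frame(x$dose), row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("Synthetic cohort spec: %d subjects x %d conditions (%s), %d regions x %d timepoints, grades %s, seed %d\n",
              x$n_subjects, length(x$conditions),
              paste(x$conditions, collapse = "/"),
              x$n_regions, x$n_timepoints,
              paste(x$complexity_grade, collapse = "/"), x$seed))
  invisible(x)
}
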