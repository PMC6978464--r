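metric_names <- c("lzc", "sampen", "pca_n", "hurst", "higuchi",
                  "alg_conn", "lz_graph")

#' Full complexity profile of one scan
#'
#' Runs the whole per-scan pipeline once: Hilbert envelope, then the five
#' temporal measures (normalised Lempel-Ziv compressibility, mean sample
#' entropy, PCA component count, mean Hurst exponent, mean Higuchi
#' dimension — the per-series measures averaged over regions) and the two
#' threshold-integrated graph measures (algebraic connectivity and
#' adjacency compressibility) on the Pearson connectivity matrix of the
#' envelopes. Deterministic given the scan and `lz_seed`.
#'
#' @param scan numeric matrix (regions x timepoints).
#' @param subject_id,condition optional labels carried into the output.
#' @param m,r_coef sample-entropy embedding length and tolerance coefficient.
#' @param k_max Higuchi subsampling limit; `"auto"` selects a stable value
#'   via [select_kmax()] on a subsample of rows.
#' @param variance_threshold cumulative-variance target for the PCA count.
#' @param thresholds proportional thresholds for the graph curves.
#' @param lz_seed seed of the Lempel-Ziv surrogate shuffle.
#' @param min_window smallest R/S window size.
#' @return a one-row tibble with columns `subject_id`, `condition`, and the
#'   seven metrics `lzc`, `sampen`, `pca_n`, `hurst`, `higuchi`, `alg_conn`,
#'   `lz_graph`.
#' @examples
#' scan <- gen_cohort(cohort_spec(n_subjects = 2, n_regions = 20,
#'                                n_timepoints = 96, seed = 7))$scans[[1]]
#' compute_profile(scan, subject_id = "sub01", condition = "awake")
#' @export
compute_profile <- function(scan, subject_id = NA_character_,
                            condition = NA_character_,
                            m = 2L, r_coef = 0.3, k_max = 32L,
                            variance_threshold = 0.95,
                            thresholds = seq(10, 90, by = 10),
                            lz_seed = 1L, min_window = 8L) {
  scan <- as_roi_matrix(scan, min_timepoints = 8L)
  env <- hilbert_envelope(scan)
  if (identical(k_max, "auto")) {
    rows <- seq_len(min(nrow(env), 20L))
    k_max <- select_kmax(env[rows, , drop = FALSE])
  }
  lz <- lzc_normalised(scan, seed = lz_seed)
  se_vals <- apply(env, 1L, function(r) {
    suppressWarnings(sample_entropy(r, m = m, r_coef = r_coef)$value)
  })
  if (any(!is.finite(se_vals))) {
    warn(sprintf("%d region(s) with non-finite sample entropy excluded",
                 sum(!is.finite(se_vals))))
  }
  hu_vals <- hurst_rs_rows(env, min_window = min_window)
  hi_vals <- higuchi_fd_rows(env, k_max)
  pca <- pca_compressibility(env, variance_threshold = variance_threshold)
  fc <- connectivity_matrix(env)
  ac <- threshold_curve(fc, "algebraic_connectivity", thresholds)
  gl <- threshold_curve(fc, "graph_lz", thresholds)
  prof <- tibble::tibble(
    subject_id = subject_id,
    condition = condition,
    lzc = lz$normalised,
    sampen = mean(se_vals[is.finite(se_vals)]),
    pca_n = as.numeric(pca$n_components),
    hurst = mean(hu_vals),
    higuchi = mean(hi_vals),
    alg_conn = ac$integral,
    lz_graph = gl$integral
  )
  if (!all(is.finite(unlist(prof[metric_names])))) {
    bad <- metric_names[!is.finite(unlist(prof[metric_names]))]
    abort(paste("non-finite metric(s) in profile:", paste(bad, collapse = ", ")))
  }
  prof
}

#' Complexity profiles for a whole cohort
#'
#' Maps [compute_profile()] over every scan of a synthetic (or loaded)
#' cohort and joins the metadata (condition, dose).
#'
#' @param cohort a `synthetic_cohort` from [gen_cohort()], or a named list
#'   of scan matrices named `"<subject_id>.<condition>"` plus a `metadata`
#'   tibble supplied separately.
#' @param metadata tibble with `subject_id`, `condition` and optionally
#'   `dose`; taken from the cohort object when omitted.
#' @param ... passed on to [compute_profile()].
#' @return tibble with one row per scan: labels, the seven metrics, and
#'   `dose` when available.
#' @export
cohort_profiles <- function(cohort, metadata = NULL, ...) {
  if (inherits(cohort, "synthetic_cohort")) {
    scans <- cohort$scans
    if (is.null(metadata)) metadata <- cohort$metadata
  } else {
    scans <- cohort
  }
  stopifnot(!is.null(names(scans)), all(nzchar(names(scans))))
  profs <- purrr::map(names(scans), function(id) {
    parts <- strsplit(id, ".", fixed = TRUE)[[1L]]
    compute_profile(scans[[id]],
                    subject_id = parts[1L],
                    condition = if (length(parts) > 1L) parts[2L] else NA_character_,
                    ...)
  })
  out <- dplyr::bind_rows(profs)
  if (!is.null(metadata) && "dose" %in% names(metadata)) {
    out <- dplyr::left_join(out,
                            dplyr::select(metadata, "subject_id", "condition", "dose"),
                            by = c("subject_id", "condition"))
  }
  out
}

#' Inter-metric correlation matrix
#'
#' Pearson correlation between each pair of the seven complexity metrics
#' across all profiles (pooled across conditions), with the diagonal masked
#' to `NA`. A strong shared factor shows up as uniformly high off-diagonal
#' magnitudes, with the Hurst exponent anticorrelated with the others.
#'
#' @param profiles tibble of profiles (>= 4 rows) from [cohort_profiles()].
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return 7x7 symmetric correlation matrix with `NA` diagonal.
#' @export
metric_correlation_matrix <- function(profiles, method = "pearson") {
  x <- as.matrix(profiles[metric_names])
  if (nrow(x) < 4L) abort("need at least 4 profiles")
  sds <- apply(x, 2L, sd)
  if (any(sds == 0)) {
    warn("zero-variance metric(s): correlations undefined, set to NA")
  }
  m <- suppressWarnings(cor(x, method = method))
  m[, sds == 0] <- NA_real_
  m[sds == 0, ] <- NA_real_
  diag(m) <- NA_real_
  m
}

#' Overall-complexity principal component
#'
#' Standardises each of the seven metrics across profiles (so that their
#' wildly different scales cannot dominate) and extracts the first principal
#' component: its scores are the per-scan "overall complexity", its
#' explained-variance fraction quantifies how much a single construct
#' accounts for all seven measures. The component's sign is a reporting
#' convention only; it is oriented so that the loading on the Lempel-Ziv
#' metric is negative, and any sign flip of an input column leaves the
#' explained variance unchanged.
#'
#' @param profiles tibble of profiles (>= 4 rows).
#' @return an object of class `overall_pca`: `scores` (tibble with labels,
#'   dose when present, and `pc1`), `loadings` (named vector),
#'   `variance_explained`, and the full `explained_curve`.
#' @export
overall_complexity_pca <- function(profiles) {
  x <- as.matrix(profiles[metric_names])
  if (nrow(x) < 4L) abort("need at least 4 profiles")
  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  loadings <- pc$rotation[, 1L]
  scores <- pc$x[, 1L]
  if (loadings[["lzc"]] > 0) { # orientation convention
    loadings <- -loadings
    scores <- -scores
  }
  keep <- intersect(c("subject_id", "condition", "dose"), names(profiles))
  structure(
    list(scores = dplyr::bind_cols(profiles[keep],
                                   tibble::tibble(pc1 = as.numeric(scores))),
         loadings = loadings,
         variance_explained = ev[1L] / sum(ev),
         explained_curve = cumsum(ev) / sum(ev)),
    class = "overall_pca"
  )
}

#' Non-parametric condition comparison
#'
#' Kruskal-Wallis omnibus test across all conditions plus paired Wilcoxon
#' signed-rank tests for every condition pair, on one metric at a time.
#' Pairing is by subject; subjects missing from either condition of a pair
#' are dropped with a warning. Exact signed-rank p-values are used for
#' n <= 25 (ties permitting), the normal approximation otherwise. P-values
#' are reported uncorrected; set `p_adjust` for a Holm correction of the
#' pairwise set.
#'
#' @param profiles tibble with at least `subject_id`, `condition`, and the
#'   metric column.
#' @param value metric column name (string).
#' @param p_adjust multiple-testing correction for the pairwise p-values,
#'   `"none"` (default) or any [stats::p.adjust] method.
#' @return list of class `group_tests`: `omnibus` (tibble: statistic, df, p)
#'   and `pairwise` (tibble: pair, n, statistic, p).
#' @export
group_comparison <- function(profiles, value, p_adjust = "none") {
  stopifnot(value %in% names(profiles))
  conds <- unique(profiles$condition)
  if (length(conds) < 2L) abort("need at least 2 conditions")
  v <- profiles[[value]]
  kw <- kruskal.test(v, factor(profiles$condition, levels = conds))
  if (!is.finite(kw$statistic)) { # all values tied: no evidence of any kind
    kw$statistic[] <- 0
    kw$p.value <- 1
  }
  pairs <- utils::combn(conds, 2L, simplify = FALSE)
  pw <- purrr::map(pairs, function(pr) {
    a <- profiles[profiles$condition == pr[1L], c("subject_id", value)]
    b <- profiles[profiles$condition == pr[2L], c("subject_id", value)]
    common <- intersect(a$subject_id, b$subject_id)
    if (length(common) < length(union(a$subject_id, b$subject_id))) {
      warn(sprintf("unpaired subjects dropped for %s vs %s", pr[1L], pr[2L]))
    }
    av <- a[[value]][match(common, a$subject_id)]
    bv <- b[[value]][match(common, b$subject_id)]
    if (all(av == bv)) { # no nonzero differences: signed-rank degenerate
      stat <- 0; pval <- 1
    } else {
      wt <- suppressWarnings(
        wilcox.test(av, bv, paired = TRUE, exact = length(common) <= 25L)
      )
      stat <- unname(wt$statistic); pval <- wt$p.value
    }
    tibble::tibble(condition_a = pr[1L], condition_b = pr[2L],
                   n = length(common),
                   statistic = stat,
                   p_value = pval)
  })
  pw <- dplyr::bind_rows(pw)
  pw$p_value <- stats::p.adjust(pw$p_value, method = p_adjust)
  structure(
    list(metric = value,
         omnibus = tibble::tibble(statistic = unname(kw$statistic),
                                  df = unname(kw$parameter),
                                  p_value = kw$p.value),
         pairwise = pw),
    class = "group_tests"
  )
}

#' Dose-response correlation over sedated scans
#'
#' Correlation between a metric and the serum-concentration covariate across
#' sedated profiles only: zero-dose (awake) rows must be excluded before the
#' call, since they carry no concentration information.
#'
#' @param profiles tibble of sedated profiles (>= 4 rows, nonconstant dose).
#' @param value metric column name (string).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return one-row tibble: `metric`, `n`, `r`, `p_value`.
#' @export
dose_correlation <- function(profiles, value, method = "pearson") {
  stopifnot(value %in% names(profiles), "dose" %in% names(profiles))
  d <- profiles$dose
  v <- profiles[[value]]
  keep <- is.finite(d) & d > 0
  d <- d[keep]; v <- v[keep]
  if (length(d) < 4L) abort("need at least 4 profiles with nonzero dose")
  if (sd(d) == 0) abort("dose is constant; correlation undefined")
  ct <- cor.test(v, d, method = method)
  tibble::tibble(metric = value, n = length(d),
                 r = unname(ct$estimate), p_value = ct$p.value)
}

#' Higher-order analysis of a cohort's profiles
#'
#' Convenience wrapper producing the full higher-order result set: the
#' inter-metric correlation matrix, the overall-complexity principal
#' component, per-metric (and PC1) condition tests, and per-metric (and PC1)
#' dose correlations when a nonconstant dose covariate is present.
#'
#' @param profiles tibble from [cohort_profiles()].
#' @param conditions optional ordered condition labels (defaults to order of
#'   appearance).
#' @return an object of class `cohort_result` with elements
#'   `metric_correlations`, `pca`, `tests` (named list of `group_tests`),
#'   and `dose` (tibble or `NULL`).
#' @export
analyse_cohort <- function(profiles, conditions = NULL) {
  if (!is.null(conditions)) {
    profiles$condition <- factor(profiles$condition, levels = conditions)
    profiles$condition <- as.character(profiles$condition)
  }
  pca <- overall_complexity_pca(profiles)
  prof_pc <- dplyr::bind_cols(profiles, tibble::tibble(pc1 = pca$scores$pc1))
  tests <- purrr::map(c(metric_names, "pc1"),
                      function(v) group_comparison(prof_pc, v))
  names(tests) <- c(metric_names, "pc1")
  dose_tab <- NULL
  if ("dose" %in% names(profiles) &&
      sum(is.finite(profiles$dose) & profiles$dose > 0) >= 4L) {
    sed <- prof_pc[is.finite(prof_pc$dose) & prof_pc$dose > 0, ]
    if (sd(sed$dose) > 0) {
      dose_tab <- dplyr::bind_rows(
        purrr::map(c(metric_names, "pc1"), function(v) dose_correlation(sed, v))
      )
    }
  }
  structure(
    list(metric_correlations = metric_correlation_matrix(profiles),
         pca = pca,
         tests = tests,
         dose = dose_tab,
         n_profiles = nrow(profiles)),
    class = "cohort_result"
  )
}
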