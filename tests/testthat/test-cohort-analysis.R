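test_that("profiles are total, finite, and deterministic", {
  scan <- tiny_scan(n_regions = 12, n_timepoints = 64, phi = 0.4, seed = 1)
  p1 <- compute_profile(scan, "s01", "awake", k_max = 8)
  p2 <- compute_profile(scan, "s01", "awake", k_max = 8)
  expect_identical(p1, p2)
  expect_true(all(is.finite(unlist(p1[complexbold:::metric_names]))))
  expect_named(p1, c("subject_id", "condition", complexbold:::metric_names))
})

test_that("automatic k_max selection plugs into the profile", {
  scan <- tiny_scan(n_regions = 6, n_timepoints = 96, seed = 2)
  p <- compute_profile(scan, k_max = "auto")
  expect_true(is.finite(p$higuchi))
})

test_that("cohort profiles join dose metadata by subject and condition", {
  coh <- gen_cohort(cohort_spec(n_subjects = 3, n_regions = 14,
                                n_timepoints = 64, seed = 31))
  profs <- cohort_profiles(coh, k_max = 8)
  expect_equal(nrow(profs), 6)
  expect_true("dose" %in% names(profs))
  expect_equal(profs$dose,
               coh$metadata$dose[match(paste(profs$subject_id, profs$condition),
                                       paste(coh$metadata$subject_id,
                                             coh$metadata$condition))])
})

test_that("metric correlations detect collinearity and independence", {
  set.seed(51)
  latent <- rnorm(30)
  perfect <- tibble::tibble(
    lzc = latent, sampen = 2 * latent, pca_n = -latent, hurst = -3 * latent,
    higuchi = latent + 1, alg_conn = 0.5 * latent, lz_graph = 10 * latent
  )
  m <- metric_correlation_matrix(perfect)
  expect_true(all(abs(m[upper.tri(m)]) > 1 - 1e-9))
  expect_true(all(is.na(diag(m))))
  noisy <- tibble::as_tibble(as.data.frame(matrix(rnorm(7 * 200), 200, 7,
    dimnames = list(NULL, complexbold:::metric_names))))
  m2 <- metric_correlation_matrix(noisy)
  expect_lt(max(abs(m2[upper.tri(m2)])), 0.3)
  expect_error(metric_correlation_matrix(perfect[1:3, ]), "at least 4")
})

test_that("overall-complexity PCA recovers rank-1 structure and orientation", {
  set.seed(53)
  latent <- rnorm(40)
  rank1 <- tibble::tibble(
    lzc = latent, sampen = latent, pca_n = latent, hurst = -latent,
    higuchi = latent, alg_conn = latent, lz_graph = latent
  )
  res <- overall_complexity_pca(rank1)
  expect_equal(res$variance_explained, 1)
  expect_lt(res$loadings[["lzc"]], 0)
  # independent metrics: no dominant component at n = 30
  maxev <- sapply(1:20, function(s) {
    set.seed(600 + s)
    df <- tibble::as_tibble(as.data.frame(matrix(rnorm(7 * 30), 30, 7,
      dimnames = list(NULL, complexbold:::metric_names))))
    overall_complexity_pca(df)$variance_explained
  })
  expect_lt(max(maxev), 0.45)
})

test_that("PC1 variance explained is invariant to rescaling and sign flips", {
  coh <- gen_cohort(cohort_spec(n_subjects = 4, n_regions = 14,
                                n_timepoints = 64, seed = 57))
  profs <- cohort_profiles(coh, k_max = 8)
  base <- overall_complexity_pca(profs)$variance_explained
  flipped <- profs
  flipped$hurst <- -flipped$hurst
  expect_equal(overall_complexity_pca(flipped)$variance_explained, base,
               tolerance = 1e-12)
  scaled <- profs
  scaled$lz_graph <- scaled$lz_graph * 1000
  expect_equal(overall_complexity_pca(scaled)$variance_explained, base,
               tolerance = 1e-12)
})

test_that("group comparison handles the no-signal case exactly", {
  profs <- tibble::tibble(
    subject_id = rep(sprintf("s%02d", 1:6), 2),
    condition = rep(c("awake", "deep"), each = 6),
    lzc = rep(0.9, 12)
  )
  gt <- group_comparison(profs, "lzc")
  expect_equal(gt$omnibus$statistic, 0)
  expect_equal(gt$omnibus$p_value, 1)
  expect_equal(gt$pairwise$p_value, 1)
})

test_that("all-positive paired differences give the textbook exact p", {
  set.seed(59)
  a <- c(3.1, 1.4, 4.9, 2.6, 5.3, 9.2, 2.2, 6.8)
  profs <- tibble::tibble(
    subject_id = rep(sprintf("s%d", 1:8), 2),
    condition = rep(c("awake", "deep"), each = 8),
    lzc = c(a + runif(8, 0.5, 1.5), a)
  )
  gt <- group_comparison(profs, "lzc")
  expect_equal(gt$pairwise$p_value, 2 / 2^8, tolerance = 1e-12)
})

test_that("exact Wilcoxon p matches full sign enumeration", {
  diffs <- c(1.2, -0.4, 2.2, 0.6, -1.8, 3.1, 0.9, -0.2, 1.5, 2.8)
  n <- length(diffs)
  w_obs <- sum(rank(abs(diffs))[diffs > 0])
  # null distribution of W by enumerating all 2^n sign assignments
  rk <- rank(abs(diffs))
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% rk
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  p_exact <- min(1, 2 * min(p_low, p_high))
  profs <- tibble::tibble(
    subject_id = rep(sprintf("s%02d", 1:n), 2),
    condition = rep(c("awake", "deep"), each = n),
    lzc = c(diffs + 10, rep(10, n))
  )
  gt <- group_comparison(profs, "lzc")
  expect_equal(gt$pairwise$p_value, p_exact, tolerance = 1e-12)
})

test_that("unpaired subjects are dropped with a warning", {
  profs <- tibble::tibble(
    subject_id = c(sprintf("s%d", 1:6), sprintf("s%d", 2:6)),
    condition = c(rep("awake", 6), rep("deep", 5)),
    lzc = rnorm(11)
  )
  expect_warning(gt <- group_comparison(profs, "lzc"), "unpaired")
  expect_equal(gt$pairwise$n, 5)
})

test_that("dose correlation recovers exact linear dependence", {
  profs <- tibble::tibble(dose = c(100, 200, 300, 400, 500),
                          lzc = c(0.9, 0.8, 0.7, 0.6, 0.5))
  dc <- dose_correlation(profs, "lzc")
  expect_equal(dc$r, -1, tolerance = 1e-12)
  expect_error(dose_correlation(tibble::tibble(dose = rep(5, 6), lzc = rnorm(6)),
                                "lzc"), "constant")
  expect_error(dose_correlation(tibble::tibble(dose = c(0, 0, 0, 1),
                                               lzc = rnorm(4)), "lzc"),
               "at least 4")
})

test_that("zero-dose profiles are excluded from the dose analysis", {
  profs <- tibble::tibble(dose = c(0, 0, 150, 250, 350, 450),
                          lzc = c(5, -5, 0.9, 0.8, 0.7, 0.6))
  dc <- dose_correlation(profs, "lzc")
  expect_equal(dc$n, 4)
  expect_equal(dc$r, -1, tolerance = 1e-9)
})

test_that("analyse_cohort assembles all higher-order pieces", {
  coh <- gen_cohort(cohort_spec(n_subjects = 4, n_regions = 14,
                                n_timepoints = 64,
                                conditions = c("awake", "mild", "deep"),
                                complexity_grade = c(0, 0.4, 0.8),
                                seed = 61))
  profs <- cohort_profiles(coh, k_max = 8)
  res <- analyse_cohort(profs, conditions = c("awake", "mild", "deep"))
  expect_s3_class(res, "cohort_result")
  expect_equal(dim(res$metric_correlations), c(7, 7))
  expect_equal(nrow(res$pca$scores), 12)
  expect_named(res$tests, c(complexbold:::metric_names, "pc1"))
  expect_equal(nrow(res$tests$lzc$pairwise), 3)
  expect_true(!is.null(res$dose))
  expect_equal(unique(res$dose$n), sum(profs$dose > 0))
  gl <- glance(res)
  expect_true(gl$pc1_variance_explained > 0 & gl$pc1_variance_explained <= 1)
})

test_that("tidiers return well-formed tibbles", {
  hf <- hurst_rs(gen_fgn(0.7, 256, seed = 3))
  expect_named(glance(hf), c("exponent", "n_windows", "r_squared"))
  expect_equal(nrow(tidy(hf)), length(hf$window_sizes))
  tc <- threshold_curve(random_weight_matrix(10, seed = 5), "graph_lz")
  expect_named(tidy(tc), c("threshold", "value"))
  expect_equal(glance(tc)$integral, tc$integral)
})
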