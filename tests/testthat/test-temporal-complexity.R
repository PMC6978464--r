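test_that("LZ76 phrase counts match the definition on elementary inputs", {
  expect_equal(lz76_dictionary_size(0L), 1L)
  expect_equal(lz76_dictionary_size(c(0L, 1L)), 2L)
  expect_equal(lz76_dictionary_size(rep(0L, 6)), bf_lz76(rep(0L, 6)))
  alt <- rep(c(0L, 1L), 4)
  expect_equal(lz76_dictionary_size(alt), bf_lz76(alt))
  expect_error(lz76_dictionary_size(integer(0)), "empty")
  expect_error(lz76_dictionary_size(c(0L, 2L)), "0/1")
})

test_that("LZ76 agrees with the brute-force parser on random strings", {
  set.seed(41)
  for (i in 1:200) {
    bits <- sample(0:1, sample(1:64, 1), replace = TRUE,
                   prob = c(0.5, 0.5) + c(1, -1) * runif(1, -0.3, 0.3))
    expect_equal(lz76_dictionary_size(bits), bf_lz76(bits))
  }
})

test_that("normalised LZ of structureless binary data is near 1", {
  set.seed(13)
  vals <- sapply(1:5, function(s) {
    bin <- matrix(sample(0:1, 40 * 100, replace = TRUE), 40, 100)
    lzc_normalised(bin, seed = s, envelope = FALSE)$normalised
  })
  expect_true(all(vals > 0.9 & vals < 1.1))
})

test_that("periodic signals are more compressible than noise", {
  set.seed(19)
  t <- seq_len(128)
  periodic <- t(replicate(20, sign(sin(2 * pi * t / 16)) + 1.5))
  noise <- matrix(rnorm(20 * 128) + 5, 20, 128)
  expect_lt(lzc_normalised(periodic)$normalised,
            lzc_normalised(noise)$normalised)
})

test_that("all-constant input flags the normalised LZ as degenerate", {
  res <- suppressWarnings(lzc_normalised(matrix(2, 4, 32)))
  expect_true(res$degenerate)
  expect_equal(res$normalised, 1) # equal minimal dictionaries either side
})

test_that("sample entropy of a constant series is exactly zero", {
  expect_identical(sample_entropy(rep(1, 100))$value, 0)
})

test_that("sample entropy counts match the brute-force counter exactly", {
  x <- rep(c(1, 2, 3), length.out = 60)
  se <- sample_entropy(x, m = 2, r_coef = 0.3)
  bf <- bf_sampen_counts(x, 2L, 0.3 * sd(x))
  expect_equal(se$match_count_m, unname(bf["B"]))
  expect_equal(se$match_count_m1, unname(bf["A"]))
  expect_equal(se$value, -log(bf["A"] / bf["B"]), ignore_attr = TRUE)
})

test_that("widening the tolerance r only adds template matches", {
  # A and B are individually non-decreasing in r; their ratio (and so the
  # entropy) can wobble locally, but falls over any broad range
  set.seed(29)
  for (rep_i in 1:5) {
    x <- rnorm(80)
    rs <- seq(0.1, 1.2, by = 0.1) * sd(x)
    counts <- sapply(rs, function(r) {
      se <- suppressWarnings(sample_entropy(x, r = r))
      c(se$match_count_m, se$match_count_m1, se$value)
    })
    expect_true(all(diff(counts[1, ]) >= 0))
    expect_true(all(diff(counts[2, ]) >= 0))
    vals <- counts[3, ]
    fin <- which(is.finite(vals))
    expect_lt(vals[max(fin)], vals[min(fin)])
  }
})

test_that("sample entropy flags the degenerate match regimes", {
  expect_warning(se <- sample_entropy(c(1, 2, 4, 8, 16, 32, 64), r = 0.1),
                 "undefined")
  expect_true(is.na(se$value))
  # repeating (1,1) templates that always continue differently: B > 0, A = 0
  x <- c(1, 1, 2, 1, 1, 3, 1, 1, 4, 1, 1, 5)
  expect_warning(se2 <- sample_entropy(x, r = 0.1), "infinite")
  expect_identical(se2$value, Inf)
  expect_gt(se2$match_count_m, 0)
  expect_error(sample_entropy(1:3), "too short")
})

test_that("R/S Hurst estimates are unbiased enough on white noise and ramps", {
  est <- sapply(1:20, function(s) {
    set.seed(s)
    hurst_rs(rnorm(2048))$exponent
  })
  expect_lt(abs(mean(est) - 0.5), 0.07)
  expect_gte(hurst_rs(as.numeric(1:512))$exponent, 0.9)
  expect_error(hurst_rs(rnorm(16)), "too short")
})

test_that("the matrix fast path reproduces the per-series Hurst estimator", {
  set.seed(31)
  m <- matrix(rnorm(6 * 160), 6, 160)
  fast <- complexbold:::hurst_rs_rows(m)
  slow <- apply(m, 1, function(r) hurst_rs(r)$exponent)
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("Higuchi dimension spans smooth (1) to noise-like (2)", {
  expect_lt(abs(higuchi_fd(as.numeric(1:512), 32)$dimension - 1), 0.1)
  est <- sapply(1:20, function(s) {
    set.seed(s)
    higuchi_fd(rnorm(512), 32)$dimension
  })
  expect_true(mean(est) > 1.85 && mean(est) < 2.05)
  expect_error(higuchi_fd(rnorm(50), 32), "exceed")
})

test_that("k_max selection respects feasibility and stability", {
  set.seed(37)
  series <- lapply(1:5, function(i) rnorm(190))
  k <- select_kmax(series)
  expect_lte(k, 32)
  expect_true(k %in% 2^(1:5)) # 64 and 128 infeasible at N = 190
  expect_equal(select_kmax(list(rnorm(80)), candidates = c(32)), 32L)
  # stability self-check: selected k's dimension close to next candidate's
  feas <- 2^(1:5)
  dims <- sapply(feas, function(kk) {
    mean(sapply(series, function(s) higuchi_fd(s, kk)$dimension))
  })
  i <- match(k, feas)
  if (i < length(feas)) expect_lt(abs(dims[i] - dims[i + 1]), 0.05)
})

test_that("PCA component counts track the true rank structure", {
  t <- seq_len(200)
  rank1 <- outer(rep(1, 10), sin(2 * pi * t / 50))
  expect_equal(pca_compressibility(rank1)$n_components, 1L)
  set.seed(43)
  flat <- matrix(rnorm(10 * 1000), 10, 1000)
  expect_equal(pca_compressibility(flat)$n_components, 10L)
  # g orthogonal factors + small noise -> about g components
  g <- 4
  factors <- matrix(rnorm(g * 300), g, 300)
  load <- matrix(rnorm(30 * g), 30, g)
  data <- load %*% factors + 0.05 * matrix(rnorm(30 * 300), 30, 300)
  expect_lte(abs(pca_compressibility(data)$n_components - g), 1)
})

test_that("zero-variance regions are tolerated with a warning in the PCA", {
  set.seed(47)
  m <- rbind(matrix(rnorm(4 * 50), 4, 50), rep(2, 50))
  expect_warning(res <- pca_compressibility(m), "zero-variance")
  expect_true(res$n_components >= 1)
  curve <- res$explained_curve
  expect_true(all(diff(curve) >= -1e-12))
  expect_gte(curve[res$n_components], 0.95)
})
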