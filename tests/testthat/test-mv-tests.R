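# Brute-force Hotelling oracle: explicit means, covariances and inverse,
# no shortcuts shared with the implementation.
oracle_hotelling <- function(a, b) {
  n1 <- nrow(a); n2 <- nrow(b); p <- ncol(a)
  m1 <- colMeans(a); m2 <- colMeans(b)
  S1 <- matrix(0, p, p); S2 <- matrix(0, p, p)
  for (i in seq_len(n1)) S1 <- S1 + tcrossprod(a[i, ] - m1)
  for (i in seq_len(n2)) S2 <- S2 + tcrossprod(b[i, ] - m2)
  Sp <- (S1 + S2) / (n1 + n2 - 2)
  d <- m1 - m2
  T2 <- (n1 * n2 / (n1 + n2)) * drop(t(d) %*% solve(Sp) %*% d)
  Fs <- (n1 + n2 - p - 1) / (p * (n1 + n2 - 2)) * T2
  list(T2 = T2, F = Fs, p = pf(Fs, p, n1 + n2 - p - 1, lower.tail = FALSE))
}

test_that("identical samples give T2 = 0 and p = 1", {
  x <- gauss_window(10, 4, seed = 1)
  ht <- hotelling_t2(x, x)
  expect_equal(unname(ht$statistic["T2"]), 0, tolerance = 1e-12)
  expect_equal(ht$p.value, 1)
})

test_that("univariate Hotelling is the squared pooled t", {
  # the hand case: pooled t on {0,2} vs {1,3} is -1/sqrt(2), so T2 = 0.5
  ht <- hotelling_t2(matrix(c(0, 2), 2), matrix(c(1, 3), 2))
  expect_equal(unname(ht$statistic["T2"]), 0.5, tolerance = 1e-12)
  for (i in 1:50) {
    set.seed(i)
    a <- matrix(rnorm(7, i %% 3), 7)
    b <- matrix(rnorm(9), 9)
    tt <- t.test(a, b, var.equal = TRUE)
    ht <- hotelling_t2(a, b)
    expect_equal(unname(ht$statistic["T2"]), unname(tt$statistic)^2,
                 tolerance = 1e-10)
    expect_equal(ht$p.value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("Hotelling matches the brute-force oracle at screen scale", {
  set.seed(42)
  a <- matrix(rnorm(24 * 30, 0, 1), 24, 30)
  b <- matrix(rnorm(24 * 30, 0.2, 1.1), 24, 30)
  ht <- hotelling_t2(a, b)
  or <- oracle_hotelling(a, b)
  expect_equal(unname(ht$statistic["T2"]), or$T2, tolerance = 1e-10)
  expect_equal(unname(ht$statistic["F"]), or$F, tolerance = 1e-10)
  expect_equal(ht$p.value, or$p, tolerance = 1e-10)
  expect_equal(unname(ht$parameter), c(30, 24 + 24 - 30 - 1))
})

test_that("Hotelling is invariant under shared invertible transforms", {
  set.seed(3)
  a <- matrix(rnorm(36), 12, 3)
  b <- matrix(rnorm(36, 0.5), 12, 3)
  base <- hotelling_t2(a, b)$statistic["T2"]
  for (i in 1:10) {
    repeat {
      A <- matrix(rnorm(9), 3, 3)
      if (abs(det(A)) > 0.1) break
    }
    shift <- rnorm(3)
    ta <- sweep(a %*% A, 2, shift, `+`)
    tb <- sweep(b %*% A, 2, shift, `+`)
    expect_equal(unname(hotelling_t2(ta, tb)$statistic["T2"]), unname(base),
                 tolerance = 1e-8)
  }
})

test_that("Hotelling rejects unusable inputs informatively", {
  a <- gauss_window(5, 10, seed = 4)
  b <- gauss_window(5, 10, seed = 5)
  expect_error(hotelling_t2(a, b), "hd_two_sample_test")
  # singular pooled covariance: a duplicated coordinate
  a2 <- cbind(gauss_window(10, 2, seed = 6), 0)
  b2 <- cbind(gauss_window(10, 2, seed = 7), 0)
  expect_error(hotelling_t2(a2, b2), "singular")
  ht <- hotelling_t2(a2, b2, ridge = 1e-6)
  expect_p_value(ht$p.value)
  expect_equal(ht$ridge, 1e-6)
  expect_error(hotelling_t2(gauss_window(4, 2), gauss_window(4, 3)), "dimension")
})

test_that("the high-dimensional test is exact on identical samples", {
  x <- gauss_window(24, 30, seed = 8)
  ht <- hd_two_sample_test(x, x, seed = 1)
  expect_equal(unname(ht$statistic["T_HD"]), 0)
  expect_equal(ht$p.value, 1)
})

test_that("the high-dimensional test is bit-for-bit reproducible by seed", {
  a <- gauss_window(24, 30, seed = 9)
  b <- gauss_window(24, 30, seed = 10)
  p1 <- hd_two_sample_test(a, b, n_boot = 500, seed = 77)$p.value
  p2 <- hd_two_sample_test(a, b, n_boot = 500, seed = 77)$p.value
  expect_identical(p1, p2)
  p3 <- hd_two_sample_test(a, b, n_boot = 500, seed = 78)$p.value
  expect_p_value(p3)
  m1 <- hd_two_sample_test(a, b, n_boot = 500, seed = 77,
                           calibration = "multiplier")$p.value
  m2 <- hd_two_sample_test(a, b, n_boot = 500, seed = 77,
                           calibration = "multiplier")$p.value
  expect_identical(m1, m2)
})

test_that("the high-dimensional test detects sparse mean shifts", {
  # 3-within-group-SD shift planted in 5 of 30 coordinates
  hits <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    a <- matrix(rnorm(24 * 30), 24, 30)
    b <- matrix(rnorm(24 * 30), 24, 30)
    b[, 1:5] <- b[, 1:5] + 3
    hd_two_sample_test(a, b, n_boot = 400, seed = i)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the high-dimensional test holds its level on null data", {
  # reduced-size level check; the full calibration run backs acceptance
  ps <- vapply(1:200, function(i) {
    set.seed(2000 + i)
    hd_two_sample_test(matrix(rnorm(24 * 30), 24), matrix(rnorm(24 * 30), 24),
                       n_boot = 400, seed = i)$p.value
  }, numeric(1))
  expect_gte(mean(ps < 0.05), 0.01)
  expect_lte(mean(ps < 0.05), 0.10)
  # p-values roughly uniform: similarity criterion mass near the top decile
  expect_gte(mean(ps > 0.9), 0.04)
  expect_lte(mean(ps > 0.9), 0.18)
})

test_that("hd test validates its inputs", {
  a <- gauss_window(4, 6, seed = 1)
  expect_error(hd_two_sample_test(a, gauss_window(4, 5, seed = 1), seed = 1),
               "dimension")
  expect_error(hd_two_sample_test(a, a, n_boot = 100, seed = 1), ">= 200")
  expect_error(hd_two_sample_test(a, a), "seed")
  expect_error(hd_two_sample_test(matrix(1:6, 1), matrix(1:6, 1), seed = 1),
               "at least 2")
})

test_that("Welch test matches the hand computation and is antisymmetric", {
  ht <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(round(unname(ht$statistic), 3), -3.674)
  expect_equal(unname(ht$statistic), -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(unname(ht$parameter), 4, tolerance = 1e-10)
  rev <- welch_t(c(4, 5, 6), c(1, 2, 3))
  expect_equal(unname(rev$statistic), -unname(ht$statistic), tolerance = 1e-12)
  expect_equal(rev$p.value, ht$p.value, tolerance = 1e-12)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  expect_error(welch_t(c(1, 1, 1), c(1, 1, 1)), "undefined")
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("chi-square reproduces the rod-phenotype table statistics", {
  lat <- pearson_chi2_2x2(rbind(c(9, 15), c(16, 8)))
  expect_equal(round(unname(lat$statistic), 2), 4.09)
  expect_equal(unname(lat$parameter), 1)
  expect_lt(lat$p.value, 0.05)
  ven <- pearson_chi2_2x2(rbind(c(8, 16), c(16, 8)))
  expect_equal(round(unname(ven$statistic), 2), 5.33)
  expect_lt(ven$p.value, 0.05)
})

test_that("chi-square handles independence and table symmetries", {
  flat <- pearson_chi2_2x2(rbind(c(5, 5), c(5, 5)))
  expect_equal(unname(flat$statistic), 0)
  expect_equal(flat$p.value, 1)
  tab <- rbind(c(9, 15), c(16, 8))
  base <- pearson_chi2_2x2(tab)$statistic
  expect_equal(pearson_chi2_2x2(t(tab))$statistic, base, tolerance = 1e-12)
  expect_equal(pearson_chi2_2x2(tab[2:1, ])$statistic, base, tolerance = 1e-12)
  expect_equal(pearson_chi2_2x2(tab[, 2:1])$statistic, base, tolerance = 1e-12)
  expect_error(pearson_chi2_2x2(rbind(c(0, 0), c(5, 5))), "margin")
  expect_error(pearson_chi2_2x2(rbind(c(1.5, 2), c(3, 4))), "integer")
  expect_error(pearson_chi2_2x2(matrix(1:6, 2)), "2x2")
})

test_that("ANOVA detects planted group offsets", {
  hits <- vapply(1:200, function(i) {
    set.seed(3000 + i)
    g <- list(a = rnorm(10, 0, 0.5), b = rnorm(10, 1, 0.5), c = rnorm(10, 2, 0.5))
    anova_pairwise_fdr(g)$anova$p.value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("ANOVA p-values are near-uniform under the null", {
  ps <- vapply(1:200, function(i) {
    set.seed(4000 + i)
    anova_pairwise_fdr(list(a = rnorm(10), b = rnorm(10), c = rnorm(10)))$anova$p.value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("pairwise adjustment is Benjamini-Hochberg step-up", {
  set.seed(5)
  res <- anova_pairwise_fdr(list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2)))
  pw <- res$pairwise
  expect_equal(nrow(pw), 3L)
  # hand step-up: p_(i) * m / i, cumulative minimum from the largest
  ord <- order(pw$p_raw)
  hand <- pw$p_raw[ord] * 3 / seq_len(3)
  hand <- rev(cummin(rev(hand)))
  expect_equal(pw$p_adj[ord], pmin(hand, 1), tolerance = 1e-12)
  expect_equal(pw$p_adj, stats::p.adjust(pw$p_raw, "BH"), tolerance = 1e-15)
})

test_that("ANOVA rejects degenerate groupings", {
  expect_error(anova_pairwise_fdr(list(a = c(1, 1), b = c(1, 1))), "identical")
  expect_error(anova_pairwise_fdr(list(a = 1, b = c(1, 2))), "n >= 2")
  expect_error(anova_pairwise_fdr(list(a = c(1, 2))), "2 groups")
})
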