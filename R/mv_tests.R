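# Hypothesis tests used by the screening analysis. Hotelling's T-squared and
# the high-dimensional studentized max-type test are implemented here from
# their definitions; univariate helpers delegate to stats::.

.vmr_test <- function(statistic, parameter = NULL, p.value, method, data.name,
                      extra = list()) {
  out <- c(list(statistic = statistic, parameter = parameter,
                p.value = p.value, method = method, data.name = data.name),
           extra)
  class(out) <- c("vmr_test", "htest")
  out
}

.as_window_pair <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!is.numeric(a) || !is.numeric(b)) .stop_fmt("samples must be numeric matrices")
  if (ncol(a) != ncol(b))
    .stop_fmt("samples have different dimensions (%d vs %d)", ncol(a), ncol(b))
  list(a = a, b = b)
}

#' Two-sample Hotelling's T-squared test
#'
#' Compares the mean displacement vectors of two groups of larvae over the
#' same post-event window using the pooled covariance. The statistic is
#' converted to an F variate as
#' `F = (n1 + n2 - p - 1) / (p * (n1 + n2 - 2)) * T^2 ~ F(p, n1 + n2 - p - 1)`,
#' testing the null that the two mean vectors are equal.
#'
#' @param a,b numeric matrices (rows = larvae, columns = seconds), e.g.
#'   [extract_window()] results, with equal column dimension.
#' @param ridge optional non-negative ridge added to the pooled covariance
#'   diagonal when it is singular; 0 (default) raises an error instead. When a
#'   ridge is used the result records it.
#' @return a `vmr_test` (printable as an `htest`) with `T2` and `F` statistics,
#'   degrees of freedom `df1 = p`, `df2 = n1 + n2 - p - 1`, the p-value and
#'   sample sizes.
#' @examples
#' set.seed(1)
#' hotelling_t2(matrix(rnorm(120), 24), matrix(rnorm(120) + 1, 24))
#' @export
hotelling_t2 <- function(a, b, ridge = 0) {
  w <- .as_window_pair(a, b)
  n1 <- nrow(w$a); n2 <- nrow(w$b); p <- ncol(w$a)
  if (n1 < 2L || n2 < 2L) .stop_fmt("need at least 2 larvae per group")
  if (p > n1 + n2 - 2L)
    .stop_fmt(paste("dimension p = %d exceeds n1 + n2 - 2 = %d; the pooled",
                    "covariance cannot be inverted -- use hd_two_sample_test()"),
              p, n1 + n2 - 2L)
  if (!is.numeric(ridge) || ridge < 0) .stop_fmt("`ridge` must be >= 0")
  d <- colMeans(w$a) - colMeans(w$b)
  df2 <- n1 + n2 - p - 1L
  if (all(d == 0)) {
    # the quadratic form vanishes for a zero mean difference whatever the
    # covariance (identical groups would otherwise look singular)
    return(.vmr_test(statistic = c(T2 = 0, F = 0),
                     parameter = c(df1 = p, df2 = df2), p.value = 1,
                     method = "Two-sample Hotelling's T-squared test",
                     data.name = sprintf("%d vs %d larvae, p = %d s", n1, n2, p),
                     extra = list(n1 = n1, n2 = n2, p_dim = p, ridge = 0)))
  }
  S <- ((n1 - 1) * stats::cov(w$a) + (n2 - 1) * stats::cov(w$b)) / (n1 + n2 - 2)
  solve_S <- function(S) tryCatch(solve(S, d), error = function(e) NULL)
  Sd <- solve_S(S)
  ridge_used <- 0
  if (is.null(Sd) && ridge > 0) {
    Sd <- solve_S(S + diag(ridge, p))
    ridge_used <- ridge
  }
  if (is.null(Sd))
    .stop_fmt("pooled covariance is singular; pass `ridge` > 0 or reduce the window")
  T2 <- (n1 * n2 / (n1 + n2)) * sum(d * Sd)
  Fstat <- (n1 + n2 - p - 1) / (p * (n1 + n2 - 2)) * T2
  pval <- stats::pf(Fstat, p, df2, lower.tail = FALSE)
  .vmr_test(statistic = c(T2 = T2, F = Fstat),
            parameter = c(df1 = p, df2 = df2),
            p.value = pval,
            method = if (ridge_used > 0)
              sprintf("Two-sample Hotelling's T-squared test (ridge %g)", ridge_used)
            else "Two-sample Hotelling's T-squared test",
            data.name = sprintf("%d vs %d larvae, p = %d s", n1, n2, p),
            extra = list(n1 = n1, n2 = n2, p_dim = p, ridge = ridge_used))
}

# Studentized coordinate-wise statistics |m1 - m2| / se for column-selection
# matrix S (n x B of 0/1 with n1 ones per column). Returns a p x B matrix.
.hd_stat_matrix <- function(Z, Z2, S, n1, n2) {
  s1 <- crossprod(Z, S); q1 <- crossprod(Z2, S)
  s2 <- crossprod(Z, 1 - S); q2 <- crossprod(Z2, 1 - S)
  m1 <- s1 / n1; m2 <- s2 / n2
  v1 <- (q1 - n1 * m1^2) / (n1 - 1)
  v2 <- (q2 - n2 * m2^2) / (n2 - 1)
  abs(m1 - m2) / sqrt(v1 / n1 + v2 / n2)
}

#' High-dimensional two-sample mean test (studentized max statistic)
#'
#' For windows whose dimension exceeds the per-group sample size (the 30-s
#' window with 24 larvae per group), the pooled covariance is singular and
#' Hotelling's test is unavailable. This test uses the max-type statistic
#' `T_HD = max_j |mean_a_j - mean_b_j| / se_j` over the p seconds, with its
#' null distribution calibrated by resampling: by default random permutations
#' of group labels (exact under exchangeability), alternatively a Gaussian
#' multiplier bootstrap of the group-centered data.
#'
#' The screening pipeline also uses this test with the inequality reversed: a
#' LARGE p-value (> 0.9) is read as evidence that two replicates are highly
#' similar. That reading needs a well-calibrated null, which is why the
#' exactly-calibrated permutation scheme is the default.
#'
#' @param a,b numeric matrices with equal column dimension, >= 2 rows each.
#' @param n_boot number of resamples (>= 200; default 1000).
#' @param seed mandatory RNG seed; results are bit-for-bit reproducible.
#' @param calibration `"permutation"` (default) or `"multiplier"`.
#' @return a `vmr_test` with statistic `T_HD`, the resampling p-value
#'   `(1 + #{T* >= T}) / (n_boot + 1)`, sample sizes and dimension.
#' @examples
#' set.seed(2)
#' hd_two_sample_test(matrix(rnorm(720), 24), matrix(rnorm(720), 24), seed = 7)
#' @export
hd_two_sample_test <- function(a, b, n_boot = 1000L, seed,
                               calibration = c("permutation", "multiplier")) {
  calibration <- match.arg(calibration)
  w <- .as_window_pair(a, b)
  n1 <- nrow(w$a); n2 <- nrow(w$b); n <- n1 + n2
  if (n1 < 2L || n2 < 2L) .stop_fmt("need at least 2 larvae per group")
  if (!.is_count(n_boot) || n_boot < 200L) .stop_fmt("`n_boot` must be >= 200")
  if (missing(seed)) .stop_fmt("`seed` is mandatory")
  n_boot <- as.integer(n_boot)
  Z <- rbind(w$a, w$b); Z2 <- Z^2
  S0 <- matrix(c(rep(1, n1), rep(0, n2)), n, 1)
  T0 <- max(.hd_stat_matrix(Z, Z2, S0, n1, n2))
  Tb <- .with_seed(seed, {
    if (calibration == "permutation") {
      S <- vapply(seq_len(n_boot), function(i) {
        s <- numeric(n); s[sample.int(n, n1)] <- 1; s
      }, numeric(n))
      apply(.hd_stat_matrix(Z, Z2, S, n1, n2), 2, max)
    } else {
      mx <- colMeans(w$a); my <- colMeans(w$b)
      v1 <- .colVars(w$a); v2 <- .colVars(w$b)
      se <- sqrt(v1 / n1 + v2 / n2)
      Xc <- sweep(w$a, 2, mx); Yc <- sweep(w$b, 2, my)
      G1 <- matrix(stats::rnorm(n1 * n_boot), n1, n_boot)
      G2 <- matrix(stats::rnorm(n2 * n_boot), n2, n_boot)
      D <- crossprod(Xc, G1) / sqrt(n1 * (n1 - 1)) -
        crossprod(Yc, G2) / sqrt(n2 * (n2 - 1))
      apply(abs(D / se), 2, max)
    }
  })
  pval <- (1 + sum(Tb >= T0)) / (n_boot + 1)
  .vmr_test(statistic = c(T_HD = T0),
            p.value = pval,
            method = sprintf("High-dimensional two-sample max test (%s, B = %d)",
                             calibration, n_boot),
            data.name = sprintf("%d vs %d larvae, p = %d s", n1, n2, ncol(w$a)),
            extra = list(n1 = n1, n2 = n2, p_dim = ncol(w$a),
                         n_boot = n_boot, seed = as.integer(seed),
                         calibration = calibration))
}

.colVars <- function(m) {
  mu <- colMeans(m)
  (colSums(m^2) - nrow(m) * mu^2) / (nrow(m) - 1)
}

#' Welch's two-sample t-test
#'
#' @param a,b numeric vectors, n >= 2 each.
#' @return a `vmr_test` with the Welch statistic, Satterthwaite df and
#'   two-sided p-value.
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) .stop_fmt("need n >= 2 per group")
  ht <- tryCatch(stats::t.test(a, b, var.equal = FALSE),
                 error = function(e)
                   .stop_fmt("Welch statistic undefined: %s", conditionMessage(e)))
  .vmr_test(statistic = c(t = unname(ht$statistic)),
            parameter = c(df = unname(ht$parameter)),
            p.value = ht$p.value,
            method = "Welch two-sample t-test",
            data.name = sprintf("n1 = %d, n2 = %d", length(a), length(b)),
            extra = list(n1 = length(a), n2 = length(b)))
}

#' Pearson chi-square test on a 2x2 table, without continuity correction
#'
#' Used for the rod-phenotype contingency tables (Strong/Intermediate/Weak
#' collapsed to the two observed categories, df = 1).
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return a `vmr_test` with the chi-square statistic, df = 1 and p-value.
#' @examples
#' pearson_chi2_2x2(rbind(c(9, 15), c(16, 8)))   # X-squared = 4.09
#' @export
pearson_chi2_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!identical(dim(tab), c(2L, 2L))) .stop_fmt("`table` must be 2x2")
  if (any(!is.finite(tab)) || any(tab < 0) || any(tab != round(tab)))
    .stop_fmt("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    .stop_fmt("degenerate table: a row or column margin is zero")
  ht <- stats::chisq.test(tab, correct = FALSE)
  .vmr_test(statistic = c(`X-squared` = unname(ht$statistic)),
            parameter = c(df = unname(ht$parameter)),
            p.value = ht$p.value,
            method = "Pearson chi-square test (no continuity correction)",
            data.name = "2x2 contingency table",
            extra = list(observed = tab))
}

#' One-way ANOVA with FDR-corrected pairwise t-tests
#'
#' The omnibus test is a standard one-way ANOVA; post hoc, every pair of
#' groups is compared with a pooled-variance two-sample t-test and the raw
#' p-values are adjusted by the Benjamini-Hochberg step-up procedure.
#'
#' @param values numeric vector of observations, or a named list of group
#'   vectors (in which case `groups` is ignored).
#' @param groups group labels parallel to `values`.
#' @return list with `anova` (a `vmr_test`) and `pairwise` (data.frame with
#'   group pair, t statistic, df, raw and BH-adjusted p-values).
#' @export
anova_pairwise_fdr <- function(values, groups = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    if (is.null(names(values)) || any(!nzchar(names(values))))
      .stop_fmt("group list must be named")
    groups <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  values <- as.numeric(values)
  g <- factor(groups)
  if (length(values) != length(g)) .stop_fmt("`values` and `groups` lengths differ")
  sizes <- table(g)
  if (nlevels(g) < 2L) .stop_fmt("need at least 2 groups")
  if (any(sizes < 2L))
    .stop_fmt("every group needs n >= 2 (group %s has %d)",
              names(sizes)[which(sizes < 2)[1]], min(sizes))
  if (stats::var(values) == 0)
    .stop_fmt("all observations identical: ANOVA F is undefined")
  fit <- stats::lm(values ~ g)
  an <- stats::anova(fit)
  anova_res <- .vmr_test(
    statistic = c(F = an$`F value`[1]),
    parameter = c(df1 = an$Df[1], df2 = an$Df[2]),
    p.value = an$`Pr(>F)`[1],
    method = "One-way ANOVA",
    data.name = sprintf("%d groups, N = %d", nlevels(g), length(values)),
    extra = list(group_sizes = as.integer(sizes)))
  pairs <- utils::combn(levels(g), 2)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   t = NA_real_, df = NA_real_, p_raw = NA_real_,
                   stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    ht <- stats::t.test(values[g == pairs[1, i]], values[g == pairs[2, i]],
                        var.equal = TRUE)
    pw$t[i] <- unname(ht$statistic)
    pw$df[i] <- unname(ht$parameter)
    pw$p_raw[i] <- ht$p.value
  }
  pw$p_adj <- stats::p.adjust(pw$p_raw, method = "BH")
  list(anova = anova_res, pairwise = pw)
}
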