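test_that("paired t and dz recompute the printed table rows", {
  for (nm in names(printed_paired_rows)) {
    r <- printed_paired_rows[[nm]]
    iv <- rounding_intervals(r[1], r[2], 9)
    # the printed statistics lie inside the rounding interval ...
    expect_gte(r[3], iv$t[1])
    expect_lte(r[3], iv$t[2])
    expect_gte(r[4], iv$dz[1])
    expect_lte(r[4], iv$dz[2])
    # ... and so do the recomputed ones
    res <- paired_t(sample_with_moments(r[1], r[2], 9))
    expect_gte(res$statistic, iv$t[1])
    expect_lte(res$statistic, iv$t[2])
    expect_gte(res$effect_size, iv$dz[1])
    expect_lte(res$effect_size, iv$dz[2])
    expect_equal(res$df, 8)
  }
})

test_that("paired t handles degenerate and symmetric inputs", {
  expect_error(paired_t(rep(2, 5)), "variance")
  res <- paired_t(c(1.5, -1.5, 0.7, -0.7, 2.2, -2.2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  # sign flip
  d <- c(0.3, -0.1, 0.8, 0.2, -0.4)
  expect_equal(paired_t(d)$statistic, -paired_t(-d)$statistic)
})

test_that("dz is scale invariant and zero-centred at zero mean", {
  d <- c(0.2, 0.5, -0.1, 0.9)
  expect_equal(cohens_d_paired(d * 7), cohens_d_paired(d))
  expect_equal(cohens_d_paired(c(-1, 1, -2, 2)), 0)
})

test_that("two-sample t reproduces the printed baseline comparison", {
  # printed pre-treatment B2/3 descriptives: 0.435 (0.359, n=9) vs
  # 0.664 (0.244, n=10); pooled t printed as -1.639
  a <- sample_with_moments(0.435, 0.359, 9)
  b <- sample_with_moments(0.664, 0.244, 10)
  res <- two_sample_t(a, b)
  corners <- expand.grid(m1 = 0.435 + c(-5e-4, 5e-4),
                         s1 = 0.359 + c(-5e-4, 5e-4),
                         m2 = 0.664 + c(-5e-4, 5e-4),
                         s2 = 0.244 + c(-5e-4, 5e-4))
  ts <- with(corners, {
    sp <- sqrt((8 * s1^2 + 9 * s2^2) / 17)
    (m1 - m2) / (sp * sqrt(1 / 9 + 1 / 10))
  })
  expect_gte(-1.639, min(ts))
  expect_lte(-1.639, max(ts))
  expect_gte(res$statistic, min(ts))
  expect_lte(res$statistic, max(ts))
  expect_equal(res$df, 17)
})

test_that("two-sample t vanishes for identical groups; d matches brute force", {
  x <- c(1, 2, 3, 4)
  expect_equal(two_sample_t(x, x)$statistic, 0)
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(11, 0.5)
    sp <- sqrt((7 * var(a) + 10 * var(b)) / 17)
    expect_equal(two_sample_t(a, b)$effect_size, (mean(a) - mean(b)) / sp)
  }
})

test_that("minimal detectable effects are monotone and vanish near alpha", {
  m1 <- mde_t("two_sample", n1 = 9, n2 = 10)
  m2 <- mde_t("two_sample", n1 = 18, n2 = 20)
  expect_gt(m1, m2)                       # decreasing in n
  expect_gt(mde_t("paired", n = 18, power = 0.9),
            mde_t("paired", n = 18, power = 0.8))
  expect_gt(mde_t("paired", n = 18, alpha = 0.01),
            mde_t("paired", n = 18, alpha = 0.05))
  near <- sapply(c(0.3, 0.1, 0.06), function(p)
    mde_t("paired", n = 18, power = p))
  expect_true(all(diff(near) < 0))
  expect_lt(near[3], 0.2)
  expect_error(mde_t("paired", n = 1), "pairs")
})

test_that("equivalence verdicts follow the SESOI rule", {
  set.seed(5)
  x <- rnorm(500)
  expect_true(equivalence_check(x, x + rnorm(500, 0, 1e-3), 1.366)$equivalent)
  # the study's verdict for mean vigilance: CI (-0.16, 1.72) vs SESOI 1.366
  expect_false(equivalence_verdict(c(-0.16, 1.72), 1.366))
  # monotone in sesoi
  ci <- c(-0.4, 0.9)
  verdicts <- sapply(c(0.5, 0.95, 1.5, 3), equivalence_verdict, ci = ci)
  expect_true(all(diff(verdicts) >= 0))
  expect_error(equivalence_check(rep(1, 5), rep(2, 5), 1), "variance")
})

test_that("the noncentral-t pivot CI agrees with a bootstrap oracle", {
  set.seed(42)
  a <- rnorm(30, 0.4)
  b <- rnorm(30)
  eq <- equivalence_check(a, b, 1.366)
  dfun <- function(x, y) {
    sp <- sqrt((var(x) * (length(x) - 1) + var(y) * (length(y) - 1)) /
                 (length(x) + length(y) - 2))
    (mean(x) - mean(y)) / sp
  }
  B <- 1e5
  ds <- vapply(seq_len(B), function(i)
    dfun(sample(a, 30, TRUE), sample(b, 30, TRUE)), 0)
  boot_ci <- unname(stats::quantile(ds, c(0.025, 0.975)))
  expect_lt(max(abs(eq$ci - boot_ci)), 0.05)
})

test_that("mixed ANOVA matches a cell-means computation on a toy design", {
  set.seed(8)
  n <- 4
  d <- expand.grid(id = sprintf("s%d", 1:(2 * n)), time = c("pre", "post"))
  d$group <- ifelse(as.integer(sub("s", "", d$id)) <= n, "G1", "G2")
  d$y <- rnorm(nrow(d)) + ifelse(d$time == "post", 0.5, 0) +
    ifelse(d$group == "G1" & d$time == "post", 0.8, 0)
  res <- mixed_anova_2x2(d, "y")

  # independent split-plot sums of squares from cell means
  y <- d$y
  grand <- mean(y)
  sub_means <- tapply(y, d$id, mean)
  t_means <- tapply(y, d$time, mean)
  cell <- tapply(y, list(d$group, d$time), mean)
  g_means <- tapply(y, d$group, mean)
  ss_time <- 2 * n * sum((t_means - grand)^2)
  ss_int <- n * sum((sweep(sweep(cell, 1, g_means), 2, t_means) + grand)^2)
  resid <- y - sub_means[as.character(d$id)] -
    cell[cbind(d$group, as.character(d$time))] +
    g_means[d$group]
  ss_err <- sum(resid^2)
  df_err <- (2 * n - 2) * 1
  expect_equal(res$time$statistic, (ss_time / 1) / (ss_err / df_err),
               tolerance = 1e-10)
  expect_equal(res$time_group$statistic, (ss_int / 1) / (ss_err / df_err),
               tolerance = 1e-10)
  expect_equal(res$time$df, c(1, df_err))
})

test_that("mixed ANOVA degenerates correctly", {
  set.seed(9)
  d <- expand.grid(id = sprintf("s%d", 1:8), time = c("pre", "post"))
  d$group <- rep(c("G1", "G2"), each = 4)
  idx <- as.integer(sub("s", "", d$id))
  base <- rnorm(8)
  # noise with zero mean in every group x time cell: keeps the error
  # stratum positive while the targeted effects stay exactly null
  e <- matrix(rnorm(8), 4, 2)
  e <- sweep(e, 2, colMeans(e))
  cell_noise <- rbind(e, e)[cbind(idx, as.integer(d$time))]
  # post = pre for everyone (plus cell-centred noise) -> no time effect
  d$y <- base[idx] + cell_noise
  res <- mixed_anova_2x2(d, "y")
  expect_lt(res$time$statistic, 1e-10)
  # both groups shift by the same constant -> no interaction
  d$y <- base[idx] + ifelse(d$time == "post", 1.7, 0) + cell_noise
  res2 <- mixed_anova_2x2(d, "y")
  expect_lt(res2$time_group$statistic, 1e-10)
  # missing cell errors with the participant named
  expect_error(mixed_anova_2x2(d[-1, ], "y"), "s1")
})

test_that("wilcoxon matches exact enumeration for n = 8", {
  enum_p <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vs <- signs %*% r
    p_le <- mean(vs <= v_obs)
    p_ge <- mean(vs >= v_obs)
    min(1, 2 * min(p_le, p_ge))
  }
  set.seed(13)
  for (i in 1:10) {
    d <- round(rnorm(8), 3)
    while (any(duplicated(abs(d))) || any(d == 0)) d <- round(rnorm(8), 3)
    expect_equal(wilcoxon_signed_rank(d, method = "exact")$p.value,
                 enum_p(d), tolerance = 1e-12)
  }
  # all-positive differences: the smallest attainable two-tailed p
  res <- wilcoxon_signed_rank(1:10, method = "exact")
  expect_equal(res$p.value, 2 / 2^10, tolerance = 1e-12)
})

test_that("wilcoxon normal approximation is symmetric and bounded", {
  d <- c(1.2, -1.2, 0.6, -0.6, 2.1, -2.1, 0.3, -0.3)
  res <- wilcoxon_signed_rank(d)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)
  expect_equal(res$effect_size, 0)
})

test_that("chi-square matches the direct formula and its edge cases", {
  # independence: table proportional to its margins
  tab <- outer(c(10, 20), c(6, 9, 15)) / 5
  expect_equal(chi_square_crosstab(round(tab))$statistic, 0,
               tolerance = 1e-10)
  res <- chi_square_crosstab(matrix(c(10, 0, 0, 10), 2))
  expect_equal(res$effect_size, 1)
  set.seed(17)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 8) + 1, 2, 3)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(chi_square_crosstab(tab)$statistic,
                 sum((tab - E)^2 / E), tolerance = 1e-12)
    expect_equal(chi_square_crosstab(tab)$df, 2)
  }
})

test_that("pearson correlation behaves canonically", {
  x <- 1:20
  expect_equal(pearson_r(x, x)$effect_size, 1)
  expect_equal(pearson_r(x, x)$df, 18)
  set.seed(23)
  a <- rnorm(1e4); b <- rnorm(1e4)
  expect_lt(abs(pearson_r(a, b)$effect_size), 0.05)
  # affine invariance
  y <- rnorm(20)
  expect_equal(pearson_r(x, y)$effect_size,
               pearson_r(3 * x - 5, 0.5 * y + 2)$effect_size)
})
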