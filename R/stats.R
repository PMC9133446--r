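# Statistical battery of the pre/post two-group design: paired and
# two-sample t-tests with Cohen's d, exact noncentral-t minimal detectable
# effect sizes, equivalence against a SESOI via the noncentral-t pivot,
# 2x2 mixed ANOVA, Wilcoxon signed-rank, chi-square crosstabs and Pearson
# correlations. Base R provides the distributions and the classical
# tests; the noncentral-t root-finding, pivot CIs and effect-size
# attachments are implemented here.

new_test_result <- function(method, statistic, df, p, effect, effect_type,
                            ci = NULL, extra = list()) {
  structure(c(list(method = method, statistic = statistic, df = df,
                   p.value = p, effect_size = effect,
                   effect_type = effect_type, ci = ci), extra),
            class = "vig_test")
}

#' @export
print.vig_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3f, df = %s, p = %.3f, %s = %.3f\n",
              x$method, x$statistic, paste(round(x$df, 2), collapse = ", "),
              x$p.value, x$effect_type, x$effect_size))
  if (!is.null(x$ci))
    cat(sprintf("  95%% CI [%.3f, %.3f]\n", x$ci[1], x$ci[2]))
  invisible(x)
}

#' Paired t-test on pre-post differences
#'
#' Classical paired t-test on per-participant differences with the paired
#' effect size dz = mean(diff) / sd(diff) attached.
#'
#' @param differences per-participant difference values (pre - post).
#' @return a `vig_test` with t, df = n-1, two-tailed p, dz, and the 95%
#'   CI of the mean difference.
#' @export
paired_t <- function(differences) {
  differences <- differences[!is.na(differences)]
  n <- length(differences)
  if (n < 2) stop("need at least 2 non-missing pairs")
  if (stats::sd(differences) == 0)
    stop("zero variance in differences: t undefined")
  ht <- stats::t.test(differences)
  new_test_result("paired t", unname(ht$statistic), unname(ht$parameter),
                  ht$p.value, cohens_d_paired(differences), "dz",
                  ci = unname(ht$conf.int),
                  extra = list(mean = mean(differences),
                               sd = stats::sd(differences), n = n))
}

#' Paired effect size dz
#'
#' Cohen's dz for paired designs: mean of the differences divided by
#' their standard deviation. Invariant under positive rescaling of the
#' measurement unit.
#'
#' @param differences per-participant difference values.
#' @return dz.
#' @export
cohens_d_paired <- function(differences) {
  differences <- differences[!is.na(differences)]
  if (length(differences) < 2) stop("need at least 2 pairs")
  s <- stats::sd(differences)
  if (s == 0) stop("zero variance in differences: dz undefined")
  mean(differences) / s
}

# pooled-SD Cohen's d for two independent groups
cohens_d_pooled <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
               (n1 + n2 - 2))
  (mean(a) - mean(b)) / sp
}

#' Two-sample t-test with Cohen's d
#'
#' Pooled-variance (default) or Welch two-sample t-test, with the pooled
#' Cohen's d attached in either mode.
#'
#' @param group_a,group_b numeric vectors.
#' @param variance_mode `"pooled"` or `"unpooled"` (Welch).
#' @return a `vig_test`.
#' @export
two_sample_t <- function(group_a, group_b,
                         variance_mode = c("pooled", "unpooled")) {
  variance_mode <- match.arg(variance_mode)
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 observations")
  ht <- stats::t.test(group_a, group_b,
                      var.equal = variance_mode == "pooled")
  new_test_result(paste0("two-sample t (", variance_mode, ")"),
                  unname(ht$statistic), unname(ht$parameter), ht$p.value,
                  cohens_d_pooled(group_a, group_b), "d",
                  extra = list(n = c(length(group_a), length(group_b))))
}

# two-tailed power of a t-test at noncentrality ncp
noncentral_t_power <- function(ncp, df, alpha) {
  tc <- stats::qt(1 - alpha / 2, df)
  (1 - stats::pt(tc, df, ncp)) + stats::pt(-tc, df, ncp)
}

#' Minimal detectable effect size via the exact noncentral t
#'
#' Smallest standardized effect (Cohen's d for two-sample, dz for paired)
#' at which a two-tailed t-test of level `alpha` reaches the target
#' power, solved by root-finding on the exact noncentral-t power
#' function to a tolerance of 1e-6 in d.
#'
#' @param family `"two_sample"` or `"paired"`.
#' @param n number of pairs (paired family).
#' @param n1,n2 group sizes (two-sample family).
#' @param alpha two-tailed type-I error probability.
#' @param power target power.
#' @return the minimal detectable d (or dz).
#' @export
#' @examples
#' mde_t("two_sample", n1 = 9, n2 = 10)   # the SESOI of a 9 vs 10 design
#' mde_t("paired", n = 18)
mde_t <- function(family = c("two_sample", "paired"), n = NULL,
                  n1 = NULL, n2 = NULL, alpha = 0.05, power = 0.8) {
  family <- match.arg(family)
  if (!(alpha > 0 && alpha < 1) || !(power > 0 && power < 1))
    stop("alpha and power must lie in (0, 1)")
  if (power <= alpha)
    stop("target power must exceed alpha")
  if (family == "two_sample") {
    if (is.null(n1) || is.null(n2) || n1 < 2 || n2 < 2)
      stop("two-sample family needs n1 >= 2 and n2 >= 2")
    df <- n1 + n2 - 2
    k <- sqrt(n1 * n2 / (n1 + n2))
  } else {
    if (is.null(n) || n < 2) stop("paired family needs n >= 2 pairs")
    df <- n - 1
    k <- sqrt(n)
  }
  f <- function(d) noncentral_t_power(d * k, df, alpha) - power
  if (f(50) < 0) stop("target power unreachable at any plausible d")
  stats::uniroot(f, c(1e-8, 50), tol = 1e-6)$root
}

# 95% CI for Cohen's d via the noncentral-t pivot: the ncp values whose
# noncentral t distribution puts 2.5% beyond the observed t
noncentral_d_ci <- function(t_obs, df, k, conf = 0.95) {
  a <- (1 - conf) / 2
  lim <- max(10, abs(t_obs) * 3 + 10)
  pt_q <- function(ncp, q) suppressWarnings(stats::pt(t_obs, df, ncp)) - q
  lo <- tryCatch(
    stats::uniroot(pt_q, c(-lim, lim), q = 1 - a, tol = 1e-8)$root,
    error = function(e) -lim)
  hi <- tryCatch(
    stats::uniroot(pt_q, c(-lim, lim), q = a, tol = 1e-8)$root,
    error = function(e) lim)
  c(lo, hi) / k
}

#' Equivalence check against a smallest effect size of interest
#'
#' Computes the pooled Cohen's d for two groups with a 95% confidence
#' interval from the noncentral-t pivot and declares the groups
#' EQUIVALENT when both CI bounds lie strictly inside (-sesoi, +sesoi).
#'
#' @param group_a,group_b numeric vectors.
#' @param sesoi the equivalence bound on Cohen's d.
#' @param conf confidence level of the d interval.
#' @return list with `d`, `ci`, `sesoi`, `equivalent`, and the underlying
#'   t-test.
#' @export
equivalence_check <- function(group_a, group_b, sesoi, conf = 0.95) {
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0)
    stop("degenerate variance: equivalence CI undefined")
  tt <- two_sample_t(group_a, group_b, "pooled")
  n1 <- length(group_a); n2 <- length(group_b)
  k <- sqrt(n1 * n2 / (n1 + n2))
  ci <- noncentral_d_ci(tt$statistic, tt$df, k, conf)
  list(d = tt$effect_size, ci = ci, sesoi = sesoi,
       equivalent = equivalence_verdict(ci, sesoi), t_test = tt)
}

#' Equivalence verdict for a given effect-size interval
#'
#' @param ci `c(lower, upper)` bounds of the Cohen's d interval.
#' @param sesoi equivalence bound.
#' @return `TRUE` iff both bounds lie strictly inside (-sesoi, +sesoi).
#' @export
equivalence_verdict <- function(ci, sesoi) {
  ci[1] > -sesoi && ci[2] < sesoi
}

#' 2x2 mixed ANOVA (group x time)
#'
#' Repeated-measures ANOVA with one between factor (group), one within
#' factor (time, pre/post) and their interaction, fitted with the
#' classical univariate error strata. Effect sizes are reported as
#' Cohen's d via the d = 2f conversion with f^2 = F * df_num / df_den.
#'
#' @param data data frame with columns `id`, `group`, `time`, and the
#'   outcome named by `outcome`; one row per participant and timepoint.
#' @param outcome name of the outcome column.
#' @return list of `vig_test` results for `time` and `time_group`.
#' @export
mixed_anova_2x2 <- function(data, outcome) {
  need <- c("id", "group", "time", outcome)
  if (!all(need %in% names(data)))
    stop("data must contain columns: ", paste(need, collapse = ", "))
  wide <- stats::reshape(
    data[, need], direction = "wide", idvar = c("id", "group"),
    timevar = "time", v.names = outcome)
  incomplete <- wide$id[!stats::complete.cases(wide)]
  if (length(incomplete))
    stop("missing cells for participants: ",
         paste(incomplete, collapse = ", "))
  d <- data.frame(id = factor(data$id), group = factor(data$group),
                  time = factor(data$time), y = data[[outcome]])
  fit <- stats::aov(y ~ group * time + Error(id), data = d)
  within <- summary(fit)[["Error: Within"]][[1]]
  res <- list()
  for (term in c("time", "group:time")) {
    row <- trimws(rownames(within)) == term
    Fv <- within[row, "F value"]
    df1 <- within[row, "Df"]
    df2 <- within[trimws(rownames(within)) == "Residuals", "Df"]
    p <- within[row, "Pr(>F)"]
    f2 <- Fv * df1 / df2
    res[[if (term == "time") "time" else "time_group"]] <-
      new_test_result(paste("mixed ANOVA", term), Fv, c(df1, df2), p,
                      2 * sqrt(f2), "d (=2f)")
  }
  res
}

#' Wilcoxon signed-rank test
#'
#' Signed-rank test on paired differences. `method = "normal"` (default)
#' reports the continuity-corrected normal approximation Z with effect
#' size r = |Z| / sqrt(n); `method = "exact"` uses the exact signed-rank
#' distribution (no ties/zeros).
#'
#' @param differences per-participant differences.
#' @param method `"normal"` or `"exact"`.
#' @return a `vig_test` with Z (or the V statistic for exact), p and r.
#' @export
wilcoxon_signed_rank <- function(differences,
                                 method = c("normal", "exact")) {
  method <- match.arg(method)
  d <- differences[!is.na(differences) & differences != 0]
  n <- length(d)
  if (n < 1) stop("no non-zero differences")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  z_num <- V - mu
  z <- (z_num - sign(z_num) * 0.5) / sqrt(sig2)
  if (method == "exact") {
    if (any(duplicated(abs(d))))
      warning("ties present: exact p is approximate")
    p <- 2 * min(stats::psignrank(V, n),
                 1 - stats::psignrank(V - 1, n))
    p <- min(1, p)
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  new_test_result(paste("Wilcoxon signed-rank,", method), z, NA_real_, p,
                  abs(z) / sqrt(n), "r", extra = list(V = V, n = n))
}

#' Pearson chi-square test on a crosstab
#'
#' Pearson chi-square without continuity correction, with Cohen's
#' w = sqrt(chi^2 / N) attached.
#'
#' @param table matrix of non-negative counts, at least 2x2.
#' @return a `vig_test`.
#' @export
chi_square_crosstab <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("need at least a 2x2 table")
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  new_test_result("Pearson chi-square", unname(ht$statistic),
                  unname(ht$parameter), ht$p.value,
                  sqrt(unname(ht$statistic) / sum(table)), "w")
}

#' Pearson correlation test
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return a `vig_test` with r, df = n-2 and the two-tailed p from the t
#'   transform.
#' @export
pearson_r <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  ht <- stats::cor.test(x, y, method = "pearson")
  new_test_result("Pearson correlation", unname(ht$statistic),
                  unname(ht$parameter), ht$p.value,
                  unname(ht$estimate), "r", ci = unname(ht$conf.int))
}
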