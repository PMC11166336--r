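# Shared statistical kernels: Wilcoxon signed-rank with matched-pairs
# rank-biserial correlation, paired t with Cohen's d, correlations with CIs,
# and Cronbach's alpha. All tests are two-sided by default.

new_test_summary <- function(statistic, p_value, effect_size,
                             effect_ci_low, effect_ci_high, n, method) {
  structure(list(statistic = statistic, p_value = p_value,
                 effect_size = effect_size, effect_ci_low = effect_ci_low,
                 effect_ci_high = effect_ci_high, n = n, method = method),
            class = "test_summary")
}

#' @export
print.test_summary <- function(x, ...) {
  cat(x$method, "\n  statistic = ", signif(x$statistic, 6),
      ", p = ", format.pval(x$p_value, digits = 4),
      ", n = ", x$n, "\n  effect = ", round(x$effect_size, 4), sep = "")
  if (!is.na(x$effect_ci_low)) {
    cat(" [", round(x$effect_ci_low, 4), ", ", round(x$effect_ci_high, 4),
        "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Wilcoxon signed-rank test with rank-biserial effect size
#'
#' Tests whether the distribution of paired differences is centred on zero.
#' Zero differences are dropped (Wilcoxon convention); `V` is the sum of the
#' ranks of the positive differences. The p-value uses the exact signed-rank
#' null distribution when `n <= exact_threshold` and the absolute differences
#' are tie-free, otherwise a normal approximation with continuity and tie
#' correction. The effect size is the matched-pairs rank-biserial correlation
#' `r = 2V/S - 1` (S = total rank sum), with a bootstrap percentile CI.
#'
#' @param diffs Numeric vector of paired differences.
#' @param exact_threshold Largest n for which the exact distribution is used
#'   (default 25).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param n_boot Bootstrap resamples for the effect-size CI (default 2000;
#'   0 suppresses the CI).
#' @param conf_level Confidence level for the effect-size CI.
#' @param seed Optional integer seed for the bootstrap.
#' @return A `test_summary` with `statistic` = V.
#' @export
wilcoxon_signed_rank <- function(diffs, exact_threshold = 25L,
                                 alternative = c("two.sided", "greater", "less"),
                                 n_boot = 2000L, conf_level = 0.95,
                                 seed = NULL) {
  alternative <- match.arg(alternative)
  d <- diffs[!is.na(diffs)]
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L) abort("all differences are zero: signed-rank test is degenerate")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  S <- n * (n + 1) / 2
  ties <- anyDuplicated(abs(d)) > 0L

  if (n <= exact_threshold && !ties) {
    p_ge <- stats::psignrank(V - 1, n, lower.tail = FALSE)
    p_le <- stats::psignrank(V, n)
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
  } else {
    mu <- S / 2
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24
    if (ties) {
      tt <- table(r)
      sigma2 <- sigma2 - sum(tt^3 - tt) / 48
    }
    z_num <- V - mu
    cc <- switch(alternative,
                 two.sided = sign(z_num) * 0.5,
                 greater = 0.5, less = -0.5)
    z <- (z_num - cc) / sqrt(sigma2)
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = min(1, 2 * stats::pnorm(-abs(z))))
  }

  rbs <- function(x) {
    x <- x[x != 0]
    if (length(x) == 0L) return(NA_real_)
    rr <- rank(abs(x))
    2 * sum(rr[x > 0]) / (length(x) * (length(x) + 1) / 2) - 1
  }
  est <- rbs(d)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L && n >= 3L) {
    if (!is.null(seed)) set.seed(seed)
    boot <- vapply(seq_len(n_boot),
                   function(i) rbs(sample(d, n, replace = TRUE)), numeric(1))
    boot <- boot[!is.na(boot)]
    alpha <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  }
  new_test_summary(V, p, est, ci[1], ci[2], n,
                   "Wilcoxon signed-rank (matched-pairs rank-biserial r)")
}

#' Paired t-test with Cohen's d
#'
#' Cohen's d for paired data is `mean(a - b) / sd(a - b)`; its confidence
#' interval is obtained by inverting the noncentral t distribution.
#'
#' @param a,b Paired numeric vectors of equal length.
#' @param conf_level Confidence level for the d CI.
#' @return A `test_summary` with `statistic` = t (df = n - 1) and
#'   `effect_size` = d; also carries `df` and `mean_diff` attributes.
#' @export
paired_t_cohens_d <- function(a, b, conf_level = 0.95) {
  if (length(a) != length(b)) abort("a and b must have equal length")
  ok <- stats::complete.cases(a, b)
  d <- a[ok] - b[ok]
  n <- length(d)
  if (n < 2L) abort("need at least 2 complete pairs")
  if (stats::sd(d) == 0) abort("zero-variance differences: paired t undefined")
  tt <- stats::t.test(d)
  dd <- mean(d) / stats::sd(d)
  t_obs <- unname(tt$statistic)
  alpha <- (1 - conf_level) / 2
  # noncentrality bounds: ncp_lo s.t. P(T >= t_obs | ncp) = alpha, etc.
  ncp_root <- function(target) {
    f <- function(ncp) {
      suppressWarnings(stats::pt(t_obs, df = n - 1, ncp = ncp)) - target
    }
    lo <- t_obs - 10 - 10 * abs(t_obs)
    hi <- t_obs + 10 + 10 * abs(t_obs)
    stats::uniroot(f, c(lo, hi), extendInt = "yes", tol = 1e-8)$root
  }
  ci <- c(ncp_root(1 - alpha), ncp_root(alpha)) / sqrt(n)
  out <- new_test_summary(t_obs, tt$p.value, dd, ci[1], ci[2], n,
                          "Paired t-test (Cohen's d)")
  out$df <- n - 1
  out$mean_diff <- mean(d)
  out$mean_diff_ci <- unname(tt$conf.int)
  out
}

#' Correlation with confidence interval
#'
#' Pearson correlation with a Fisher-z interval, or Spearman rank correlation
#' with a bootstrap percentile interval.
#'
#' @param x,y Numeric vectors of equal length (n >= 4).
#' @param method `"pearson"` or `"spearman"`.
#' @param n_boot Bootstrap resamples for the Spearman CI (default 2000).
#' @param conf_level Confidence level.
#' @param seed Optional integer seed for the bootstrap.
#' @return A `test_summary` with `statistic` = `effect_size` = the coefficient.
#' @export
correlations <- function(x, y, method = c("pearson", "spearman"),
                         n_boot = 2000L, conf_level = 0.95, seed = NULL) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) abort("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("constant input: correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  est <- unname(ct$estimate)
  alpha <- (1 - conf_level) / 2
  if (method == "pearson") {
    z <- atanh(est)
    se <- 1 / sqrt(n - 3)
    ci <- tanh(z + c(-1, 1) * stats::qnorm(1 - alpha) * se)
  } else {
    if (!is.null(seed)) set.seed(seed)
    boot <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) == 0 || stats::sd(y[idx]) == 0) return(NA_real_)
      stats::cor(x[idx], y[idx], method = "spearman")
    }, numeric(1))
    ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  label <- if (method == "pearson") "Pearson correlation" else
    "Spearman rank correlation"
  new_test_summary(est, ct$p.value, est, ci[1], ci[2], n, label)
}

#' Cronbach's alpha with Feldt confidence interval
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance of the total)`.
#' The Feldt interval uses the F distribution with `n - 1` and
#' `(n - 1)(k - 1)` degrees of freedom.
#'
#' @param items Numeric matrix or data.frame, rows = respondents, columns =
#'   items (already reverse-scored where applicable).
#' @param conf_level Confidence level.
#' @return List with `alpha`, `ci_low`, `ci_high`, `k`, `n`.
#' @export
cronbach_alpha <- function(items, conf_level = 0.95) {
  items <- as.matrix(items)
  items <- items[stats::complete.cases(items), , drop = FALSE]
  k <- ncol(items)
  n <- nrow(items)
  if (k < 2L) abort("need at least 2 items")
  if (n < 3L) abort("need at least 3 respondents")
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) {
    return(list(alpha = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                k = k, n = n))
  }
  alpha <- k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
  a2 <- (1 - conf_level) / 2
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  ci_low <- 1 - (1 - alpha) * stats::qf(1 - a2, df1, df2)
  ci_high <- 1 - (1 - alpha) * stats::qf(a2, df1, df2)
  list(alpha = alpha, ci_low = ci_low, ci_high = ci_high, k = k, n = n)
}
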