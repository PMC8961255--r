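#' Upper-sided pooled-variance two-sample t-test
#'
#' Tests `H0: mu_x = mu_y` against `H1: mu_x > mu_y` with the classical
#' equal-variance two-sample t statistic and `n_x + n_y - 2` degrees of
#' freedom.  The null is rejected when `p < alpha` (strict).
#'
#' @param x,y Numeric samples, each of size at least 2.
#' @param alpha Significance level, default 0.05.
#' @return An object of class `"npi_test"`: list with `statistic`, `p.value`,
#'   `reject`, `alpha`, `alternative` (`"greater"`), `method`, `df`.
#' @examples
#' t_test_upper(c(5, 6, 7), c(1, 2, 3))
#' @export
t_test_upper <- function(x, y, alpha = 0.05) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2, is.numeric(x), is.numeric(y))
  .check_alpha(alpha)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  delta <- mean(x) - mean(y)
  if (sp2 == 0) {
    if (delta == 0) stop("zero pooled variance with equal means: t statistic undefined")
    tstat <- sign(delta) * Inf
  } else {
    tstat <- delta / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  p <- pt(tstat, df = n1 + n2 - 2, lower.tail = FALSE)
  .new_test(tstat, p, alpha, df = n1 + n2 - 2,
            method = "upper-sided pooled-variance two-sample t-test")
}

#' Upper-sided Wilcoxon-Mann-Whitney test
#'
#' Rank-sum test of the alternative that the first group is stochastically
#' larger.  The p-value is exact (via the null distribution of the
#' Mann-Whitney U statistic) when the pooled sample is tie-free and
#' `n_x + n_y <= 20`; otherwise a normal approximation with continuity and
#' tie correction is used.
#'
#' @inheritParams t_test_upper
#' @return An object of class `"npi_test"`; `statistic` is the Mann-Whitney
#'   U count for the first group.
#' @examples
#' wmt_upper(c(4, 5, 6), c(1, 2, 3))  # exact p = 1/20
#' @export
wmt_upper <- function(x, y, alpha = 0.05) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1, n2 >= 1, is.numeric(x), is.numeric(y))
  .check_alpha(alpha)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (!ties && n1 + n2 <= 20) {
    p <- pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    method <- "upper-sided Wilcoxon-Mann-Whitney test (exact)"
  } else {
    p <- .wmt_normal_p(U, n1, n2, pooled)
    method <- "upper-sided Wilcoxon-Mann-Whitney test (normal approximation)"
  }
  .new_test(U, p, alpha, df = NA_real_, method = method)
}

# Normal approximation with continuity correction and tie correction,
# matching the classical large-sample treatment.
.wmt_normal_p <- function(U, n1, n2, pooled) {
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tab <- table(pooled)
  tiecorr <- sum(tab^3 - tab) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * (n + 1 - tiecorr)
  if (sigma2 <= 0) return(0.5)
  pnorm((U - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
}

.check_alpha <- function(alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
}

.new_test <- function(statistic, p, alpha, df, method) {
  structure(list(statistic = statistic, p.value = p, reject = p < alpha,
                 alpha = alpha, alternative = "greater", df = df,
                 method = method),
            class = "npi_test")
}

#' @export
print.npi_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("statistic = %g, p-value = %g, alpha = %g -> %s\n",
              x$statistic, x$p.value, x$alpha,
              if (x$reject) "reject H0" else "do not reject H0"))
  invisible(x)
}

#' Effect size and Cohen's d with averaged-variance pooled sd
#'
#' The effect size is the difference of sample means, `mean(x) - mean(y)`.
#' Cohen's d standardises it by the pooled sample standard deviation taken as
#' `sqrt((s_x^2 + s_y^2) / 2)` — the average of the two group variances
#' (appropriate when group sizes are equal or nearly so), with `n - 1`
#' denominators.
#'
#' @inheritParams t_test_upper
#' @return List with `effect_size`, `cohens_d` and `pooled_sd`.
#' @examples
#' effect_stats(c(5, 6, 7), c(1, 2, 3))
#' @export
effect_stats <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  es <- mean(x) - mean(y)
  s <- sqrt((var(x) + var(y)) / 2)
  if (s == 0) stop("both samples are constant: Cohen's d undefined")
  list(effect_size = es, cohens_d = es / s, pooled_sd = s)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (monotone-enforced,
#' capped at 1), order-preserving with the input positions.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p_values) {
  stopifnot(is.numeric(p_values), length(p_values) >= 1)
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

# ---- vectorised p-values over bootstrap replicates (rows) ------------------

# Upper-tail pooled-t p-value per row pair of X (N x n1) and Y (N x n2).
.t_p_rows <- function(X, Y) {
  n1 <- ncol(X); n2 <- ncol(Y)
  mx <- rowMeans(X); my <- rowMeans(Y)
  ssx <- rowSums(X * X) - n1 * mx^2
  ssy <- rowSums(Y * Y) - n2 * my^2
  sp2 <- (ssx + ssy) / (n1 + n2 - 2)
  tt <- (mx - my) / sqrt(sp2 * (1 / n1 + 1 / n2))
  pt(tt, df = n1 + n2 - 2, lower.tail = FALSE)
}

# Upper-tail WMT p-value per row pair; rows from NPI-B are almost surely
# tie-free so the exact/approximate rule matches wmt_upper().
.wmt_p_rows <- function(X, Y) {
  n1 <- ncol(X); n2 <- ncol(Y)
  U <- cpp_mwu_rows(X, Y)
  if (n1 + n2 <= 20) {
    pwilcox(U - 1, n1, n2, lower.tail = FALSE)
  } else {
    mu <- n1 * n2 / 2
    sigma <- sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
    pnorm((U - mu - 0.5) / sigma, lower.tail = FALSE)
  }
}

.p_rows_fun <- function(test) {
  switch(test, t = .t_p_rows, wmt = .wmt_p_rows,
         stop("unknown test: ", test))
}

.test_fun <- function(test) {
  switch(test, t = t_test_upper, wmt = wmt_upper,
         stop("unknown test: ", test))
}
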