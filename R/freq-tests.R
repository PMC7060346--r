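#' Container for a single test result
#'
#' One row in the style of a results-table cell: estimate, test statistic,
#' degrees of freedom, two-tailed p, 95% CI where defined, Bayes factor,
#' and the effective n the test used.
#'
#' @param estimate Point estimate (mean difference, r, or R^2).
#' @param statistic Test statistic (t, W, F, ...).
#' @param df Degrees of freedom (string for F: "k,n-k-1").
#' @param p Two-tailed p value.
#' @param ci_low,ci_high 95% CI bounds (NA when undefined).
#' @param bf10 Bayes factor H1 vs H0 (NA if not computed).
#' @param n Effective sample size.
#' @param method Label for the test.
#' @return One-row data frame of class `stat_result`.
#' @export
stat_result <- function(estimate, statistic, df, p,
                        ci_low = NA_real_, ci_high = NA_real_,
                        bf10 = NA_real_, n = NA_integer_, method = "") {
  out <- data.frame(method = method, estimate = estimate,
                    statistic = statistic, df = as.character(df), p = p,
                    ci_low = ci_low, ci_high = ci_high, bf10 = bf10, n = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("stat_result", "data.frame")
  out
}

#' Paired t-test with 95% CI and default Bayes factor
#'
#' @param x,y Paired numeric vectors.
#' @param prior_scale Cauchy prior scale for the Bayes factor.
#' @return [stat_result()] row; estimate is the mean difference x - y.
#' @export
paired_t <- function(x, y, prior_scale = sqrt(2) / 2) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_invalid("need at least 3 complete pairs")
  d <- x - y
  if (stats::sd(d) == 0) stop_invalid("zero variance in differences: degenerate test")
  tt <- stats::t.test(x, y, paired = TRUE)
  stat_result(estimate = unname(tt$estimate), statistic = unname(tt$statistic),
              df = unname(tt$parameter), p = tt$p.value,
              ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
              bf10 = bf_ttest(t = unname(tt$statistic), n = n,
                              scale = prior_scale),
              n = n, method = "paired t")
}

#' Wilcoxon signed-rank test
#'
#' Signed-rank statistic W (sum of positive ranks), ties mid-ranked and
#' zero differences dropped; exact p for n <= 25 with no ties, otherwise
#' the normal approximation with tie correction. A z-approximation is
#' reported alongside W in all cases.
#'
#' @param x,y Paired numeric vectors.
#' @return [stat_result()] row; `statistic` is W, the estimate is the
#'   median difference, and an extra column `z` carries the normal deviate.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  d <- (x - y)[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n < 5L) stop_invalid("need at least 5 non-zero differences")
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  exact <- n <= 25L && !any(duplicated(abs(d)))
  suppressWarnings(
    wt <- stats::wilcox.test(d, exact = exact, correct = !exact)
  )
  ## normal deviate with tie correction
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                sum(ties^3 - ties) / 48)
  out <- stat_result(estimate = stats::median(x - y, na.rm = TRUE),
                     statistic = W, df = NA, p = wt$p.value,
                     n = n, method = if (exact) "wilcoxon (exact)"
                                     else "wilcoxon (normal approx.)")
  out$z <- (W - mu) / sig
  out
}

#' Pearson correlation with default Bayes factor
#'
#' Pairwise deletion of missing values; the effective n is reported and
#' used for both the t-transform p value and the Bayes factor.
#'
#' @param x,y Numeric vectors.
#' @param prior_width Stretched-beta prior width for the Bayes factor.
#' @return [stat_result()] row; estimate is r, statistic the t transform.
#' @export
pearson_test <- function(x, y, prior_width = 1) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_invalid("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_invalid("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y)
  r <- unname(ct$estimate)
  stat_result(estimate = r, statistic = unname(ct$statistic),
              df = n - 2, p = ct$p.value,
              ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
              bf10 = if (abs(r) < 1 - 1e-8)
                bf_pearson(r = r, n = n, width = prior_width)
              else Inf,
              n = n, method = "pearson")
}

#' Simultaneous-entry ("Enter") multiple regression
#'
#' All predictors entered at once; reports the omnibus F against the
#' intercept-only model, R^2, and the default Bayes factor of the full
#' model against the null.
#'
#' @param y Response vector.
#' @param X Data frame or matrix of predictors (columns named).
#' @param prior_scale Mixture-of-g prior scale for the Bayes factor.
#' @return [stat_result()] row; estimate is R^2, statistic is F,
#'   df is "k,n-k-1".
#' @export
ols_enter <- function(y, X, prior_scale = sqrt(2) / 4) {
  X <- as.data.frame(X)
  ok <- stats::complete.cases(y, X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y)
  k <- ncol(X)
  if (n <= k + 1) stop_invalid("need n > k + 1")
  if (qr(cbind(1, as.matrix(X)))$rank < k + 1)
    stop_invalid("rank-deficient design matrix")
  fit <- stats::lm(y ~ ., data = X)
  sm <- summary(fit)
  r2 <- sm$r.squared
  f <- unname(sm$fstatistic[1])
  p <- stats::pf(f, k, n - k - 1, lower.tail = FALSE)
  stat_result(estimate = r2, statistic = f,
              df = paste0(k, ",", n - k - 1), p = p,
              bf10 = bf_regression(n = n, k = k, r2 = r2,
                                   scale = prior_scale),
              n = n, method = "ols (enter)")
}

#' Correlation matrix with per-cell Bayes factors
#'
#' All requested row-column pairs as two-tailed Pearson correlations with
#' pairwise deletion; no multiple-comparison correction is applied. Cells
#' with fewer than 3 complete pairs are returned as missing.
#'
#' @param data Data frame.
#' @param rows,cols Character vectors of column names to correlate.
#' @param prior_width Stretched-beta prior width for the Bayes factors.
#' @return Long-format data frame: `row`, `col`, `r`, `p`, `bf10`, `n`.
#' @export
correlation_matrix <- function(data, rows, cols, prior_width = 1) {
  stopifnot(all(c(rows, cols) %in% names(data)))
  grid <- expand.grid(row = rows, col = cols, stringsAsFactors = FALSE)
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    x <- data[[grid$row[i]]]
    y <- data[[grid$col[i]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3L ||
        stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(data.frame(row = grid$row[i], col = grid$col[i],
                        r = NA_real_, p = NA_real_, bf10 = NA_real_,
                        n = sum(ok)))
    res <- pearson_test(x, y, prior_width = prior_width)
    data.frame(row = grid$row[i], col = grid$col[i],
               r = res$estimate, p = res$p, bf10 = res$bf10, n = res$n)
  })
  out <- do.call(rbind, cells)
  rownames(out) <- NULL
  out
}
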