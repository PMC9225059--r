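#' Dichotomize paired measurements into a 2x2 table
#'
#' Both coordinates of each pair are classified as positive when strictly
#' greater than `cutoff` (ties at the cutoff go negative). The first
#' coordinate plays the role of the test, the second the outcome.
#'
#' @param x,y paired numeric vectors (e.g. forecast and observed
#'   concentrations), equal length, non-empty.
#' @param cutoff dichotomization threshold (default 5 µg/mL).
#' @return An object of class `"two_by_two"`: a 2x2 integer matrix with
#'   cells a (test+/outcome+), b (test+/outcome-), c (test-/outcome+),
#'   d (test-/outcome-).
#' @export
table_from_threshold <- function(x, y, cutoff = 5) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || length(x) != length(y))
    stop("x and y must be non-empty vectors of equal length")
  two_by_two(a = sum(x > cutoff & y > cutoff),
             b = sum(x > cutoff & y <= cutoff),
             c = sum(x <= cutoff & y > cutoff),
             d = sum(x <= cutoff & y <= cutoff))
}

#' @rdname table_from_threshold
#' @param a,b,c,d non-negative cell counts.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  if (sum(cells) < 1) stop("the 2x2 table must contain at least one count")
  m <- matrix(as.integer(cells), 2, 2, byrow = TRUE,
              dimnames = list(test = c("positive", "negative"),
                              outcome = c("positive", "negative")))
  structure(m, class = c("two_by_two", "matrix"))
}

tab_cells <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  c(a = t[1, 1], b = t[1, 2], c = t[2, 1], d = t[2, 2])
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' `kappa = (po - pe) / (1 - pe)` with observed agreement
#' `po = (a + d) / N` and chance agreement
#' `pe = ((a+b)(a+c) + (c+d)(b+d)) / N^2`, with the large-sample standard
#' error `sqrt(po (1 - po)) / ((1 - pe) sqrt(N))`. Degenerate margins
#' (`pe = 1`) return kappa 0 with a warning.
#'
#' @param t a [two_by_two] table.
#' @return List with `kappa` and `se`.
#' @export
cohens_kappa <- function(t) {
  k <- tab_cells(t)
  n <- sum(k)
  po <- (k[["a"]] + k[["d"]]) / n
  pe <- ((k[["a"]] + k[["b"]]) * (k[["a"]] + k[["c"]]) +
           (k[["c"]] + k[["d"]]) * (k[["b"]] + k[["d"]])) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    warning("degenerate margins (chance agreement = 1); kappa defined as 0")
    return(list(kappa = 0, se = NA_real_))
  }
  list(kappa = (po - pe) / (1 - pe),
       se = sqrt(po * (1 - po) / n) / (1 - pe))
}

#' Diagnostic statistics of a 2x2 table
#'
#' Sensitivity `a/(a+c)`, specificity `d/(b+d)`, likelihood ratios
#' `LR+ = sens/(1-spec)` and `LR- = (1-sens)/spec`, the diagnostic odds
#' ratio `ad/bc` with a Woolf (log-normal) 95% confidence interval. When
#' any cell is zero the Haldane-Anscombe correction (add 0.5 to every cell)
#' is applied to the odds ratio and its interval, and flagged.
#'
#' @param t a [two_by_two] table.
#' @return List with `sens`, `spec`, `lr_pos`, `lr_neg`, `or`, `or_ci95`
#'   and `corrected`.
#' @export
diagnostic_stats <- function(t) {
  k <- tab_cells(t)
  if (sum(k) < 1 || all(k == 0)) stop("empty 2x2 table")
  sens <- k[["a"]] / (k[["a"]] + k[["c"]])
  spec <- k[["d"]] / (k[["b"]] + k[["d"]])
  corrected <- any(k == 0)
  kk <- if (corrected) k + 0.5 else k
  or <- (kk[["a"]] * kk[["d"]]) / (kk[["b"]] * kk[["c"]])
  se_log <- sqrt(sum(1 / kk))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se_log)
  list(sens = sens, spec = spec,
       lr_pos = sens / (1 - spec), lr_neg = (1 - sens) / spec,
       or = or, or_ci95 = ci, corrected = corrected)
}

#' Deming errors-in-variables regression
#'
#' Method-comparison regression allowing measurement error on both axes,
#' with error-variance ratio `lambda` (default 1: both axes measured by the
#' same assay). The slope is
#' `(s_yy - lambda s_xx + sqrt((s_yy - lambda s_xx)^2 + 4 lambda s_xy^2)) /
#' (2 s_xy)`; the intercept passes through the means. The 95% slope
#' confidence interval is by leave-one-out jackknife; `r_squared` is the
#' squared Pearson correlation of the pairs.
#'
#' @param x,y paired measurements (>= 3 pairs, non-degenerate).
#' @param lambda ratio of y- to x-error variances (> 0).
#' @return Object of class `"deming_fit"` with `slope`, `intercept`,
#'   `r_squared`, `slope_ci95`, `slope_se`, `lambda`, `n`.
#' @export
deming_fit <- function(x, y, lambda = 1) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 3) stop("Deming regression needs at least 3 pairs")
  if (lambda <= 0) stop("lambda must be positive")
  slope_fun <- function(x, y) {
    sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
    if (sxx <= 0) stop("variance of x must be positive")
    if (abs(sxy) < .Machine$double.eps)
      stop("x and y are uncorrelated; Deming slope orientation undefined")
    d <- syy - lambda * sxx
    (d + sqrt(d * d + 4 * lambda * sxy * sxy)) / (2 * sxy)
  }
  slope <- slope_fun(x, y)
  intercept <- mean(y) - slope * mean(x)
  loo <- vapply(seq_len(n), function(i) slope_fun(x[-i], y[-i]), 0)
  ps <- n * slope - (n - 1) * loo  # pseudo-values
  se <- stats::sd(ps) / sqrt(n)
  ci <- slope + c(-1, 1) * stats::qt(0.975, n - 1) * se
  structure(list(slope = slope, intercept = intercept,
                 r_squared = stats::cor(x, y)^2,
                 slope_ci95 = ci, slope_se = se, lambda = lambda, n = n),
            class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf(
    "Deming regression (lambda = %g, n = %d):\n  slope %.3f (95%% CI %.3f to %.3f), intercept %.3f, R2 %.3f\n",
    x$lambda, x$n, x$slope, x$slope_ci95[1], x$slope_ci95[2], x$intercept,
    x$r_squared))
  invisible(x)
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC via the Mann-Whitney statistic (ties between a positive and a
#' negative score receive half credit), equal to the probability that a
#' random positive scores higher than a random negative. The 95% CI uses
#' DeLong's placement-value variance estimator, truncated to [0, 1].
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary outcome (logical, or coercible 0/1); both classes
#'   must be present.
#' @return List with `auc`, `se`, `ci95`.
#' @export
roc_auc <- function(scores, labels) {
  scores <- as.numeric(scores)
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop("scores and labels must be complete vectors of equal length")
  pos <- scores[labels]
  neg <- scores[!labels]
  n1 <- length(pos); n0 <- length(neg)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  # placement values: V10[i] = P-hat(pos_i > random negative)
  v10 <- vapply(pos, function(s) (sum(s > neg) + 0.5 * sum(s == neg)) / n0, 0)
  v01 <- vapply(neg, function(s) (sum(pos > s) + 0.5 * sum(pos == s)) / n1, 0)
  auc <- mean(v10)
  var_auc <- (if (n1 > 1) stats::var(v10) / n1 else 0) +
    (if (n0 > 1) stats::var(v01) / n0 else 0)
  se <- sqrt(var_auc)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * stats::qnorm(0.975) * se))
  list(auc = auc, se = se, ci95 = ci)
}
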