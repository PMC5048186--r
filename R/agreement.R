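#' Bland-Altman limits of agreement
#'
#' Absolute agreement between two paired measurement series: the mean and
#' sample SD of the differences `x - y`, limits of agreement at mean
#' difference +/- 1.96 SD, the percentage of pairs outside those limits, and
#' a proportional-bias test (OLS slope of the difference on the pairwise
#' mean, with its two-sided p-value — the "P for trend").
#'
#' @param x,y paired measurements (equal length, at least 3 pairs).
#' @param loa_z multiplier for the limits (1.96 for ~95%).
#' @return List of class `"bland_altman"`: `mean_difference`,
#'   `sd_difference`, `loa_lower`, `loa_upper`, `pct_outside_loa`,
#'   `trend_slope`, `trend_p`, `n`, plus the `differences` and `means`.
#' @examples
#' ba <- bland_altman(rnorm(50, 10), rnorm(50, 12))
#' ba$loa_lower; ba$loa_upper
#' @export
bland_altman <- function(x, y, loa_z = 1.96) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  stopifnot(length(x) >= 3L)
  d <- x - y
  m <- (x + y) / 2
  md <- mean(d)
  sdd <- stats::sd(d)
  lo <- md - loa_z * sdd
  hi <- md + loa_z * sdd
  if (stats::var(m) > 0 && sdd > 0) {
    fit <- summary(stats::lm(d ~ m))$coefficients
    slope <- fit["m", "Estimate"]; p <- fit["m", "Pr(>|t|)"]
  } else {
    slope <- 0; p <- NA_real_
  }
  structure(list(mean_difference = md, sd_difference = sdd,
                 loa_lower = lo, loa_upper = hi,
                 pct_outside_loa = 100 * mean(d < lo | d > hi),
                 trend_slope = slope, trend_p = p,
                 n = length(d), differences = d, means = m, loa_z = loa_z),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  mean difference %.3f (sd %.3f)\n",
              x$mean_difference, x$sd_difference))
  cat(sprintf("  limits of agreement (%.2f, %.2f); %.1f%% outside\n",
              x$loa_lower, x$loa_upper, x$pct_outside_loa))
  cat(sprintf("  trend: slope %.4f, P = %s\n", x$trend_slope,
              format.pval(x$trend_p, digits = 3)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, xlab = "Mean of methods",
                              ylab = "Difference between methods", ...) {
  graphics::plot(x$means, x$differences, pch = 16, col = "grey30",
                 xlab = xlab, ylab = ylab, ...)
  graphics::abline(h = x$mean_difference, lwd = 2)
  graphics::abline(h = c(x$loa_lower, x$loa_upper), lty = 2)
  invisible(x)
}

#' Calibration slope of measured expenditure on reported intake
#'
#' OLS regression of measured TEE on reported EI; the slope (the calibration
#' coefficient) carries a 95% CI from its standard error and the t-quantile
#' at n - 2 degrees of freedom. A slope of 1 with a tight CI would indicate
#' that reported intake tracks expenditure one-to-one.
#'
#' @param ei reported energy intake, MJ/d.
#' @param tee measured energy expenditure, MJ/d.
#' @param level confidence level.
#' @return List: `slope`, `ci_lower`, `ci_upper`, `intercept`, `n`.
#' @export
calibration_slope <- function(ei, tee, level = 0.95) {
  if (length(ei) != length(tee)) stop("ei and tee must be paired",
                                      call. = FALSE)
  stopifnot(length(ei) >= 3L)
  if (stats::var(ei) == 0)
    stop("reported EI has zero variance: slope undefined", call. = FALSE)
  fit <- stats::lm(tee ~ ei)
  # suppressWarnings: summary.lm warns on numerically perfect fits
  ci <- suppressWarnings(stats::confint(fit, "ei", level = level))
  list(slope = unname(stats::coef(fit)["ei"]),
       ci_lower = ci[1], ci_upper = ci[2],
       intercept = unname(stats::coef(fit)[1]),
       n = length(ei))
}

#' Paired comparison of two instruments by the Wilcoxon signed-rank test
#'
#' Wraps [stats::wilcox.test()] with `paired = TRUE`: exact distribution for
#' 25 or fewer non-zero differences without ties, normal approximation with
#' continuity and tie correction otherwise. Zero differences are dropped
#' before ranking (their count is reported); when every difference is zero
#' the result is flagged degenerate rather than tested.
#'
#' @param x,y paired measurement vectors.
#' @return List: `statistic` (V), `p_value`, `n_zero` (dropped zero
#'   differences), `degenerate`.
#' @export
paired_compare <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  d <- x - y
  n_zero <- sum(d == 0)
  if (all(d == 0))
    return(list(statistic = NA_real_, p_value = NA_real_,
                n_zero = n_zero, degenerate = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_zero = n_zero, degenerate = FALSE)
}

#' Correlation between instruments or against a reference
#'
#' Crude associations between absolute intakes use Spearman rank correlation
#' (midranks for ties); associations between energy-adjusted, transformed
#' intakes use Pearson correlation.
#'
#' @param x,y paired values (length at least 3, non-zero variance).
#' @param mode `"crude_spearman"` or `"adjusted_pearson"`.
#' @return List: `estimate`, `p_value`, `method`, `n`.
#' @export
correlate <- function(x, y, mode = c("crude_spearman", "adjusted_pearson")) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  stopifnot(length(x) >= 3L)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  method <- if (mode == "crude_spearman") "spearman" else "pearson"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       method = method, n = length(x))
}

#' Assign subjects to sample-quantile bins
#'
#' Splits a variable at its sample quantiles `1/k, ..., (k-1)/k`
#' (interpolation type 7). Intervals are right-closed, so values tied with an
#' interior boundary fall in the lower bin.
#'
#' @param values numeric vector, length at least `k`.
#' @param k number of bins (3 for tertiles, 4 for quartiles).
#' @return Integer bin labels in `1..k`. When boundaries collapse (heavy
#'   ties), fewer distinct bins are produced and a warning is given.
#' @examples
#' quantile_bins(1:9, 3)
#' @export
quantile_bins <- function(values, k) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  stopifnot(length(values) >= k)
  br <- stats::quantile(values, probs = seq(0, 1, length.out = k + 1),
                        type = 7, names = FALSE)
  if (anyDuplicated(br)) {
    warning("degenerate bins: tied quantile boundaries collapse categories")
    br <- unique(br)
    if (length(br) < 2L) return(rep(1L, length(values)))
  }
  .bincode(values, br, right = TRUE, include.lowest = TRUE)
}

#' Cross-classify two ordinal binnings of the same subjects
#'
#' Builds the k x k contingency table of paired bin labels and summarises
#' ranking agreement: the percentage classified in the same bin, in adjacent
#' bins (labels differing by one), in intermediate bins, and in the extreme
#' opposite corners (1 vs k), together with Cohen's weighted kappa.
#'
#' @param bins_a,bins_b integer bin labels from [quantile_bins()] with the
#'   same `k`.
#' @param k number of categories (defaults to the largest label observed).
#' @param scheme kappa weight scheme, `"linear"` (default) or `"quadratic"`.
#' @return List of class `"cross_class"`: `table`, `pct_same`,
#'   `pct_adjacent`, `pct_intermediate`, `pct_opposite`, `kappa_weighted`,
#'   `weight_scheme`, `n`.
#' @export
cross_classify <- function(bins_a, bins_b, k = max(bins_a, bins_b),
                           scheme = c("linear", "quadratic")) {
  scheme <- match.arg(scheme)
  if (length(bins_a) != length(bins_b))
    stop("bin vectors must be paired", call. = FALSE)
  if (max(bins_a) > k || max(bins_b) > k)
    stop("bin labels exceed k", call. = FALSE)
  fa <- factor(bins_a, levels = seq_len(k))
  fb <- factor(bins_b, levels = seq_len(k))
  tab <- table(fa, fb)
  n <- length(bins_a)
  dist <- abs(outer(seq_len(k), seq_len(k), "-"))
  pct <- function(sel) 100 * sum(tab[sel]) / n
  opposite <- matrix(FALSE, k, k)
  opposite[1, k] <- opposite[k, 1] <- TRUE
  structure(list(table = tab,
                 pct_same = pct(dist == 0),
                 pct_adjacent = pct(dist == 1),
                 pct_intermediate = pct(dist > 1 & !opposite),
                 pct_opposite = pct(opposite),
                 kappa_weighted = weighted_kappa(tab, scheme),
                 weight_scheme = scheme,
                 n = n),
            class = "cross_class")
}

#' @export
print.cross_class <- function(x, ...) {
  k <- nrow(x$table)
  cat(sprintf("Cross-classification (%d x %d, n = %d)\n", k, k, x$n))
  cat(sprintf("  same %.1f%%, adjacent %.1f%%, opposite %.1f%%\n",
              x$pct_same, x$pct_adjacent, x$pct_opposite))
  cat(sprintf("  weighted kappa (%s weights) = %.2f\n",
              x$weight_scheme, x$kappa_weighted))
  invisible(x)
}

#' Cohen's weighted kappa for an ordinal contingency table
#'
#' Chance-corrected agreement with distance-dependent disagreement weights:
#' \deqn{\kappa_w = 1 - \frac{\sum w_{ij} p_{obs,ij}}
#'                           {\sum w_{ij} p_{exp,ij}}}
#' with `w_ij = |i-j|/(k-1)` (linear) or `((i-j)/(k-1))^2` (quadratic) and
#' expected proportions from the margin products.
#'
#' @param table square matrix of non-negative counts.
#' @param scheme `"linear"` (default) or `"quadratic"`.
#' @return The weighted kappa (at most 1; 1 for a purely diagonal table).
#' @examples
#' weighted_kappa(diag(c(5, 8, 7)))
#' @export
weighted_kappa <- function(table, scheme = c("linear", "quadratic")) {
  scheme <- match.arg(scheme)
  table <- as.matrix(unclass(table))
  k <- nrow(table)
  stopifnot(ncol(table) == k, all(table >= 0))
  total <- sum(table)
  if (total == 0) stop("empty table", call. = FALSE)
  p <- table / total
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  w <- if (scheme == "linear") d else d^2
  p_exp <- outer(rowSums(p), colSums(p))
  expected_disagreement <- sum(w * p_exp)
  if (expected_disagreement == 0) return(1)
  1 - sum(w * p) / expected_disagreement
}
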