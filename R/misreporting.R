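#' Goldberg/Black confidence limits for the EI:TEE ratio
#'
#' Under complete, unbiased reporting the ratio of reported energy intake
#' (EI) to measured total energy expenditure (TEE) is expected to be 1 in
#' weight-stable adults. The 95% confidence limits around 1 account for
#' within-subject variation in both quantities:
#' \deqn{1 \mp z \sqrt{CV_{EI}^2 / d + CV_{TEE}^2} / 100}
#' where the CVs are in percent and `d` is the number of recording days. For
#' a food-frequency instrument `d` is taken as infinite, so only the TEE term
#' remains. With the defaults (CV_TEE 8.4%, CV_EI 20.6%, z = 2) the limits
#' round to (0.73, 1.27) at d = 4 and (0.83, 1.17) at d = Inf.
#'
#' @param cv_tee within-subject CV of TEE, percent.
#' @param cv_ei within-subject CV of reported energy intake, percent.
#' @param d number of recording days; `Inf` for frequency instruments.
#' @param z limit multiplier (2 for ~95% limits).
#' @return List of class `"goldberg_limits"`: `lower`, `upper` (unrounded),
#'   `lower_rounded`, `upper_rounded` (2 decimals), and the parameters.
#' @examples
#' goldberg_limits(d = 4)    # food record
#' goldberg_limits(d = Inf)  # FFQ
#' @export
goldberg_limits <- function(cv_tee = 8.4, cv_ei = 20.6, d = 4, z = 2) {
  if (cv_tee < 0 || cv_ei < 0) stop("CVs must be non-negative", call. = FALSE)
  if (!is.infinite(d) && (d < 1 || d != round(d)))
    stop("d must be a positive whole number of days or Inf", call. = FALSE)
  if (z <= 0) stop("z must be positive", call. = FALSE)
  ei_term <- if (is.infinite(d)) 0 else cv_ei^2 / d
  half_width <- z * sqrt(ei_term + cv_tee^2) / 100
  structure(list(lower = 1 - half_width,
                 upper = 1 + half_width,
                 lower_rounded = round(1 - half_width, 2),
                 upper_rounded = round(1 + half_width, 2),
                 cv_tee = cv_tee, cv_ei = cv_ei, d = d, z = z),
            class = "goldberg_limits")
}

#' @export
print.goldberg_limits <- function(x, ...) {
  cat(sprintf(paste0("Goldberg cut-offs for EI:TEE ",
                     "(CV_TEE %.1f%%, CV_EI %.1f%%, d = %s, z = %g):\n"),
              x$cv_tee, x$cv_ei,
              if (is.infinite(x$d)) "Inf" else format(x$d), x$z))
  cat(sprintf("  under-reporting  < %.2f   over-reporting > %.2f\n",
              x$lower_rounded, x$upper_rounded))
  cat(sprintf("  (unrounded %.6f, %.6f)\n", x$lower, x$upper))
  invisible(x)
}

#' Classify reporters against Goldberg cut-offs
#'
#' Computes the EI:TEE ratio per subject and classifies each as an
#' under-reporter (ratio strictly below the lower limit), over-reporter
#' (strictly above the upper limit) or plausible reporter. A ratio exactly
#' equal to a limit counts as plausible. By default the comparison uses the
#' 2-decimal rounded limits, matching how printed thresholds such as
#' "EI:TEE < 0.73" are applied.
#'
#' @param ei reported energy intake, MJ/d (positive).
#' @param tee measured energy expenditure, MJ/d (positive), recycled if
#'   scalar.
#' @param limits a [goldberg_limits()] object, or a numeric `c(lower, upper)`.
#' @param use_rounded logical; compare against the rounded limits (default)
#'   or the unrounded ones.
#' @return Data frame with columns `ratio` and `status` (factor with levels
#'   `under`, `plausible`, `over`).
#' @examples
#' classify_reporter(c(7, 10, 13), 10, goldberg_limits(d = 4))
#' @export
classify_reporter <- function(ei, tee, limits = goldberg_limits(),
                              use_rounded = TRUE) {
  if (any(ei <= 0) || any(tee <= 0))
    stop("ei and tee must be positive", call. = FALSE)
  if (inherits(limits, "goldberg_limits")) {
    lo <- if (use_rounded) limits$lower_rounded else limits$lower
    hi <- if (use_rounded) limits$upper_rounded else limits$upper
  } else {
    stopifnot(length(limits) == 2L, limits[1] <= limits[2])
    lo <- limits[1]; hi <- limits[2]
  }
  ratio <- ei / tee
  status <- factor(ifelse(ratio < lo, "under",
                          ifelse(ratio > hi, "over", "plausible")),
                   levels = c("under", "plausible", "over"))
  data.frame(ratio = ratio, status = status)
}

#' Reporting accuracy as a percentage of measured expenditure
#'
#' `100 * EI / TEE` per subject; the summary across a cohort is its mean and
#' sample (n-1) standard deviation.
#'
#' @inheritParams classify_reporter
#' @param summarise if `TRUE`, return `c(mean, sd, n)` across subjects
#'   instead of the per-subject vector.
#' @return Numeric vector of percentages, or a named summary vector.
#' @examples
#' reporting_accuracy(8, 10)
#' reporting_accuracy(c(6, 10), 10, summarise = TRUE)
#' @export
reporting_accuracy <- function(ei, tee, summarise = FALSE) {
  if (any(tee <= 0)) stop("tee must be positive", call. = FALSE)
  acc <- 100 * ei / tee
  if (!summarise) return(acc)
  c(mean = mean(acc), sd = stats::sd(acc), n = length(acc))
}
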