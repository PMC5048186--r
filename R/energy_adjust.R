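#' Residual-model energy adjustment
#'
#' Regresses a nutrient on total energy intake by ordinary least squares and
#' replaces each value with its residual plus the predicted value at the
#' cohort mean energy. The adjusted series is uncorrelated with energy (to
#' numerical precision) while keeping the original units and mean level.
#'
#' @param nutrient per-subject nutrient amounts (already transformed if a
#'   transformation is in use).
#' @param energy per-subject energy intakes, MJ/d; must vary.
#' @return Numeric vector of adjusted values, with attributes `slope` and
#'   `intercept` (the fitted audit coefficients) and `mean_energy`.
#' @examples
#' adj <- residual_adjust(c(10, 20, 30, 40), c(5, 6, 7, 8))
#' cor(adj, c(5, 6, 7, 8))  # ~0
#' @export
residual_adjust <- function(nutrient, energy) {
  stopifnot(length(nutrient) == length(energy), length(energy) >= 3L)
  if (stats::var(energy) == 0)
    stop("energy has zero variance: cannot energy-adjust", call. = FALSE)
  fit <- stats::lm(nutrient ~ energy)
  b <- unname(stats::coef(fit))
  adj <- unname(stats::residuals(fit)) + (b[1] + b[2] * mean(energy))
  attr(adj, "slope") <- b[2]
  attr(adj, "intercept") <- b[1]
  attr(adj, "mean_energy") <- mean(energy)
  adj
}

#' Energy density adjustment
#'
#' Expresses a nutrient per unit of energy (unit/MJ).
#'
#' @inheritParams residual_adjust
#' @return Numeric vector `nutrient / energy`.
#' @export
energy_density <- function(nutrient, energy) {
  stopifnot(length(nutrient) == length(energy))
  if (any(energy <= 0))
    stop("energy must be positive for density adjustment", call. = FALSE)
  nutrient / energy
}

#' Choose between log and square-root transformation
#'
#' Dietary intake variables are right-skewed; before correlation and
#' agreement analyses they are transformed. This rule picks, per variable,
#' whichever of `log` and `sqrt` leaves the smaller absolute sample skewness,
#' breaking ties in favour of `log`. Variables containing zeros (alcohol,
#' typically) get half the smallest positive value added before the log.
#'
#' @param values non-negative intake values.
#' @return `"log"` or `"sqrt"` (with a warning and `"sqrt"` when skewness is
#'   undefined because all values are equal).
#' @examples
#' choose_transformation(rlnorm(200, 1, 0.8))
#' @export
choose_transformation <- function(values) {
  stopifnot(all(values >= 0))
  if (length(unique(values)) == 1L) {
    warning("all values equal: skewness undefined, defaulting to sqrt")
    return("sqrt")
  }
  sk_log <- abs(e1071::skewness(log(shift_zeros(values))))
  sk_sqrt <- abs(e1071::skewness(sqrt(values)))
  if (sk_log <= sk_sqrt) "log" else "sqrt"
}

# half-minimum shift so zero intakes survive the log
shift_zeros <- function(values) {
  if (!any(values == 0)) return(values)
  pos <- values[values > 0]
  if (!length(pos)) stop("cannot log-transform an all-zero variable",
                         call. = FALSE)
  values + min(pos) / 2
}

#' Apply a named transformation to intake values
#'
#' @param values non-negative intake values.
#' @param transformation `"log"`, `"sqrt"` or `"none"`.
#' @return Transformed numeric vector.
#' @export
apply_transformation <- function(values,
                                 transformation = c("log", "sqrt", "none")) {
  transformation <- match.arg(transformation)
  switch(transformation,
         log = log(shift_zeros(values)),
         sqrt = sqrt(values),
         none = values)
}

#' Energy-adjust a table of reported intakes
#'
#' For each nutrient column, selects a transformation with
#' [choose_transformation()] (pooled across instruments so both instruments
#' share a scale), transforms, then applies the residual model against the
#' same instrument's transformed energy — within sex strata by default, since
#' intake distributions differ by sex.
#'
#' @param intakes intake table as produced by [generate_cohort()]
#'   (`subject_id`, `instrument`, `energy`, nutrient columns).
#' @param subjects subject table carrying `id` and `sex`; required when
#'   `by_sex = TRUE`.
#' @param nutrients nutrient columns to adjust.
#' @param by_sex adjust within sex strata (default) or pooled.
#' @param method `"residual"` or `"density"`.
#' @return A long data frame: `subject_id`, `instrument`, `nutrient`,
#'   `method`, `transformation`, `value`.
#' @export
adjust_intakes <- function(intakes, subjects = NULL,
                           nutrients = c("protein", "fat", "sfa", "mufa",
                                         "pufa", "carbohydrate", "sucrose",
                                         "fibre", "alcohol"),
                           by_sex = TRUE,
                           method = c("residual", "density")) {
  method <- match.arg(method)
  if (by_sex) {
    if (is.null(subjects))
      stop("subjects table required for sex-stratified adjustment",
           call. = FALSE)
    strata <- subjects$sex[match(intakes$subject_id, subjects$id)]
  } else {
    strata <- rep("all", nrow(intakes))
  }

  out <- lapply(nutrients, function(nu) {
    trans <- if (method == "residual") choose_transformation(intakes[[nu]])
             else "none"
    rows <- lapply(split(seq_len(nrow(intakes)),
                         list(strata, intakes$instrument), drop = TRUE),
                   function(idx) {
      x <- intakes[[nu]][idx]
      e <- intakes$energy[idx]
      value <- if (method == "density") energy_density(x, e)
               else as.numeric(residual_adjust(apply_transformation(x, trans),
                                               apply_transformation(e, "log")))
      data.frame(subject_id = intakes$subject_id[idx],
                 instrument = intakes$instrument[idx],
                 nutrient = nu, method = method, transformation = trans,
                 value = value, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
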