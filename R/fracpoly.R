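# Fractional-polynomial basis: candidate enumeration and exact value /
# derivative / definite integral of curves over the basis.

#' The fixed set of candidate fractional-polynomial powers
#'
#' Power 0 denotes the natural-log term `ln(age)`.
#'
#' @return Numeric vector `c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)`.
#' @export
fp_power_set <- function() c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' Enumerate candidate fractional-polynomial power sets
#'
#' All subsets of the 8 candidate powers with cardinality (model degree)
#' between `min_degree` and `max_degree`, without duplicated powers.
#' Canonical order: by degree, then lexicographically on the (ascending)
#' powers, so candidate indices are reproducible across runs.
#'
#' @param min_degree,max_degree Integer degree bounds, between 1 and 8.
#' @return A list of strictly increasing numeric power vectors.
#' @examples
#' length(fp_candidates())      # 219
#' length(fp_candidates(4, 4))  # 70
#' @export
fp_candidates <- function(min_degree = 3L, max_degree = 8L) {
  ps <- fp_power_set()
  if (min_degree < 1 || max_degree > length(ps) || min_degree > max_degree)
    stop("degrees must satisfy 1 <= min_degree <= max_degree <= 8")
  out <- list()
  for (m in seq(min_degree, max_degree)) {
    cmb <- utils::combn(ps, m, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

check_powers <- function(powers) {
  if (!is.numeric(powers) || anyDuplicated(powers))
    stop("powers must be distinct numeric values")
  if (!all(powers %in% fp_power_set()))
    stop("powers must be drawn from {-2, -1, -0.5, 0, 0.5, 1, 2, 3}")
  sort(powers)
}

#' Fractional-polynomial basis values
#'
#' Evaluates each basis term `age^p` (with `ln(age)` for p = 0) at the given
#' ages. Ages must be positive: negative powers and the log term are
#' undefined at 0.
#'
#' @param age Positive ages in months (vector).
#' @param powers Distinct powers from [fp_power_set()].
#' @param intercept Prepend a column of ones?
#' @return Matrix with one row per age and one column per term.
#' @export
fp_basis <- function(age, powers, intercept = TRUE) {
  if (any(!is.finite(age)) || any(age <= 0))
    stop("age must be positive (basis undefined at age <= 0)")
  B <- vapply(powers, function(p) {
    if (p == 0) log(age) else age^p
  }, numeric(length(age)))
  B <- matrix(B, nrow = length(age))
  colnames(B) <- fp_term_names(powers)
  if (intercept) B <- cbind(`(Intercept)` = 1, B)
  B
}

fp_term_names <- function(powers) {
  vapply(powers, function(p) {
    if (p == 0) "log(age)" else sprintf("age^%g", p)
  }, character(1))
}

#' Construct a fractional-polynomial BMI curve
#'
#' A curve is an intercept plus coefficients aligned to a power set:
#' `BMI(age) = b0 + sum_j b_j age^{p_j}` with the p = 0 term read as
#' `b_j ln(age)`.
#'
#' @param powers Distinct powers from [fp_power_set()].
#' @param coefficients Numeric vector of length `length(powers) + 1`,
#'   intercept first, then coefficients in ascending-power order.
#' @param sex Optional label ("male"/"female").
#' @param child_id Optional identifier for individual-specific curves.
#' @param residual_variance Optional per-child residual BMI variance
#'   (kg/m^2)^2 attached by the model-fitting stage.
#' @return An object of class `fp_curve`.
#' @export
fp_curve <- function(powers, coefficients, sex = NULL, child_id = NULL,
                     residual_variance = NULL) {
  powers <- check_powers(powers)
  if (length(coefficients) != length(powers) + 1L)
    stop("need length(powers) + 1 coefficients (intercept first)")
  structure(list(powers = powers,
                 coefficients = as.numeric(coefficients),
                 sex = sex, child_id = child_id,
                 residual_variance = residual_variance),
            class = "fp_curve")
}

#' @export
print.fp_curve <- function(x, digits = 4, ...) {
  terms <- c("1", fp_term_names(x$powers))
  co <- signif(x$coefficients, digits)
  rhs <- paste0(ifelse(co < 0, " - ", " + "), abs(co), "*", terms)
  rhs[1] <- as.character(co[1])
  cat("Fractional-polynomial BMI curve",
      if (!is.null(x$sex)) paste0(" (", x$sex, ")"), "\n", sep = "")
  cat("  BMI =", paste(rhs, collapse = ""), "\n")
  if (!is.null(x$child_id))
    cat("  child:", x$child_id,
        if (!is.null(x$residual_variance))
          sprintf(" (residual BMI variance %.3f)", x$residual_variance),
        "\n")
  invisible(x)
}

#' Evaluate a fractional-polynomial curve
#'
#' @param curve An [fp_curve()].
#' @param age Positive ages in months.
#' @return BMI values (kg/m^2).
#' @export
fp_value <- function(curve, age) {
  drop(fp_basis(age, curve$powers) %*% curve$coefficients)
}

#' First derivative of a fractional-polynomial curve
#'
#' `d/dage [b_j age^{p_j}] = b_j p_j age^{p_j - 1}`; the log term contributes
#' `b_log / age`; the intercept contributes 0.
#'
#' @inheritParams fp_value
#' @return BMI velocity (kg/m^2 per month).
#' @export
fp_deriv <- function(curve, age) {
  if (any(!is.finite(age)) || any(age <= 0)) stop("age must be positive")
  p <- curve$powers
  b <- curve$coefficients[-1]
  D <- vapply(seq_along(p), function(j) {
    if (p[j] == 0) b[j] / age else b[j] * p[j] * age^(p[j] - 1)
  }, numeric(length(age)))
  rowSums(matrix(D, nrow = length(age)))
}

#' Definite integral of a fractional-polynomial curve
#'
#' Closed-form antiderivative: `x^{p+1}/(p+1)` for p not in \{-1, 0\},
#' `ln x` for p = -1, `x ln x - x` for the log term, and `b0 x` for the
#' intercept; evaluated at `upper` minus at `lower`.
#'
#' @inheritParams fp_value
#' @param lower,upper Integration bounds in months, `0 < lower <= upper`.
#' @return Area under the curve (kg/m^2 months).
#' @export
fp_integral <- function(curve, lower, upper) {
  if (any(lower <= 0) || any(upper < lower))
    stop("need 0 < lower <= upper")
  anti <- function(x) {
    p <- curve$powers
    b <- curve$coefficients[-1]
    terms <- vapply(seq_along(p), function(j) {
      if (p[j] == -1) b[j] * log(x)
      else if (p[j] == 0) b[j] * (x * log(x) - x)
      else b[j] * x^(p[j] + 1) / (p[j] + 1)
    }, numeric(length(x)))
    curve$coefficients[1] * x + rowSums(matrix(terms, nrow = length(x)))
  }
  anti(upper) - anti(lower)
}

#' @export
predict.fp_curve <- function(object, age, deriv = 0L, ...) {
  switch(as.character(deriv),
         "0" = fp_value(object, age),
         "1" = fp_deriv(object, age),
         stop("only deriv = 0 or 1 supported"))
}

#' @export
plot.fp_curve <- function(x, from = 0.225, to = 216, n = 500, ...) {
  age <- exp(seq(log(from), log(to), length.out = n))
  plot(age, fp_value(x, age), type = "l",
       xlab = "Age (months)", ylab = "BMI (kg/m^2)", ...)
  invisible(x)
}

#' Bundled population-average BMI curves
#'
#' Sex-specific 5th-degree fractional-polynomial population-average BMI
#' curves (powers -2, -1, -0.5, log, 0.5) estimated from a large US
#' well-child-visit cohort followed from 1 week to 18 years. They serve as
#' the default population curves of the synthetic-cohort simulator and as
#' deterministic worked examples for milestone detection.
#'
#' @param sex "male" or "female".
#' @return An [fp_curve()].
#' @examples
#' fp_value(fp_reference_curve("male"), 7.1)  # about 17.7 kg/m^2
#' @export
fp_reference_curve <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  co <- if (sex == "male")
    c(96.8, -3.6, 51.0, -134.9, -24.4, 4.6)
  else
    c(90.8, -3.2, 47.0, -125.4, -22.7, 4.3)
  fp_curve(c(-2, -1, -0.5, 0, 0.5), co, sex = sex)
}

#' Read/write a curve serialization record
#'
#' JSON record with fields `powers`, `coefficients`, `sex`, `child_id`,
#' `residual_variance` — the exchange format between the fitting and
#' milestone stages.
#'
#' @param curve An [fp_curve()]; `path` a file path.
#' @name fp_curve_io
#' @export
write_fp_curve <- function(curve, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for curve serialization")
  jsonlite::write_json(unclass(curve), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname fp_curve_io
#' @param path File path.
#' @export
read_fp_curve <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for curve serialization")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fp_curve(x$powers, x$coefficients, sex = x$sex,
           child_id = x$child_id, residual_variance = x$residual_variance)
}
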