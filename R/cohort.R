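# Cohort data model and preprocessing: recumbent-length correction, BMI
# computation, visit-schedule eligibility, covariate recoding, internal
# birth-weight z-scores, and delimited-text readers/writers.

MONTHS_PER_DAY <- 1 / 30.4375
MONTHS_PER_YEAR <- 12
KG_PER_LB <- 0.45359237
CM_PER_IN <- 2.54

STATURE_METHODS <- c("paper_pencil_recumbent", "standing", "unknown")
RACE_LEVELS <- c("white", "black", "other", "unknown")
INSURANCE_LEVELS <- c("medicaid", "non_medicaid", "unknown")

#' Correct a paper-and-pencil recumbent length
#'
#' Applies the validated linear correction for the paper-and-pencil
#' recumbent-length technique, which systematically overestimates length in
#' infants: corrected = 0.953 x measured + 1.8 cm. Callers apply it only to
#' measurements taken before 24 months of age (see
#' [preprocess_cohort()]); the function itself is the bare affine map.
#'
#' @param stature_cm Measured length in cm (positive).
#' @return Corrected length in cm.
#' @examples
#' correct_length(50)   # 49.45
#' @export
correct_length <- function(stature_cm) {
  if (any(!is.finite(stature_cm)) || any(stature_cm <= 0))
    stop("invalid measurement: stature must be positive")
  0.953 * stature_cm + 1.8
}

#' Compute body mass index
#'
#' @param weight_kg Weight in kilograms (positive).
#' @param stature_cm Length/height in centimeters (positive).
#' @return BMI in kg/m^2: `weight / (stature/100)^2`.
#' @export
compute_bmi <- function(weight_kg, stature_cm) {
  if (any(!is.finite(weight_kg)) || any(weight_kg <= 0))
    stop("invalid measurement: weight must be positive")
  if (any(!is.finite(stature_cm)) || any(stature_cm <= 0))
    stop("invalid measurement: stature must be positive")
  weight_kg / (stature_cm / 100)^2
}

#' The default visit-schedule eligibility rule
#'
#' Children qualify for trajectory modelling when they have enough
#' well-child visits spread over childhood: at least 2 visits in each of
#' 1 week-2.9, 3-7.4, 7.5-13.4 and 13.5-20.9 months, 1 in 21.0-29.9 months,
#' 1 in each of 2.5-3.4, 3.5-4.4, 4.5-5.4 and 5.5-6.4 years, 3 in 6.5-10.4
#' years, and 1 in each of 10.5-14.4 and 14.5-18.0 years — 18 visits
#' minimum in total. Interval bounds are in months, closed on both sides.
#'
#' @return An `eligibility_rule`: a data frame with columns `lower`,
#'   `upper`, `min_visits` and attribute `total_minimum`.
#' @export
default_eligibility_rule <- function() {
  r <- data.frame(
    lower = c(0.225, 3, 7.5, 13.5, 21, 30, 42, 54, 66, 78, 126, 174),
    upper = c(2.9, 7.4, 13.4, 20.9, 29.9, 40.8, 52.8, 64.8, 76.8,
              124.8, 172.8, 216),
    min_visits = c(2, 2, 2, 2, 1, 1, 1, 1, 1, 3, 1, 1)
  )
  eligibility_rule(r)
}

#' Build and validate an eligibility rule
#'
#' @param intervals Data frame with columns `lower`, `upper`, `min_visits`
#'   (months; closed intervals), ordered and non-overlapping.
#' @return The validated rule with class `eligibility_rule`.
#' @export
eligibility_rule <- function(intervals) {
  stopifnot(all(c("lower", "upper", "min_visits") %in% names(intervals)))
  if (any(intervals$upper < intervals$lower))
    stop("configuration error: interval upper bound below lower bound")
  if (is.unsorted(intervals$lower, strictly = TRUE))
    stop("configuration error: intervals must be ordered")
  if (nrow(intervals) > 1 &&
      any(intervals$lower[-1] <= intervals$upper[-nrow(intervals)]))
    stop("configuration error: overlapping eligibility intervals")
  structure(intervals,
            total_minimum = sum(intervals$min_visits),
            class = c("eligibility_rule", "data.frame"))
}

#' Check one child's visit ages against an eligibility rule
#'
#' A visit outside all intervals contributes to no interval.
#'
#' @param visit_ages Positive visit ages in months.
#' @param rule An [eligibility_rule()]; default [default_eligibility_rule()].
#' @return List with `eligible` (flag), `counts` (per-interval), `total`.
#' @export
check_eligibility <- function(visit_ages, rule = default_eligibility_rule()) {
  if (!inherits(rule, "eligibility_rule")) rule <- eligibility_rule(rule)
  if (any(visit_ages <= 0)) stop("visit ages must be positive")
  counts <- mapply(function(lo, hi) sum(visit_ages >= lo & visit_ages <= hi),
                   rule$lower, rule$upper)
  list(eligible = all(counts >= rule$min_visits),
       counts = as.integer(counts),
       total = as.integer(sum(counts)))
}

#' Assemble a cohort object
#'
#' @param children Data frame with columns `child_id`, `sex`
#'   ("male"/"female"), and optionally `race`, `birth_year`, `birth_weight`
#'   (grams), `insurance`.
#' @param visits Data frame with columns `child_id`, `age` (months),
#'   `weight` (kg), `stature` (cm), and optionally `stature_method`, `bmi`.
#'   Sorted by child and age; duplicate ages within a child keep the first
#'   occurrence (the rest are dropped with a warning).
#' @return A `bmi_cohort` object (list with `children` and `visits`).
#' @export
bmi_cohort <- function(children, visits) {
  stopifnot(all(c("child_id", "sex") %in% names(children)),
            all(c("child_id", "age", "weight", "stature") %in% names(visits)))
  if (!all(children$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (anyDuplicated(children$child_id))
    stop("duplicate child_id in children table")
  bad <- !(visits$child_id %in% children$child_id)
  if (any(bad)) stop("visits reference unknown child_id: ",
                     paste(head(unique(visits$child_id[bad])), collapse = ", "))
  if (any(visits$age <= 0)) stop("visit ages must be positive")
  if (any(visits$weight <= 0) || any(visits$stature <= 0))
    stop("invalid measurement: weight and stature must be positive")
  if (is.null(visits$stature_method)) visits$stature_method <- "unknown"
  if (!all(visits$stature_method %in% STATURE_METHODS))
    stop("unknown stature_method value")
  visits <- visits[order(visits$child_id, visits$age), , drop = FALSE]
  dup <- duplicated(visits[c("child_id", "age")])
  if (any(dup)) {
    warning(sum(dup), " duplicate visit age(s) dropped (first kept)")
    visits <- visits[!dup, , drop = FALSE]
  }
  rownames(visits) <- NULL
  for (col in c("race", "insurance"))
    if (!is.null(children[[col]])) {
      lv <- if (col == "race") RACE_LEVELS else INSURANCE_LEVELS
      if (!all(children[[col]] %in% lv))
        stop("unknown ", col, " value; expected one of ",
             paste(lv, collapse = ", "))
    }
  structure(list(children = children, visits = visits), class = "bmi_cohort")
}

#' @export
print.bmi_cohort <- function(x, ...) {
  ns <- table(factor(x$children$sex, c("male", "female")))
  cat("BMI cohort:", nrow(x$children), "children (",
      ns[["male"]], "boys,", ns[["female"]], "girls ),",
      nrow(x$visits), "visits\n")
  cat("  visits per child: median",
      median(table(x$visits$child_id)), "\n")
  invisible(x)
}

#' Preprocess recorded visits
#'
#' Applies the recumbent-length correction to measurements taken before 24
#' months (optionally restricted to visits flagged as paper-and-pencil
#' recumbent), then computes BMI. Corrected rows are marked in a
#' `length_corrected` column so the affine correction is never applied
#' twice.
#'
#' @param cohort A [bmi_cohort()].
#' @param use_method_flag If `TRUE`, correct only visits whose
#'   `stature_method` is `"paper_pencil_recumbent"`; by default the
#'   correction keys on age < 24 months alone.
#' @param correction_age_months Upper age bound for the correction.
#' @return The cohort with corrected `stature`, a `length_corrected`
#'   column, and a `bmi` column on every visit.
#' @export
preprocess_cohort <- function(cohort, use_method_flag = FALSE,
                              correction_age_months = 24) {
  v <- cohort$visits
  if (is.null(v$length_corrected)) v$length_corrected <- FALSE
  idx <- v$age < correction_age_months & !v$length_corrected
  if (use_method_flag) idx <- idx & v$stature_method == "paper_pencil_recumbent"
  if (any(idx)) {
    v$stature[idx] <- correct_length(v$stature[idx])
    v$length_corrected[idx] <- TRUE
  }
  v$bmi <- compute_bmi(v$weight, v$stature)
  cohort$visits <- v
  cohort
}

#' Per-child eligibility report
#'
#' @param cohort A [bmi_cohort()].
#' @param rule An [eligibility_rule()].
#' @return Data frame: `child_id`, one count column per interval,
#'   `total`, `eligible`.
#' @export
cohort_eligibility <- function(cohort, rule = default_eligibility_rule()) {
  ids <- cohort$children$child_id
  res <- lapply(ids, function(id) {
    ages <- cohort$visits$age[cohort$visits$child_id == id]
    e <- check_eligibility(ages, rule)
    c(e$counts, e$total, as.integer(e$eligible))
  })
  M <- do.call(rbind, res)
  out <- data.frame(child_id = ids, M)
  names(out) <- c("child_id",
                  sprintf("n_%g_%g", rule$lower, rule$upper),
                  "total", "eligible")
  out$eligible <- as.logical(out$eligible)
  out
}

#' Internal birth-weight z-scores
#'
#' Standardizes birth weight within sex over the supplied (analytic)
#' sample: z = (birth weight - within-sex mean) / within-sex SD. Children
#' with missing birth weight get `NA`.
#'
#' @param children Data frame with `sex` and `birth_weight` (grams).
#' @param sd_type `"sample"` (denominator n-1, default) or
#'   `"population"` (denominator n).
#' @return `children` with a `birth_weight_z` column.
#' @export
birthweight_zscores <- function(children, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  z <- rep(NA_real_, nrow(children))
  for (s in unique(children$sex)) {
    i <- children$sex == s & !is.na(children$birth_weight)
    if (sum(i) < 2) stop("need at least 2 children with known birth weight per sex")
    w <- children$birth_weight[i]
    s2 <- var(w)
    if (sd_type == "population") s2 <- s2 * (length(w) - 1) / length(w)
    if (s2 <= 0) stop("degenerate birth-weight distribution (zero variance) for sex ", s)
    z[i] <- (w - mean(w)) / sqrt(s2)
  }
  children$birth_weight_z <- z
  children
}

#' Recode birth year into the analysis categories
#'
#' @param birth_year Integer years.
#' @return Factor with levels `1979-1984`, `1985-1989`, `1990-1994`.
#' @export
birth_year_category <- function(birth_year) {
  cut(birth_year, breaks = c(1978, 1984, 1989, 1994),
      labels = c("1979-1984", "1985-1989", "1990-1994"))
}

# ---- readers / writers ------------------------------------------------------

detect_sep <- function(path) {
  l1 <- readLines(path, n = 1)
  if (grepl("\t", l1)) "\t" else ","
}

#' Read a cohort from delimited text
#'
#' Reads a visit-level table and a child-level covariate table (comma- or
#' tab-delimited, auto-detected). Ages are normalized to months according
#' to `age_unit` (1 month = 30.4375 days, 1 year = 12 months). Rows failing
#' validation (non-positive age/weight/stature) are reported with their
#' line numbers and either abort (`on_error = "fail"`) or are skipped.
#'
#' @param visits_path Path to the visit table: columns `child_id`, `age`,
#'   `weight`, `stature`, optional `stature_method`.
#' @param children_path Path to the child table: columns `child_id`, `sex`,
#'   optional `race`, `birth_year`, `birth_weight`, `insurance`.
#' @param age_unit Unit of the `age` column.
#' @param on_error Policy for invalid rows.
#' @return A [bmi_cohort()].
#' @export
read_cohort <- function(visits_path, children_path,
                        age_unit = c("months", "days", "years"),
                        on_error = c("fail", "skip")) {
  age_unit <- match.arg(age_unit)
  on_error <- match.arg(on_error)
  v <- read.csv(visits_path, sep = detect_sep(visits_path),
                stringsAsFactors = FALSE)
  ch <- read.csv(children_path, sep = detect_sep(children_path),
                 stringsAsFactors = FALSE)
  need <- c("child_id", "age", "weight", "stature")
  if (!all(need %in% names(v)))
    stop("visit table missing mandatory column(s): ",
         paste(setdiff(need, names(v)), collapse = ", "))
  if (!all(c("child_id", "sex") %in% names(ch)))
    stop("child table missing mandatory column(s)")
  v$age <- switch(age_unit,
                  months = v$age,
                  days = v$age * MONTHS_PER_DAY,
                  years = v$age * MONTHS_PER_YEAR)
  bad <- which(!is.finite(v$age) | v$age <= 0 | v$weight <= 0 | v$stature <= 0)
  if (length(bad)) {
    msg <- paste("invalid visit row(s) at line(s):",
                 paste(head(bad + 1L, 10), collapse = ", "))
    if (on_error == "fail") stop(msg) else {
      warning(msg, " (skipped)")
      v <- v[-bad, , drop = FALSE]
    }
  }
  bmi_cohort(ch, v)
}

#' Write a cohort as canonical CSV
#'
#' @param cohort A [bmi_cohort()].
#' @param visits_path,children_path Output paths.
#' @export
write_cohort <- function(cohort, visits_path, children_path) {
  write.csv(cohort$visits, visits_path, row.names = FALSE)
  write.csv(cohort$children, children_path, row.names = FALSE)
  invisible(cohort)
}
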