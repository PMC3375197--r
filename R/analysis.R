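# Downstream analysis of trajectory characteristics: pairwise Pearson
# correlations, multivariable linear regression on socio-demographic
# predictors, and descriptive summary tables.

# Canonical column order of the characteristics matrix (the 13 pairwise-
# correlated characteristics plus the period-1/3 age differences kept as a
# harmless superset).
CHARACTERISTIC_COLUMNS <- c(
  "ip_age", "ip_bmi", "change_1", "velocity_1", "auc_1",
  "ar_age", "ar_bmi", "age_diff_2", "change_2", "velocity_2", "auc_2",
  "change_3", "velocity_3", "auc_3")

#' Pairwise Pearson correlations among trajectory characteristics
#'
#' Pairwise-complete deletion by default, so children missing one
#' milestone still contribute to cells not involving it. Zero-variance
#' columns yield `NA` cells and a warning, never a silent 0.
#'
#' @param chars Characteristics data frame (see
#'   [cohort_characteristics()]).
#' @param columns Characteristic columns to correlate.
#' @param use Passed to [stats::cor()]; default
#'   `"pairwise.complete.obs"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(chars, columns = CHARACTERISTIC_COLUMNS,
                               use = "pairwise.complete.obs") {
  columns <- intersect(columns, names(chars))
  M <- as.matrix(chars[columns])
  sds <- apply(M, 2, sd, na.rm = TRUE)
  degenerate <- !is.na(sds) & sds == 0
  if (any(degenerate))
    warning("zero-variance column(s): ",
            paste(columns[degenerate], collapse = ", "),
            "; their correlations are undefined (NA)")
  R <- suppressWarnings(cor(M, use = use))
  diag(R)[!degenerate] <- 1
  diag(R)[degenerate] <- NA_real_
  R
}

#' Build the predictor frame for the regression stage
#'
#' Reference levels: male, white race, birth years 1979-1984,
#' non-Medicaid. Unknown race or insurance becomes missing, so those
#' children drop out of the complete-case regression sample.
#'
#' @param children Child-level table with `sex`, `race`, `birth_year`,
#'   `birth_weight_z`, `insurance`.
#' @return Data frame of factors/numerics keyed by `child_id`.
#' @export
predictor_frame <- function(children) {
  race <- factor(ifelse(children$race == "unknown", NA, children$race),
                 levels = c("white", "black", "other"))
  ins <- factor(ifelse(children$insurance == "unknown", NA,
                       children$insurance),
                levels = c("non_medicaid", "medicaid"))
  data.frame(child_id = children$child_id,
             sex = factor(children$sex, levels = c("male", "female")),
             race = race,
             birth_year_cat = birth_year_category(children$birth_year),
             birth_weight_z = children$birth_weight_z,
             insurance = ins,
             stringsAsFactors = FALSE)
}

#' Multivariable regressions of characteristics on predictors
#'
#' One ordinary-least-squares fit per characteristic with all predictors
#' entered jointly, restricted to the complete-case subsample (all
#' predictors non-missing). Constant or collinear predictors are dropped
#' with a warning naming them. Velocity outcomes can be rescaled (e.g.
#' `velocity_scale = 100` reports 10^-2 kg/m^2 per month).
#'
#' @param chars Characteristics data frame keyed by `child_id`.
#' @param predictors Output of [predictor_frame()].
#' @param outcomes Characteristic columns to model.
#' @param velocity_scale Multiplier applied to `velocity_*` outcomes.
#' @param conf_level Confidence level for the t-based intervals.
#' @return Data frame: `outcome`, `term`, `estimate`, `conf_low`,
#'   `conf_high`, `p_value`, `n`.
#' @export
fit_predictor_models <- function(chars, predictors,
                                 outcomes = CHARACTERISTIC_COLUMNS,
                                 velocity_scale = 1,
                                 conf_level = 0.95) {
  outcomes <- intersect(outcomes, names(chars))
  d <- merge(chars[c("child_id", outcomes)], predictors, by = "child_id")
  pred_cols <- c("sex", "race", "birth_year_cat", "birth_weight_z",
                 "insurance")
  cc <- complete.cases(d[pred_cols])
  d <- d[cc, , drop = FALSE]
  keep <- character()
  for (pc in pred_cols) {
    v <- d[[pc]]
    nu <- length(unique(v[!is.na(v)]))
    if (nu < 2) {
      warning("predictor '", pc, "' is constant in the complete-case ",
              "sample and was dropped")
    } else keep <- c(keep, pc)
  }
  if (!length(keep)) stop("no usable predictors")
  out <- lapply(outcomes, function(oc) {
    dd <- d[!is.na(d[[oc]]), c(oc, keep)]
    scale <- if (grepl("^velocity", oc)) velocity_scale else 1
    dd[[oc]] <- dd[[oc]] * scale
    if (nrow(dd) <= length(keep) + 2)
      stop("complete-case n too small for outcome ", oc)
    f <- lm(stats::reformulate(keep, response = as.name(oc)), data = dd)
    est <- coef(f)
    ci <- suppressMessages(confint(f, level = conf_level))
    pv <- summary(f)$coefficients[, 4]
    data.frame(outcome = oc, term = names(est), estimate = unname(est),
               conf_low = ci[, 1], conf_high = ci[, 2],
               p_value = unname(pv[names(est)]),
               n = nrow(dd), row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Descriptive summary of characteristics
#'
#' Per characteristic (optionally by group): n of children with the
#' characteristic defined, mean (SD), median and range — milestone-
#' dependent rows naturally show smaller n when milestones are absent.
#'
#' @param chars Characteristics data frame.
#' @param by Optional grouping vector aligned to rows (e.g. sex).
#' @param columns Characteristic columns to summarize.
#' @return Data frame: `group`, `characteristic`, `n`, `mean`, `sd`,
#'   `median`, `min`, `max`.
#' @export
summarize_characteristics <- function(chars, by = NULL,
                                      columns = CHARACTERISTIC_COLUMNS) {
  columns <- intersect(columns, names(chars))
  groups <- if (is.null(by)) list(all = seq_len(nrow(chars)))
            else split(seq_len(nrow(chars)), by)
  out <- lapply(names(groups), function(g) {
    idx <- groups[[g]]
    do.call(rbind, lapply(columns, function(cl) {
      v <- chars[[cl]][idx]
      v <- v[!is.na(v)]
      data.frame(group = g, characteristic = cl, n = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) sd(v) else NA_real_,
                 median = if (length(v)) median(v) else NA_real_,
                 min = if (length(v)) min(v) else NA_real_,
                 max = if (length(v)) max(v) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run the full trajectory pipeline on a cohort
#'
#' Convenience wrapper: preprocess, fit the given (or selected) mean model
#' per sex, predict individual curves, detect milestones and compute the
#' characteristics table.
#'
#' @param cohort A [bmi_cohort()].
#' @param powers Power set to fit (skips model selection).
#' @param covariance Residual covariance structure.
#' @param control Optimizer control passed to [fit_bmi_model()].
#' @return List with per-sex `fits`, `curves`, and the pooled
#'   characteristics data frame `chars` (with a `sex` column).
#' @export
trajectory_pipeline <- function(cohort, powers = c(-2, -1, -0.5, 0, 0.5),
                                covariance = "spatial_power",
                                control = list()) {
  cohort <- preprocess_cohort(cohort)
  sexes <- intersect(c("male", "female"), unique(cohort$children$sex))
  fits <- list(); chars <- list()
  for (s in sexes) {
    fit <- fit_bmi_model(cohort, powers, covariance = covariance,
                         sex = s, control = control)
    cv <- individual_curves(fit)
    ch <- cohort_characteristics(cv)
    ch$sex <- s
    fits[[s]] <- fit
    chars[[s]] <- ch
  }
  list(fits = fits, chars = do.call(rbind, chars))
}
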