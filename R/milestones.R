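# Grid-based detection of the infancy BMI peak and adiposity rebound on
# fitted curves, and the derived trajectory characteristics.

#' The milestone-detection age grid
#'
#' 8,632 evenly spaced "minor" age points 0.025 months (about one day)
#' apart, spanning 1 week to 18 years. One week is 7/30.4375 = 0.230
#' months, snapped down to 0.225 — the nearest grid multiple of 0.025 that
#' yields the canonical point count with the endpoint at exactly 216.0.
#'
#' @return Numeric vector of 8,632 ages: `0.225 + 0.025 * (0:8631)`.
#' @export
milestone_grid <- function() 0.225 + 0.025 * (0:8631)

#' Milestone search windows
#'
#' Infancy peak: 3-17 months. Adiposity rebound: 15 months-9.5 years
#' (114 months). Both sexes share the windows.
#'
#' @return Named list of `c(lower, upper)` in months.
#' @export
milestone_windows <- function() {
  list(infancy_peak = c(3, 17), adiposity_rebound = c(15, 114))
}

# Scan consecutive grid pairs in [win] for a derivative sign change of the
# requested orientation; returns the grid index of the milestone or NA.
scan_sign_change <- function(d, grid, win, kind) {
  idx <- which(grid >= win[1] & grid <= win[2])
  if (length(idx) < 2) return(NA_integer_)
  s <- d[idx]
  # an exact zero at a grid point is the milestone directly (limit of the
  # tie rule), but only where the derivative genuinely changes sign around
  # it — a flat stretch is not an extremum
  zero <- idx[s == 0]
  zero <- zero[zero > 1 & zero < length(grid)]
  if (length(zero)) {
    real <- if (kind == "infancy_peak")
      zero[d[zero - 1] > 0 & d[zero + 1] < 0]
    else
      zero[d[zero - 1] < 0 & d[zero + 1] > 0]
    if (length(real)) return(real[1])
  }
  hit <- if (kind == "infancy_peak")
    which(s[-length(s)] > 0 & s[-1] < 0)
  else
    which(s[-length(s)] < 0 & s[-1] > 0)
  if (!length(hit)) return(NA_integer_)
  # within each qualifying pair, the member with |derivative| closer to zero
  cand <- ifelse(abs(s[hit]) <= abs(s[hit + 1]), idx[hit], idx[hit + 1])
  if (length(cand) > 1) {
    warning("multiple ", kind, " sign changes; choosing the ",
            if (kind == "infancy_peak") "largest" else "smallest", " BMI")
  }
  cand
}

#' Detect infancy peak and adiposity rebound on a curve
#'
#' Evaluates the analytic first derivative of the curve at every grid point
#' and scans consecutive pairs within each milestone window. A milestone
#' exists where two consecutive points have opposite derivative signs
#' (+ to - for the infancy peak, - to + for the rebound); the member of the
#' pair with derivative closer to zero is the milestone age, and the BMI is
#' the curve value there. Absence of a sign change is a valid outcome, not
#' an error. If several windows qualify (wiggly high-degree curves) the
#' candidate with the largest BMI is kept for the peak and the smallest for
#' the rebound, with a warning. A rebound found at or before the detected
#' peak restarts the rebound search just after the peak.
#'
#' @param curve An [fp_curve()].
#' @param grid Ages from [milestone_grid()].
#' @param windows Search windows from [milestone_windows()].
#' @return Data frame with rows `infancy_peak`, `adiposity_rebound` and
#'   columns `kind`, `found`, `age`, `bmi`.
#' @examples
#' detect_milestones(fp_reference_curve("male"))  # peak at 7.1 months
#' @export
detect_milestones <- function(curve, grid = milestone_grid(),
                              windows = milestone_windows()) {
  d <- fp_deriv(curve, grid)
  pick <- function(kind, win) {
    cand <- scan_sign_change(d, grid, win, kind)
    cand <- cand[!is.na(cand)]
    if (!length(cand)) return(NA_integer_)
    if (length(cand) == 1) return(cand)
    v <- fp_value(curve, grid[cand])
    if (kind == "infancy_peak") cand[which.max(v)] else cand[which.min(v)]
  }
  ip <- pick("infancy_peak", windows$infancy_peak)
  arw <- windows$adiposity_rebound
  ar <- pick("adiposity_rebound", arw)
  if (!is.na(ip) && !is.na(ar) && grid[ar] <= grid[ip]) {
    arw[1] <- max(arw[1], grid[ip] + 0.025)
    ar <- pick("adiposity_rebound", arw)
  }
  row <- function(kind, i) {
    data.frame(kind = kind, found = !is.na(i),
               age = if (is.na(i)) NA_real_ else grid[i],
               bmi = if (is.na(i)) NA_real_ else fp_value(curve, grid[i]))
  }
  out <- rbind(row("infancy_peak", ip), row("adiposity_rebound", ar))
  rownames(out) <- out$kind
  out
}

#' Trajectory characteristics of one fitted curve
#'
#' Splits the trajectory into three periods — 1 week to infancy peak,
#' infancy peak to adiposity rebound, adiposity rebound to 18 years — and
#' computes, per period, the change in BMI, the age difference, the linear
#' velocity (change / age difference, kg/m^2 per month) and the area under
#' the curve (closed-form definite integral, kg/m^2 months). Endpoint BMIs
#' at 1 week (0.225 months) and 18 years (216 months) come from the fitted
#' curve. Any characteristic involving an absent milestone is `NA`.
#'
#' @param curve An [fp_curve()].
#' @param milestones Output of [detect_milestones()]; computed if omitted.
#' @param grid Ages from [milestone_grid()].
#' @return One-row data frame: milestone ages/BMIs, found flags, endpoint
#'   BMIs, and per-period `change`, `age_diff`, `velocity`, `auc`
#'   (suffixes 1-3).
#' @export
trajectory_characteristics <- function(curve, milestones = NULL,
                                       grid = milestone_grid()) {
  if (is.null(milestones)) milestones <- detect_milestones(curve, grid)
  a0 <- grid[1]; a3 <- grid[length(grid)]
  bmi0 <- fp_value(curve, a0); bmi3 <- fp_value(curve, a3)
  ip <- milestones["infancy_peak", ]; ar <- milestones["adiposity_rebound", ]
  seg <- function(alo, blo, ahi, bhi) {
    if (is.na(alo) || is.na(ahi))
      return(c(change = NA_real_, age_diff = NA_real_,
               velocity = NA_real_, auc = NA_real_))
    c(change = bhi - blo, age_diff = ahi - alo,
      velocity = (bhi - blo) / (ahi - alo),
      auc = fp_integral(curve, alo, ahi))
  }
  s1 <- seg(a0, bmi0, ip$age, ip$bmi)
  s2 <- seg(ip$age, ip$bmi, ar$age, ar$bmi)
  s3 <- seg(ar$age, ar$bmi, a3, bmi3)
  data.frame(
    child_id = if (is.null(curve$child_id)) NA_character_ else curve$child_id,
    ip_found = ip$found, ip_age = ip$age, ip_bmi = ip$bmi,
    ar_found = ar$found, ar_age = ar$age, ar_bmi = ar$bmi,
    bmi_1wk = bmi0, bmi_18y = bmi3,
    change_1 = s1[["change"]], age_diff_1 = s1[["age_diff"]],
    velocity_1 = s1[["velocity"]], auc_1 = s1[["auc"]],
    change_2 = s2[["change"]], age_diff_2 = s2[["age_diff"]],
    velocity_2 = s2[["velocity"]], auc_2 = s2[["auc"]],
    change_3 = s3[["change"]], age_diff_3 = s3[["age_diff"]],
    velocity_3 = s3[["velocity"]], auc_3 = s3[["auc"]],
    stringsAsFactors = FALSE)
}

#' Characteristics table for a list of individual curves
#'
#' @param curves List of [fp_curve()] objects (e.g. from
#'   [individual_curves()]).
#' @param grid Ages from [milestone_grid()].
#' @return Data frame, one row per curve (see
#'   [trajectory_characteristics()]).
#' @export
cohort_characteristics <- function(curves, grid = milestone_grid()) {
  out <- do.call(rbind, lapply(curves, function(cv)
    trajectory_characteristics(cv, grid = grid)))
  rownames(out) <- NULL
  out
}
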