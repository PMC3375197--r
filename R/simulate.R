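# Seeded synthetic-cohort generator emulating well-child-visit BMI data:
# sex-specific population fractional-polynomial curves, per-child random
# effects, serially correlated residuals, a pediatric visit schedule dense
# in infancy, covariates, and the measurement/rounding process.

# Synthetic stature-for-age references (cm, by sex), anchored to typical
# pediatric median values and interpolated monotonically. They exist only
# so recorded weight/stature pairs are anthropometrically plausible; BMI
# is what the analysis consumes.
stature_anchor_ages <- c(0.23, 1, 2, 4, 6, 9, 12, 18, 24, 36, 48, 60,
                         72, 96, 120, 144, 168, 192, 216)
stature_anchors <- list(
  male = c(50.0, 54.7, 58.4, 63.9, 67.6, 72.0, 75.7, 82.3, 87.1, 95.3,
           102.3, 109.2, 115.5, 127.0, 137.5, 149.0, 163.0, 173.0, 176.5),
  female = c(49.1, 53.7, 57.1, 62.1, 65.7, 70.1, 74.0, 80.7, 85.7, 94.1,
             101.6, 108.4, 115.1, 126.6, 138.3, 151.5, 160.0, 162.5, 163.5))

stature_for_age <- function(age, sex) {
  f <- splinefun(stature_anchor_ages, stature_anchors[[sex]],
                 method = "monoH.FC")
  f(pmin(pmax(age, 0.23), 216))
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults describe a well-child-visit cohort: sex-specific population
#' curves equal to the bundled population-average equations
#' ([fp_reference_curve()]); diagonal per-child random effects on every
#' basis term, with SDs calibrated so that simulated milestone spreads are
#' of the order seen in real cohorts (about 1 month SD for the
#' infancy-peak age, about 10 months for the rebound age); spatial-power
#' residual correlation; a pediatric visit schedule dense in infancy and
#' yearly later, with attendance and age jitter; covariate distributions
#' (race, birth weight 3442 (488) g, Medicaid 3.9%, birth years
#' 1979-1994); and the measurement process (weight rounded to the nearest
#' 0.25 lb, length to the nearest 0.25 in, with the paper-and-pencil
#' distortion below 24 months arranged as the exact inverse of
#' [correct_length()] so preprocessing recovers truth up to rounding).
#'
#' @param n_children Number of children.
#' @param sex_ratio Probability a child is male.
#' @param curves Named list of [fp_curve()] per sex (population curves).
#' @param re_sd Random-effect SDs aligned to (intercept, terms).
#' @param sigma Residual SD (kg/m^2).
#' @param rho Spatial-power residual correlation per month.
#' @param schedule Target visit ages in months.
#' @param jitter_sd_infancy,jitter_sd_later Gaussian age jitter SD below /
#'   above `jitter_cut` months.
#' @param jitter_cut Age splitting the two jitter regimes.
#' @param attendance Per-visit attendance probability.
#' @param race_probs Named multinomial probabilities (normalized).
#' @param birth_weight_mean,birth_weight_sd Birth weight (grams).
#' @param medicaid_prob Probability of Medicaid insurance.
#' @param birth_year_range Inclusive integer range of birth years.
#' @param bwz_effect Linear effect (kg/m^2 per SD of birth weight) of the
#'   generative birth-weight z-score on the random intercept, giving the
#'   regression stage a known signal.
#' @param height_factor_sd SD of the per-child multiplicative stature
#'   factor.
#' @param measurement_model Apply the rounding/distortion process?
#' @param seed Default seed used by [simulate_cohort()].
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_children = 500,
                          sex_ratio = 0.511,
                          curves = list(male = fp_reference_curve("male"),
                                        female = fp_reference_curve("female")),
                          re_sd = c(0.7, 0.02, 0.25, 0.60, 0.10, 0.25),
                          sigma = 0.9,
                          rho = 0.9,
                          schedule = c(0.25, 1, 2, 4, 6, 9, 12, 15, 18, 24,
                                       30, 36, seq(48, 216, by = 12)),
                          jitter_sd_infancy = 0.3,
                          jitter_sd_later = 1.5,
                          jitter_cut = 24,
                          attendance = 0.998,
                          race_probs = c(white = 0.718, black = 0.065,
                                         other = 0.051, unknown = 0.166),
                          birth_weight_mean = 3442,
                          birth_weight_sd = 488,
                          medicaid_prob = 0.039,
                          birth_year_range = c(1979, 1994),
                          bwz_effect = 0.2,
                          height_factor_sd = 0.025,
                          measurement_model = TRUE,
                          seed = 1L) {
  cfg <- list(n_children = n_children, sex_ratio = sex_ratio,
              curves = curves, re_sd = re_sd, sigma = sigma, rho = rho,
              schedule = schedule, jitter_sd_infancy = jitter_sd_infancy,
              jitter_sd_later = jitter_sd_later, jitter_cut = jitter_cut,
              attendance = attendance,
              race_probs = race_probs / sum(race_probs),
              birth_weight_mean = birth_weight_mean,
              birth_weight_sd = birth_weight_sd,
              medicaid_prob = medicaid_prob,
              birth_year_range = birth_year_range,
              bwz_effect = bwz_effect,
              height_factor_sd = height_factor_sd,
              measurement_model = measurement_model, seed = seed)
  validate_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_config <- function(cfg) {
  probs <- c(cfg$sex_ratio, cfg$attendance, cfg$medicaid_prob, cfg$race_probs)
  if (any(probs < 0 | probs > 1))
    stop("configuration error: probabilities must lie in [0, 1]")
  if (cfg$sigma < 0 || any(cfg$re_sd < 0) || cfg$birth_weight_sd < 0 ||
      cfg$height_factor_sd < 0)
    stop("configuration error: SDs must be non-negative")
  if (abs(cfg$rho) >= 1) stop("configuration error: |rho| must be < 1")
  if (cfg$n_children < 1) stop("configuration error: n_children must be >= 1")
  for (s in c("male", "female")) {
    cv <- cfg$curves[[s]]
    if (!inherits(cv, "fp_curve")) stop("curves$", s, " must be an fp_curve")
    if (length(cfg$re_sd) != length(cv$powers) + 1L)
      stop("re_sd must have one SD per basis term including the intercept")
  }
  if (!identical(cfg$curves$male$powers, cfg$curves$female$powers))
    stop("configuration error: both sexes must share one basis")
  invisible(cfg)
}

#' Simulate a synthetic well-child-visit cohort
#'
#' Per child: draw sex and covariates; draw diagonal random effects (the
#' intercept additionally shifted by `bwz_effect` times the generative
#' birth-weight z-score); the child's true curve is the population curve
#' plus these deviations. Visit ages come from the jittered schedule with
#' per-visit attendance; true BMI adds spatial-power-correlated Gaussian
#' residuals to the true curve. Recorded weight and length/height pass
#' through the measurement model ([apply_measurement_model()]) when
#' enabled. Both the recorded cohort and the truth layer (true
#' coefficients, true curve milestones, true visit BMI) are returned so
#' recovery can be tested end to end. The same seed gives bit-identical
#' output.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (defaults to `config$seed`).
#' @return A `synthetic_cohort`: list with `cohort` ([bmi_cohort()]),
#'   `truth` (list: `coefficients` matrix, `milestones` data frame,
#'   `visits` with true BMI) and `config`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  validate_config(config)
  set.seed(seed)
  n <- config$n_children
  ids <- sprintf("c%05d", seq_len(n))
  sex <- ifelse(runif(n) < config$sex_ratio, "male", "female")
  race <- names(config$race_probs)[
    apply(rmultinom(n, 1, config$race_probs), 2, which.max)]
  bw <- rnorm(n, config$birth_weight_mean, config$birth_weight_sd)
  z_gen <- (bw - config$birth_weight_mean) / config$birth_weight_sd
  insurance <- ifelse(runif(n) < config$medicaid_prob,
                      "medicaid", "non_medicaid")
  birth_year <- sample(seq(config$birth_year_range[1],
                           config$birth_year_range[2]), n, replace = TRUE)
  children <- data.frame(child_id = ids, sex = sex, race = race,
                         birth_year = birth_year,
                         birth_weight = bw, insurance = insurance,
                         stringsAsFactors = FALSE)

  p1 <- length(config$re_sd)
  coefs <- matrix(NA_real_, n, p1, dimnames = list(ids, NULL))
  visit_list <- vector("list", n)
  truth_list <- vector("list", n)
  hf <- rnorm(n, 1, config$height_factor_sd)
  for (i in seq_len(n)) {
    pop <- config$curves[[sex[i]]]
    u <- rnorm(p1, 0, config$re_sd)
    u[1] <- u[1] + config$bwz_effect * z_gen[i]
    co <- pop$coefficients + u
    coefs[i, ] <- co
    curve_i <- fp_curve(pop$powers, co, sex = sex[i], child_id = ids[i])

    attend <- runif(length(config$schedule)) < config$attendance
    tgt <- config$schedule[attend]
    jit <- rnorm(length(tgt),
                 sd = ifelse(tgt <= config$jitter_cut,
                             config$jitter_sd_infancy,
                             config$jitter_sd_later))
    ages <- sort(pmin(pmax(tgt + jit, 0.23), 216))
    ages <- ages[!duplicated(ages)]
    m <- length(ages)
    C <- config$rho^abs(outer(ages, ages, "-"))
    eps <- if (m > 0)
      drop(rnorm(m) %*% chol(C)) * config$sigma else numeric(0)
    # floor far below any physiologic BMI: keeps weights positive in the
    # rare extreme-left-tail draws where the steep infancy basis overshoots
    true_bmi <- pmax(fp_value(curve_i, ages) + eps, 0.5)
    true_st <- stature_for_age(ages, sex[i]) * hf[i]
    true_wt <- true_bmi * (true_st / 100)^2
    visit_list[[i]] <- data.frame(
      child_id = ids[i], age = ages, weight = true_wt, stature = true_st,
      stature_method = ifelse(ages < 24, "paper_pencil_recumbent",
                              "standing"),
      stringsAsFactors = FALSE)
    ms <- detect_milestones(curve_i)
    truth_list[[i]] <- data.frame(
      child_id = ids[i],
      ip_found = ms["infancy_peak", "found"],
      ip_age = ms["infancy_peak", "age"],
      ip_bmi = ms["infancy_peak", "bmi"],
      ar_found = ms["adiposity_rebound", "found"],
      ar_age = ms["adiposity_rebound", "age"],
      ar_bmi = ms["adiposity_rebound", "bmi"],
      stringsAsFactors = FALSE)
  }
  true_visits <- do.call(rbind, visit_list)
  true_visits$bmi_true <- compute_bmi(true_visits$weight, true_visits$stature)
  recorded <- true_visits[setdiff(names(true_visits), "bmi_true")]
  if (config$measurement_model) {
    recorded <- apply_measurement_model(recorded)
  } else {
    # recorded equals truth: mark lengths as needing no correction so
    # preprocessing leaves them untouched
    recorded$length_corrected <- TRUE
  }
  structure(list(
    cohort = bmi_cohort(children, recorded),
    truth = list(coefficients = coefs,
                 powers = config$curves$male$powers,
                 milestones = do.call(rbind, truth_list),
                 visits = true_visits,
                 z_gen = setNames(z_gen, ids)),
    config = config, seed = seed), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic well-child-visit cohort (seed ", x$seed, ")\n", sep = "")
  print(x$cohort)
  cat("  measurement model:",
      if (x$config$measurement_model) "on" else "off", "\n")
  invisible(x)
}

#' Apply the anthropometric measurement process
#'
#' Weight is rounded to the nearest 0.25 pound (in pounds, then converted
#' back; 1 lb = 0.45359237 kg). Stature is rounded to the nearest quarter
#' inch (1 in = 2.54 cm). For visits before 24 months the recorded length
#' is first distorted by the inverse of the paper-and-pencil correction,
#' `(true - 1.8) / 0.953`, so that [correct_length()] applied downstream
#' recovers the true length up to rounding error.
#'
#' @param visits Data frame with `age`, `weight` (kg), `stature` (cm).
#' @return The visits with recorded (rounded/distorted) measurements.
#' @export
apply_measurement_model <- function(visits) {
  if (any(visits$weight <= 0) || any(visits$stature <= 0))
    stop("true weights and statures must be positive")
  lb <- visits$weight / KG_PER_LB
  visits$weight <- round(lb / 0.25) * 0.25 * KG_PER_LB
  st <- visits$stature
  infant <- visits$age < 24
  st[infant] <- (st[infant] - 1.8) / 0.953
  inch <- st / CM_PER_IN
  visits$stature <- round(inch / 0.25) * 0.25 * CM_PER_IN
  visits
}

#' Write the truth sidecar of a synthetic cohort
#'
#' @param syn A `synthetic_cohort`.
#' @param coef_path,milestone_path Output CSV paths.
#' @export
write_truth <- function(syn, coef_path, milestone_path) {
  co <- as.data.frame(syn$truth$coefficients)
  names(co) <- c("(Intercept)", fp_term_names(syn$truth$powers))
  co <- cbind(child_id = rownames(syn$truth$coefficients), co)
  write.csv(co, coef_path, row.names = FALSE)
  write.csv(syn$truth$milestones, milestone_path, row.names = FALSE)
  invisible(syn)
}
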