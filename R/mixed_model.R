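# Linear mixed-effects engine over the fractional-polynomial basis:
# marginal likelihood with structured within-child residual covariance,
# profiled-GLS fitting, BIC, two-stage structure/mean selection, per-child
# BLUP curves and per-child residual BMI variance.

COV_STRUCTURES <- c("spatial_power", "variance_components",
                    "compound_symmetry", "ar1")
cov_code <- function(structure) {
  match(structure, c("variance_components", "compound_symmetry",
                     "spatial_power", "ar1")) - 1L
}
has_rho <- function(structure) structure != "variance_components"

# Normalize input to a visits frame (child_id, age, bmi) sorted by child
# then age, plus 0-based child start indices for the C++ engine.
prepare_lmm_data <- function(data, sex = NULL) {
  if (inherits(data, "bmi_cohort")) {
    v <- data$visits
    if (is.null(v$bmi))
      stop("cohort has no BMI column; run preprocess_cohort() first")
    if (!is.null(sex)) {
      keep <- data$children$child_id[data$children$sex == sex]
      v <- v[v$child_id %in% keep, , drop = FALSE]
    }
    data <- v
  }
  stopifnot(all(c("child_id", "age", "bmi") %in% names(data)))
  data <- data[order(data$child_id, data$age), , drop = FALSE]
  ids <- unique(data$child_id)
  if (length(ids) < 2)
    stop("random-effect variances are unidentifiable with a single child")
  lens <- as.integer(table(factor(data$child_id, levels = ids)))
  starts <- c(0L, cumsum(lens)[-length(lens)])
  list(df = data, ids = ids, starts = as.integer(starts), lens = lens)
}

resolve_re_cols <- function(re_terms, term_names) {
  if (is.null(re_terms) || identical(re_terms, "all"))
    return(seq_along(term_names))
  idx <- match(re_terms, term_names)
  if (anyNA(idx))
    stop("unknown random-effect term(s): ",
         paste(re_terms[is.na(idx)], collapse = ", "))
  sort(idx)
}

#' Marginal log-likelihood of the mixed model at given parameters
#'
#' Children are independent; the marginal distribution of child i's BMI
#' vector is multivariate normal with mean `X_i beta` and covariance
#' `V_i = Z_i G Z_i' + sigma2 C_i(rho)`, where G is the diagonal
#' random-effect covariance over the selected basis terms and C_i the
#' chosen residual correlation structure. Returns the sum over children of
#' the log density.
#'
#' @param data Visits data frame (`child_id`, `age`, `bmi`) or a
#'   [bmi_cohort()] (with `sex` to subset).
#' @param powers Fractional-polynomial powers.
#' @param fixed Fixed-effect coefficients, intercept first.
#' @param re_variances Random-effect variances aligned to `re_terms`.
#' @param sigma2 Residual variance (kg/m^2)^2.
#' @param rho Residual correlation parameter (ignored for
#'   `"variance_components"`).
#' @param covariance Residual structure: `"spatial_power"`
#'   (`rho^|t_j - t_k|`, continuous-time AR(1)), `"variance_components"`,
#'   `"compound_symmetry"`, or `"ar1"` (by visit order).
#' @param re_terms Which basis terms (including `"(Intercept)"`) carry
#'   random effects; default all.
#' @param sex Optional subset when `data` is a cohort.
#' @return The log-likelihood (a scalar).
#' @export
marginal_loglik <- function(data, powers, fixed, re_variances, sigma2,
                            rho = 0, covariance = COV_STRUCTURES,
                            re_terms = NULL, sex = NULL) {
  covariance <- match.arg(covariance)
  d <- prepare_lmm_data(data, sex)
  X <- fp_basis(d$df$age, sort(powers))
  if (length(fixed) != ncol(X)) stop("fixed has wrong length")
  re_cols <- resolve_re_cols(re_terms, colnames(X))
  if (length(re_variances) != length(re_cols))
    stop("re_variances has wrong length")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (has_rho(covariance) && abs(rho) >= 1) stop("|rho| must be < 1")
  m2ll <- tryCatch(
    lmm_m2ll_fixed_cpp(d$df$bmi, X, d$df$age, d$starts, d$lens,
                       re_cols - 1L, re_variances, sigma2, rho,
                       cov_code(covariance), as.numeric(fixed)),
    error = function(e) {
      m <- regmatches(conditionMessage(e),
                      regexpr("[0-9]+$", conditionMessage(e)))
      if (length(m))
        stop("residual covariance not positive definite for child ",
             d$ids[as.integer(m)], call. = FALSE)
      stop(e)
    })
  -m2ll / 2
}

#' Fit a fractional-polynomial linear mixed model of BMI on age
#'
#' Fixed effects for every fractional-polynomial term plus per-child
#' random effects (diagonal covariance) on the selected terms, with a
#' structured within-child residual covariance. Variance parameters are
#' estimated by bounded quasi-Newton (L-BFGS-B) on log-variance /
#' atanh-correlation transforms with the fixed effects profiled out by
#' generalized least squares; up to `control$starts` deterministic restarts
#' are used on non-convergence. Basis columns are standardized internally
#' for conditioning; all reported quantities are on the raw months scale.
#'
#' @inheritParams marginal_loglik
#' @param method `"ML"` (default, so BIC comparisons across mean
#'   structures are valid) or `"REML"`.
#' @param control List: `maxit` (default 400), `factr` (L-BFGS-B tolerance
#'   factor, default 1e7), `starts` (max optimizer starts, default 3).
#' @return An object of class `bmi_fpmm` with components including
#'   `coefficients` (fixed effects), `re_variances`, `sigma2`, `rho`,
#'   `m2ll`, `bic` (covariance-parameters / n-children convention),
#'   `bic_all` (all parameters / n-observations), `blup`, `beta_cov`,
#'   `converged`.
#' @examples
#' \donttest{
#' syn <- simulate_cohort(cohort_config(n_children = 40, seed = 1))
#' coh <- preprocess_cohort(syn$cohort)
#' fit <- fit_bmi_model(coh, powers = c(-1, 0, 0.5), sex = "male")
#' coef(fit)
#' }
#' @export
fit_bmi_model <- function(data, powers, covariance = COV_STRUCTURES,
                          re_terms = NULL, method = c("ML", "REML"),
                          sex = NULL, control = list()) {
  covariance <- match.arg(covariance)
  method <- match.arg(method)
  ctrl <- modifyList(list(maxit = 400L, factr = 1e7, starts = 3L), control)
  powers <- sort(powers)
  d <- prepare_lmm_data(data, sex)
  y <- d$df$bmi
  ages <- d$df$age
  X <- fp_basis(ages, powers)
  p <- ncol(X)

  scales <- apply(X, 2, sd)
  scales[1] <- 1
  if (any(scales == 0))
    stop("constant basis column(s): ",
         paste(colnames(X)[scales == 0], collapse = ", "))
  Xs <- sweep(X, 2, scales, "/")
  qrX <- qr(Xs)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop("fixed-effect design is rank deficient; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  re_cols <- resolve_re_cols(re_terms, colnames(X))
  r <- length(re_cols)
  rho_par <- has_rho(covariance)
  code <- cov_code(covariance)
  reml <- method == "REML"

  obj <- function(theta) {
    re_var <- exp(theta[seq_len(r)])
    sigma2 <- exp(theta[r + 1])
    rho <- if (rho_par) tanh(theta[r + 2]) else 0
    res <- lmm_eval_cpp(y, Xs, ages, d$starts, d$lens, re_cols - 1L,
                        re_var, sigma2, rho, code, reml, FALSE)
    if (!isTRUE(res$ok) || !is.finite(res$m2ll)) return(1e10)
    res$m2ll
  }

  ols <- qr.coef(qrX, y)
  s2 <- var(y - Xs %*% ols)[1]
  # method-of-moments start: the spread of per-child OLS coefficients
  # approximates the random-effect variances, within-child residual
  # variance the measurement noise
  mom <- NULL
  rich <- which(d$lens >= p + 2L)
  if (length(rich) >= 3) {
    per <- lapply(rich, function(i) {
      idx <- (d$starts[i] + 1):(d$starts[i] + d$lens[i])
      f <- lm.fit(Xs[idx, , drop = FALSE], y[idx])
      c(f$coefficients, sum(f$residuals^2) / max(d$lens[i] - p, 1))
    })
    per <- do.call(rbind, per)
    if (!anyNA(per)) {
      rv0 <- pmax(apply(per[, re_cols, drop = FALSE], 2, var) / 2,
                  1e-4 * s2)
      mom <- c(rv0, max(mean(per[, p + 1]), 0.05 * s2), 0.5)
    }
  }
  start_sets <- list(c(rep(s2 / (2 * r), r), s2 / 2, 0.5),
                     c(rep(s2 / (10 * r), r), 0.9 * s2, 0.2),
                     c(rep(s2 / r, r), s2 / 4, 0.8))
  if (!is.null(mom)) start_sets <- c(list(mom), start_sets)
  lower <- c(rep(log(1e-10), r), log(1e-8), if (rho_par) -atanh(0.99))
  upper <- c(rep(log(1e6), r), log(1e6), if (rho_par) atanh(0.99))

  best <- NULL
  diag_log <- character()
  for (k in seq_len(min(ctrl$starts, length(start_sets)))) {
    st <- start_sets[[k]]
    theta0 <- c(log(st[seq_len(r)]), log(st[r + 1]),
                if (rho_par) atanh(st[r + 2]))
    op <- tryCatch(
      optim(theta0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = ctrl$maxit, factr = ctrl$factr)),
      error = function(e) NULL)
    if (is.null(op)) {
      diag_log <- c(diag_log, sprintf("start %d: optimizer error", k))
      next
    }
    diag_log <- c(diag_log,
                  sprintf("start %d: code %d, -2LL %.4f", k,
                          op$convergence, op$value))
    op$converged <- op$convergence == 0 && op$value < 1e9
    if (is.null(best) || (op$converged && !best$converged) ||
        (op$converged == best$converged && op$value < best$value)) best <- op
    if (op$converged) break
  }
  if (is.null(best))
    stop("all optimizer starts failed")

  theta <- best$par
  re_var_s <- exp(theta[seq_len(r)])
  sigma2 <- exp(theta[r + 1])
  rho <- if (rho_par) tanh(theta[r + 2]) else NA_real_
  fin <- lmm_eval_cpp(y, Xs, ages, d$starts, d$lens, re_cols - 1L,
                      re_var_s, sigma2, if (rho_par) rho else 0,
                      code, reml, TRUE)
  if (!isTRUE(fin$ok)) stop("final covariance evaluation failed")

  beta <- drop(fin$beta) / scales
  names(beta) <- colnames(X)
  D <- diag(1 / scales, p)
  beta_cov <- D %*% fin$beta_cov %*% D
  dimnames(beta_cov) <- list(colnames(X), colnames(X))
  blup <- sweep(fin$blup, 2, scales[re_cols], "/")
  dimnames(blup) <- list(d$ids, colnames(X)[re_cols])
  re_variances <- setNames(re_var_s / scales[re_cols]^2,
                           colnames(X)[re_cols])

  n_child <- length(d$ids)
  n_obs <- length(y)
  q_cov <- r + 1L + as.integer(rho_par)
  m2ll <- fin$m2ll

  structure(list(
    powers = powers, coefficients = beta, beta_cov = beta_cov,
    re_terms = colnames(X)[re_cols], re_variances = re_variances,
    sigma2 = sigma2, rho = rho, covariance = covariance, method = method,
    m2ll = m2ll, logLik = -m2ll / 2,
    n_children = n_child, n_obs = n_obs,
    q_cov = q_cov, n_params = q_cov + p,
    bic = m2ll + q_cov * log(n_child),
    bic_all = m2ll + (q_cov + p) * log(n_obs),
    blup = blup, converged = isTRUE(best$converged),
    optim_log = diag_log, scales = scales,
    data = d$df, child_ids = d$ids, starts = d$starts, lens = d$lens,
    sex = sex), class = "bmi_fpmm")
}

#' Bayesian information criterion of a fitted model
#'
#' `BIC = -2LL + q log(n)`. The default convention penalizes the estimated
#' covariance parameters only, with n = number of children (matching the
#' output convention of the mixed-model software tradition this toolkit
#' follows, where the fixed effects are profiled); the textbook alternative
#' counts all estimated parameters with n = number of observations.
#'
#' @param fit A `bmi_fpmm`.
#' @param convention `"covariance_children"` or `"all_observations"`.
#' @return BIC value.
#' @export
bic <- function(fit, convention = c("covariance_children",
                                    "all_observations")) {
  convention <- match.arg(convention)
  if (convention == "covariance_children") fit$bic else fit$bic_all
}

#' @export
print.bmi_fpmm <- function(x, digits = 4, ...) {
  cat("Fractional-polynomial mixed model",
      if (!is.null(x$sex)) paste0("(", x$sex, ")"), "\n")
  cat("  powers:", paste(x$powers, collapse = ", "),
      " | residual covariance:", x$covariance,
      " | method:", x$method, "\n")
  cat("  children:", x$n_children, " observations:", x$n_obs, "\n")
  cat("  fixed effects:\n")
  print(signif(x$coefficients, digits))
  cat(sprintf("  sigma2 %.4g%s | -2LL %.2f | BIC %.2f%s\n",
              x$sigma2,
              if (!is.na(x$rho)) sprintf(", rho %.4g", x$rho) else "",
              x$m2ll, x$bic,
              if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' @export
summary.bmi_fpmm <- function(object, ...) {
  se <- sqrt(diag(object$beta_cov))
  coefs <- cbind(Estimate = object$coefficients, `Std. Error` = se,
                 `z value` = object$coefficients / se)
  rv <- residual_bmi_variance(object)
  out <- list(fit = object, coefficients = coefs,
              re_variances = object$re_variances,
              resid_var_quartiles = quantile(rv, c(0.25, 0.5, 0.75)))
  class(out) <- "summary.bmi_fpmm"
  out
}

#' @export
print.summary.bmi_fpmm <- function(x, ...) {
  print(x$fit)
  cat("  fixed-effect table:\n")
  print(signif(x$coefficients, 4))
  cat("  random-effect variances:\n")
  print(signif(x$re_variances, 4))
  cat("  per-child residual BMI variance quartiles:",
      paste(signif(x$resid_var_quartiles, 3), collapse = " / "), "\n")
  invisible(x)
}

#' @export
coef.bmi_fpmm <- function(object, ...) object$coefficients

#' @export
logLik.bmi_fpmm <- function(object, ...) {
  structure(object$logLik, df = object$n_params,
            nobs = object$n_obs, class = "logLik")
}

#' Population-average curve of a fitted model
#' @param fit A `bmi_fpmm`.
#' @return An [fp_curve()].
#' @export
population_curve <- function(fit) {
  fp_curve(fit$powers, unname(fit$coefficients), sex = fit$sex)
}

#' Individual-specific curves (fixed effects + predicted random effects)
#'
#' Each child's curve adds the best linear unbiased predictions (BLUPs) of
#' its random effects, `u_i = G Z_i' V_i^{-1} (y_i - X_i beta)`, to the
#' fixed effects (zero-padded over terms without random effects). The
#' per-child residual BMI variance — mean squared deviation of observed
#' BMI from the individual curve over the child's visits — is attached to
#' each curve.
#'
#' @param fit A `bmi_fpmm`.
#' @param children Subset of child ids (default all).
#' @return Named list of [fp_curve()] objects.
#' @export
individual_curves <- function(fit, children = fit$child_ids) {
  unknown <- setdiff(children, fit$child_ids)
  if (length(unknown))
    stop("child(ren) not in the fitted cohort: ",
         paste(head(unknown), collapse = ", "))
  term_names <- c("(Intercept)", fp_term_names(fit$powers))
  rv <- residual_bmi_variance(fit)
  out <- lapply(children, function(id) {
    u <- setNames(numeric(length(term_names)), term_names)
    u[fit$re_terms] <- fit$blup[as.character(id), ]
    fp_curve(fit$powers, unname(fit$coefficients + u), sex = fit$sex,
             child_id = id, residual_variance = rv[[as.character(id)]])
  })
  names(out) <- children
  out
}

#' Per-child residual BMI variance
#'
#' Mean of squared residuals (observed minus individual-curve BMI) over
#' each child's visits; a smaller value indicates a better individual fit.
#'
#' @param fit A `bmi_fpmm`.
#' @param denominator `"n"` (default) or `"n_minus_1"`.
#' @return Named numeric vector, one value per child.
#' @export
residual_bmi_variance <- function(fit, denominator = c("n", "n_minus_1")) {
  denominator <- match.arg(denominator)
  r <- residuals(fit, level = "individual")
  out <- vapply(split(r, factor(fit$data$child_id, levels = fit$child_ids)),
                function(ri) {
                  den <- if (denominator == "n") length(ri)
                         else max(length(ri) - 1L, 1L)
                  sum(ri^2) / den
                }, numeric(1))
  out
}

fitted_matrix <- function(fit, level) {
  X <- fp_basis(fit$data$age, fit$powers)
  pop <- drop(X %*% fit$coefficients)
  if (level == "population") return(pop)
  Z <- X[, match(fit$re_terms, colnames(X)), drop = FALSE]
  uexp <- fit$blup[match(fit$data$child_id, fit$child_ids), , drop = FALSE]
  pop + rowSums(Z * uexp)
}

#' @export
fitted.bmi_fpmm <- function(object, level = c("individual", "population"),
                            ...) {
  fitted_matrix(object, match.arg(level))
}

#' @export
residuals.bmi_fpmm <- function(object, level = c("individual", "population"),
                               ...) {
  object$data$bmi - fitted(object, level = match.arg(level))
}

#' @export
predict.bmi_fpmm <- function(object, age = NULL, child = NULL,
                             level = c("population", "individual"), ...) {
  level <- match.arg(level)
  if (is.null(age)) age <- object$data$age
  if (level == "population") return(fp_value(population_curve(object), age))
  if (is.null(child)) stop("individual prediction needs a child id")
  fp_value(individual_curves(object, child)[[1]], age)
}

#' @export
plot.bmi_fpmm <- function(x, n_children = 12, ...) {
  age <- exp(seq(log(0.225), log(216), length.out = 400))
  pop <- fp_value(population_curve(x), age)
  ids <- head(x$child_ids, n_children)
  M <- vapply(individual_curves(x, ids), function(cv) fp_value(cv, age),
              numeric(length(age)))
  plot(age, pop, type = "n", xlab = "Age (months)", ylab = "BMI (kg/m^2)",
       ylim = range(M, pop), ...)
  matlines(age, M, lty = 1, col = "grey70")
  lines(age, pop, lwd = 2)
  invisible(x)
}

#' Simulate BMI responses from a fitted model
#'
#' Draws new random effects and structured residuals at the fitted design
#' (same children, same visit ages) — the parametric-bootstrap data
#' generator implied by the model.
#'
#' @param object A `bmi_fpmm`.
#' @param nsim Number of replicate response vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Data frame with `child_id`, `age` and `sim_1..sim_nsim` columns.
#' @export
simulate.bmi_fpmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  X <- fp_basis(object$data$age, object$powers)
  Z <- X[, match(object$re_terms, colnames(X)), drop = FALSE]
  pop <- drop(X %*% object$coefficients)
  r <- length(object$re_variances)
  sims <- replicate(nsim, {
    y <- numeric(nrow(X))
    for (i in seq_along(object$child_ids)) {
      idx <- (object$starts[i] + 1):(object$starts[i] + object$lens[i])
      u <- rnorm(r, 0, sqrt(object$re_variances))
      t_i <- object$data$age[idx]
      C <- resid_cor_R(t_i, object$rho, object$covariance)
      e <- drop(rnorm(length(idx)) %*% chol(object$sigma2 * C))
      y[idx] <- pop[idx] + drop(Z[idx, , drop = FALSE] %*% u) + e
    }
    y
  })
  out <- data.frame(child_id = object$data$child_id, age = object$data$age)
  sims <- as.data.frame(sims)
  names(sims) <- paste0("sim_", seq_len(nsim))
  cbind(out, sims)
}

# R-side residual correlation builder (mirrors the C++ one).
resid_cor_R <- function(t, rho, structure) {
  n <- length(t)
  if (structure == "variance_components" || is.na(rho)) return(diag(n))
  C <- switch(structure,
    compound_symmetry = matrix(rho, n, n),
    spatial_power = rho^abs(outer(t, t, "-")),
    ar1 = rho^abs(outer(seq_len(n), seq_len(n), "-")))
  diag(C) <- 1
  C
}

#' Two-stage selection of covariance and mean structures
#'
#' Stage 1 fits the most complex mean structure — the union of all
#' candidate power sets — under each residual covariance structure and
#' keeps the structure with the lowest BIC. Stage 2 fixes that structure
#' and fits every candidate mean model, returning the one with the lowest
#' BIC. Ties break toward the lower degree, then the earlier canonical
#' candidate; non-convergent fits are recorded and ranked last.
#'
#' @inheritParams fit_bmi_model
#' @param candidates List of power sets (default [fp_candidates()]).
#' @param structures Covariance structures to consider in stage 1.
#' @param bic_convention Passed to [bic()].
#' @return `bmi_fpmm_selection`: list with `stage1` (structure table),
#'   `structure`, `ranking` (candidate table), `best_fit`.
#' @export
select_model <- function(data, candidates = fp_candidates(),
                         structures = COV_STRUCTURES,
                         re_terms = NULL, method = c("ML", "REML"),
                         sex = NULL, control = list(),
                         bic_convention = "covariance_children") {
  method <- match.arg(method)
  if (!length(candidates) || !length(structures))
    stop("need at least one candidate and one structure")
  full <- sort(unique(unlist(candidates)))
  stage1 <- lapply(structures, function(st) {
    f <- tryCatch(fit_bmi_model(data, full, covariance = st,
                                re_terms = re_terms, method = method,
                                sex = sex, control = control),
                  error = function(e) NULL)
    data.frame(structure = st,
               m2ll = if (is.null(f)) NA_real_ else f$m2ll,
               bic = if (is.null(f)) NA_real_ else bic(f, bic_convention),
               converged = !is.null(f) && f$converged)
  })
  stage1 <- do.call(rbind, stage1)
  o1 <- order(!stage1$converged, stage1$bic)
  best_structure <- stage1$structure[o1[1]]
  if (!stage1$converged[o1[1]] && all(!stage1$converged))
    warning("no stage-1 fit converged; using the best available")

  fits <- vector("list", length(candidates))
  rank_tab <- lapply(seq_along(candidates), function(i) {
    pw <- sort(candidates[[i]])
    f <- tryCatch(fit_bmi_model(data, pw, covariance = best_structure,
                                re_terms = re_terms, method = method,
                                sex = sex, control = control),
                  error = function(e) NULL)
    fits[[i]] <<- f
    data.frame(index = i, degree = length(pw),
               powers = paste(pw, collapse = " "),
               m2ll = if (is.null(f)) NA_real_ else f$m2ll,
               bic = if (is.null(f)) NA_real_ else bic(f, bic_convention),
               converged = !is.null(f) && f$converged)
  })
  rank_tab <- do.call(rbind, rank_tab)
  o2 <- order(!rank_tab$converged, rank_tab$bic, rank_tab$degree,
              rank_tab$index)
  if (all(!rank_tab$converged) || is.null(fits[[rank_tab$index[o2[1]]]]))
    stop("all stage-2 candidate fits failed")
  ranking <- rank_tab[o2, , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(stage1 = stage1[o1, , drop = FALSE],
                 structure = best_structure,
                 ranking = ranking,
                 best_fit = fits[[ranking$index[1]]]),
            class = "bmi_fpmm_selection")
}

#' @export
print.bmi_fpmm_selection <- function(x, ...) {
  cat("Two-stage model selection\n")
  cat("  selected residual covariance:", x$structure, "\n")
  cat("  best mean model: powers", x$ranking$powers[1],
      sprintf("(BIC %.2f)\n", x$ranking$bic[1]))
  cat("  candidates ranked:", nrow(x$ranking), "\n")
  invisible(x)
}
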