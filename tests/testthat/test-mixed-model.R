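test_that("marginal log-likelihood matches the brute-force stacked density", {
  set.seed(20)
  structures <- c("variance_components", "compound_symmetry",
                  "spatial_power", "ar1")
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    powers <- sort(sample(fp_power_set(), sample(1:3, 1)))
    df <- do.call(rbind, lapply(seq_len(k), function(i) {
      n <- sample(2:6, 1)
      data.frame(child_id = sprintf("c%d", i),
                 age = sort(runif(n, 0.3, 200)),
                 bmi = runif(n, 12, 25))
    }))
    beta <- rnorm(length(powers) + 1)
    # random-effect variances on the scale children actually vary: O(1)
    # BMI contribution per term (also keeps V well conditioned)
    X <- fp_basis(df$age, powers)
    re_var <- runif(ncol(X), 0.01, 0.5) / pmax(colMeans(X^2), 1)
    sigma2 <- runif(1, 0.2, 2)
    st <- sample(structures, 1)
    rho <- if (st == "variance_components") 0 else runif(1, 0.05, 0.9)
    ll <- marginal_loglik(df, powers, beta, re_var, sigma2, rho, st)
    oracle <- brute_loglik(df, powers, beta, re_var, sigma2, rho, st)
    expect_equal(ll, oracle, tolerance = 1e-8)
  }
})

test_that("with zero random effects and independent residuals the likelihood is iid Gaussian", {
  set.seed(21)
  df <- curve_cohort(fp_reference_curve("male"), k = 4)
  df$bmi <- df$bmi + rnorm(nrow(df), 0, 0.5)
  beta <- fp_reference_curve("male")$coefficients
  sigma2 <- 0.31
  ll <- marginal_loglik(df, c(-2, -1, -0.5, 0, 0.5), beta,
                        rep(1e-300, 6), sigma2, 0, "variance_components")
  X <- fp_basis(df$age, c(-2, -1, -0.5, 0, 0.5))
  r <- df$bmi - drop(X %*% beta)
  expect_equal(ll, sum(dnorm(r, 0, sqrt(sigma2), log = TRUE)),
               tolerance = 1e-8)
})

test_that("the likelihood is invariant to child relabelling", {
  set.seed(22)
  df <- curve_cohort(fp_reference_curve("female"), k = 4,
                     offsets = rnorm(4))
  beta <- fp_reference_curve("female")$coefficients
  args <- list(powers = c(-2, -1, -0.5, 0, 0.5), fixed = beta,
               re_variances = rep(0.2, 6), sigma2 = 0.5, rho = 0.6,
               covariance = "spatial_power")
  ll1 <- do.call(marginal_loglik, c(list(df), args))
  df2 <- df
  df2$child_id <- chartr("1234", "4321", df2$child_id)
  ll2 <- do.call(marginal_loglik, c(list(df2), args))
  expect_equal(ll1, ll2, tolerance = 1e-10)
})

test_that("exact data from a degree-3 curve are interpolated by the fit", {
  cv <- fp_curve(c(-1, 0, 0.5), c(18, 2, -3, 0.4))
  df <- curve_cohort(cv, k = 6, ages = c(0.5, 2, 5, 12, 36, 90, 180))
  fit <- fit_bmi_model(df, c(-1, 0, 0.5))
  expect_equal(unname(coef(fit)), cv$coefficients, tolerance = 1e-6)
})

test_that("identifiability and rank guards fire", {
  df <- curve_cohort(fp_reference_curve("male"), k = 1)
  expect_error(fit_bmi_model(df, c(-1, 0)), "single child")
  df3 <- curve_cohort(fp_reference_curve("male"), k = 3, ages = c(1, 2, 3))
  expect_error(fit_bmi_model(df3, c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)),
               "rank deficient|collinear")
})

test_that("BIC follows -2LL + q log(n) under both conventions", {
  fake <- structure(list(bic = 100 + 3 * log(1680), bic_all = NA),
                    class = "bmi_fpmm")
  expect_equal(bic(fake), 122.2796, tolerance = 1e-4)
  syn <- quick_cohort(n = 30, seed = 3)
  fit <- fit_bmi_model(preprocess_cohort(syn$cohort), c(-1, 0, 0.5),
                       sex = "male")
  expect_equal(bic(fit), fit$m2ll + fit$q_cov * log(fit$n_children))
  expect_equal(bic(fit, "all_observations"),
               fit$m2ll + fit$n_params * log(fit$n_obs))
  expect_equal(fit$q_cov, 4 + 1 + 1)  # 4 RE variances, sigma2, rho
  expect_error(bic(fit, "made_up"), "arg")
})

test_that("profiled GLS fixed effects are identical under ML and REML", {
  syn <- quick_cohort(n = 20, seed = 8)
  coh <- preprocess_cohort(syn$cohort)
  d <- bmitraj:::prepare_lmm_data(coh, sex = "female")
  X <- fp_basis(d$df$age, c(-1, 0, 0.5))
  re_var <- c(0.4, 0.1, 0.05, 0.02)
  for (reml in c(FALSE, TRUE)) {
    ev <- bmitraj:::lmm_eval_cpp(d$df$bmi, X, d$df$age, d$starts, d$lens,
                                 0:3, re_var, 0.8, 0.7, 2L, reml, FALSE)
    if (reml) beta_reml <- ev$beta else beta_ml <- ev$beta
  }
  expect_equal(beta_ml, beta_reml, tolerance = 1e-12)
})

test_that("BLUPs satisfy the explicit matrix identity on a hand-built fixture", {
  # 2 children x 3 visits, random intercept + slope-in-sqrt(age)
  df <- tiny_visits(list(
    a = list(age = c(1, 4, 9), bmi = c(14, 16, 17.5)),
    b = list(age = c(1, 4, 16), bmi = c(13, 15, 18))))
  powers <- 0.5
  re_var <- c(0.3, 0.08)
  sigma2 <- 0.5; rho <- 0.4
  d <- bmitraj:::prepare_lmm_data(df)
  X <- fp_basis(d$df$age, powers)
  ev <- bmitraj:::lmm_eval_cpp(d$df$bmi, X, d$df$age, d$starts, d$lens,
                               0:1, re_var, sigma2, rho, 2L, FALSE, TRUE)
  G <- diag(re_var)
  for (i in 1:2) {
    idx <- d$starts[i] + seq_len(d$lens[i])
    Zi <- X[idx, , drop = FALSE]
    Vi <- Zi %*% G %*% t(Zi) +
      sigma2 * oracle_cor(d$df$age[idx], rho, "spatial_power")
    ui <- G %*% t(Zi) %*% solve(Vi, d$df$bmi[idx] - Zi %*% ev$beta)
    expect_equal(unname(ev$blup[i, ]), drop(ui), tolerance = 1e-8)
  }
})

test_that("individual curves shrink toward the population curve as noise dominates", {
  # a child consistently above the population: its curve sits above at
  # every visited age
  set.seed(30)
  base <- curve_cohort(fp_reference_curve("male"), k = 8,
                       offsets = c(rep(0, 7), 3))
  base$bmi <- base$bmi + rnorm(nrow(base), 0, 0.05)
  fit <- fit_bmi_model(base, c(-2, -1, -0.5, 0, 0.5))
  high <- individual_curves(fit, "k08")[[1]]
  ages <- unique(base$age)
  expect_true(all(fp_value(high, ages) >
                  fp_value(population_curve(fit), ages)))
  # monotone shrinkage of individual residuals in the RE variance, at
  # fixed data and fixed residual parameters
  d <- bmitraj:::prepare_lmm_data(base)
  X <- fp_basis(d$df$age, c(-2, -1, -0.5, 0, 0.5))
  mean_abs_resid <- vapply(c(0.001, 0.1, 10), function(v) {
    ev <- bmitraj:::lmm_eval_cpp(d$df$bmi, X, d$df$age, d$starts, d$lens,
                                 0:5, rep(v, 6), 0.5, 0.5, 2L, FALSE, TRUE)
    fitted_i <- drop(X %*% ev$beta) +
      rowSums(X * ev$blup[rep(seq_along(d$ids), d$lens), ])
    mean(abs(d$df$bmi - fitted_i))
  }, numeric(1))
  expect_true(all(diff(mean_abs_resid) < 0))
})

test_that("per-child residual variance matches direct recomputation", {
  df <- tiny_visits(list(
    a = list(age = c(2, 8, 24), bmi = c(15, 17, 16)),
    b = list(age = c(2, 8, 24), bmi = c(14, 16.5, 15.5))))
  fit <- fit_bmi_model(df, 0.5)
  rv <- residual_bmi_variance(fit)
  r <- residuals(fit, level = "individual")
  manual <- tapply(r^2, df$child_id, mean)
  expect_equal(unname(rv[names(manual)]), as.numeric(manual))
  # the stated fixture: residuals (0.5, -0.5, 1.0) average to 0.5
  expect_equal(mean(c(0.5, -0.5, 1)^2), 0.5)
})

test_that("the fitted likelihood agrees with the standalone evaluator", {
  syn <- quick_cohort(n = 25, seed = 12)
  coh <- preprocess_cohort(syn$cohort)
  fit <- fit_bmi_model(coh, c(-1, 0, 0.5), sex = "male")
  ll <- marginal_loglik(coh, fit$powers, unname(coef(fit)),
                        unname(fit$re_variances), fit$sigma2, fit$rho,
                        "spatial_power", sex = "male")
  expect_equal(ll, fit$logLik, tolerance = 1e-6)
})

test_that("fits agree with an independent mixed-model implementation", {
  skip_if_not_installed("nlme")
  # data generated from the same degree-3 basis the model fits, so the
  # likelihood optimum is interior and both optimizers must meet there
  gen <- fp_curve(c(-1, 0, 0.5), c(14, -2, 1.2, 0.3))
  syn <- quick_cohort(n = 40, seed = 17,
                      curves = list(male = gen, female = gen),
                      re_sd = c(0.5, 0.1, 0.1, 0.05),
                      sigma = 0.6, rho = 0.8, bwz_effect = 0,
                      measurement_model = FALSE)
  coh <- preprocess_cohort(syn$cohort)
  fit <- fit_bmi_model(coh, c(-1, 0, 0.5), sex = "male")
  d <- bmitraj:::prepare_lmm_data(coh, sex = "male")$df
  d$sqrt_age <- sqrt(d$age); d$log_age <- log(d$age); d$inv_age <- 1 / d$age
  ref <- nlme::lme(bmi ~ inv_age + log_age + sqrt_age, data = d,
                   random = list(child_id =
                     nlme::pdDiag(~ inv_age + log_age + sqrt_age)),
                   correlation = nlme::corCAR1(form = ~ age | child_id),
                   method = "ML",
                   control = nlme::lmeControl(opt = "optim",
                                              returnObject = TRUE))
  expect_equal(unname(coef(fit)),
               unname(nlme::fixef(ref))[c(1, 2, 3, 4)], tolerance = 2e-2)
  expect_equal(-2 * as.numeric(stats::logLik(ref)), fit$m2ll,
               tolerance = 1e-3)
})

test_that("two-stage selection honours tie rules and trivial inputs", {
  syn <- quick_cohort(n = 20, seed = 4)
  coh <- preprocess_cohort(syn$cohort)
  one <- select_model(coh, candidates = list(c(-1, 0, 0.5)),
                      structures = "spatial_power", sex = "male",
                      control = list(starts = 1))
  expect_equal(one$structure, "spatial_power")
  expect_equal(one$ranking$powers, "-1 0 0.5")
  expect_equal(one$best_fit$powers, c(-1, 0, 0.5))
  # identical candidates give an exact BIC tie: the earlier index wins
  two <- select_model(coh, candidates = list(c(-1, 0, 0.5), c(-1, 0, 0.5)),
                      structures = "spatial_power", sex = "male",
                      control = list(starts = 1))
  expect_equal(two$ranking$index[1], 1)
  expect_error(select_model(coh, candidates = list(), sex = "male"),
               "at least one")
})

test_that("selection ranking is invariant to child relabelling", {
  syn <- quick_cohort(n = 30, seed = 44)
  coh <- preprocess_cohort(syn$cohort)
  cands <- list(c(-1, 0, 0.5), c(0, 0.5, 1))
  s1 <- select_model(coh, candidates = cands, structures = "spatial_power",
                     sex = "female", control = list(starts = 2))
  coh2 <- coh
  relabel <- setNames(rev(coh$children$child_id), coh$children$child_id)
  coh2$children$child_id <- relabel[coh2$children$child_id]
  coh2$visits$child_id <- relabel[coh2$visits$child_id]
  coh2$visits <- coh2$visits[order(coh2$visits$child_id, coh2$visits$age), ]
  s2 <- select_model(coh2, candidates = cands, structures = "spatial_power",
                     sex = "female", control = list(starts = 2))
  expect_equal(s1$ranking$powers, s2$ranking$powers)
  expect_equal(s1$ranking$bic, s2$ranking$bic, tolerance = 1e-6)
})

test_that("prediction is refused for unseen children", {
  df <- curve_cohort(fp_reference_curve("male"), k = 3)
  fit <- fit_bmi_model(df, c(-1, 0))
  expect_error(individual_curves(fit, "nobody"), "not in the fitted cohort")
})

test_that("model methods expose the fit coherently", {
  syn <- quick_cohort(n = 20, seed = 9)
  coh <- preprocess_cohort(syn$cohort)
  fit <- fit_bmi_model(coh, c(-1, 0, 0.5), sex = "male")
  expect_s3_class(fit, "bmi_fpmm")
  expect_output(print(fit), "powers")
  expect_output(print(summary(fit)), "residual BMI variance")
  expect_length(coef(fit), 4)
  expect_equal(as.numeric(logLik(fit)), fit$logLik)
  expect_equal(length(fitted(fit)), fit$n_obs)
  expect_equal(fitted(fit) + residuals(fit), fit$data$bmi)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(names(sim), c("child_id", "age", "sim_1", "sim_2"))
  expect_false(identical(sim$sim_1, sim$sim_2))
})
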