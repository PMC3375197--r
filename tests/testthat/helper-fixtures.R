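# Shared fixtures: tiny cohorts built in code and an independent
# brute-force multivariate-normal log-likelihood oracle.

# Visits frame for hand-built children: list(child_id = list(age, bmi))
tiny_visits <- function(children) {
  do.call(rbind, lapply(names(children), function(id) {
    ch <- children[[id]]
    data.frame(child_id = id, age = ch$age, bmi = ch$bmi,
               stringsAsFactors = FALSE)
  }))
}

# A minimal valid cohort with k children on a shared schedule, BMI values
# generated exactly from a curve plus optional per-child offsets.
curve_cohort <- function(curve, k = 3, ages = c(1, 3, 6, 12, 24, 60, 120),
                         offsets = rep(0, k)) {
  do.call(rbind, lapply(seq_len(k), function(i) {
    data.frame(child_id = sprintf("k%02d", i), age = ages,
               bmi = fp_value(curve, ages) + offsets[i],
               stringsAsFactors = FALSE)
  }))
}

# Residual correlation matrix, written independently of the package's
# internal builder.
oracle_cor <- function(t, rho, structure) {
  n <- length(t)
  switch(structure,
    variance_components = diag(n),
    compound_symmetry = {
      M <- matrix(rho, n, n); diag(M) <- 1; M },
    spatial_power = outer(t, t, function(a, b) rho^abs(a - b)),
    ar1 = outer(seq_len(n), seq_len(n), function(a, b) rho^abs(a - b)))
}

# Brute force: stack all children into one block-diagonal multivariate
# normal and evaluate the joint log density directly.
brute_loglik <- function(df, powers, beta, re_var, sigma2, rho, structure,
                         re_cols = NULL) {
  df <- df[order(df$child_id, df$age), ]
  X <- fp_basis(df$age, sort(powers))
  if (is.null(re_cols)) re_cols <- seq_len(ncol(X))
  ids <- unique(df$child_id)
  blocks <- lapply(ids, function(id) {
    idx <- df$child_id == id
    Zi <- X[idx, re_cols, drop = FALSE]
    Zi %*% diag(re_var, length(re_var)) %*% t(Zi) +
      sigma2 * oracle_cor(df$age[idx], rho, structure)
  })
  N <- nrow(df)
  V <- matrix(0, N, N)
  pos <- 1
  for (B in blocks) {
    n <- nrow(B)
    V[pos:(pos + n - 1), pos:(pos + n - 1)] <- B
    pos <- pos + n
  }
  r <- df$bmi - drop(X %*% beta)
  ld <- determinant(V, logarithm = TRUE)
  -0.5 * (N * log(2 * pi) + as.numeric(ld$modulus) +
          drop(crossprod(r, solve(V, r))))
}

# Small fast simulated cohort for integration-style tests.
quick_cohort <- function(n = 50, seed = 1, ...) {
  simulate_cohort(cohort_config(n_children = n, seed = seed, ...),
                  seed = seed)
}
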