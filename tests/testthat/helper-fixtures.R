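# Shared fixtures: small cohorts and hand-built model inputs, all generated
# in code at test time.

small_spec <- function(seed = 42L, n = c(SCD = 40L, MCI = 60L, AD = 80L)) {
  sim_spec(group_sizes = n, seed = seed)
}

# Spec with every education/interaction/nuisance effect switched off.
null_effect_spec <- function(seed = 1L,
                             n = c(SCD = 108L, MCI = 190L, AD = 245L)) {
  zero <- stats::setNames(rep(0, 3), cognitive_domains())
  sim_spec(group_sizes = n,
           education_slopes = list(SCD = zero, MCI = zero, AD = zero),
           interaction_coefs = list(SCD = zero, MCI = zero, AD = zero),
           seed = seed)
}

# Minimal scored-like frame for direct model fitting.
random_model_frame <- function(n, seed, groups = "SCD") {
  set.seed(seed)
  data.frame(
    diagnosis = factor(sample(groups, n, replace = TRUE),
                       levels = diagnosis_levels()),
    global_cognition = rnorm(n),
    edu_num = sample(1:3, n, replace = TRUE),
    age = round(runif(n, 55, 90)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    burden_global_cognition = rnorm(n))
}

# Independent textbook BH step-up, used as the FDR oracle.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Closed-form OLS oracle: coefficients, SEs, R2 via normal equations + RSS.
ols_oracle <- function(X, y) {
  Xm <- cbind(1, as.matrix(X))
  XtXinv <- solve(crossprod(Xm))
  beta <- drop(XtXinv %*% crossprod(Xm, y))
  e <- y - drop(Xm %*% beta)
  df <- nrow(Xm) - ncol(Xm)
  s2 <- sum(e^2) / df
  list(beta = beta, se = sqrt(diag(XtXinv) * s2),
       r2 = 1 - sum(e^2) / sum((y - mean(y))^2),
       rss = sum(e^2), df = df)
}
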