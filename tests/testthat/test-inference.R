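test_that("scale_variables z-scores listed columns and rejects zero variance", {
  tb <- data.frame(a = c(2, 4, 6), b = c(1, 1, 1), c = c(-1, 0, 1))
  out <- scale_variables(tb, c("a", "c"))
  expect_equal(out$a, c(-1, 0, 1))
  expect_equal(out$c, c(-1, 0, 1))        # idempotent on already-z columns
  expect_error(scale_variables(tb, "b"), "zero variance")
  expect_error(scale_variables(tb, "zzz"), "no column")
})

test_that("stratified fits match the normal-equations oracle and recover truth", {
  d <- random_model_frame(60, seed = 101)
  fit <- stratified_education_fit(d, "global_cognition")
  # oracle on the same standardized frame
  z <- function(x) (x - mean(x)) / sd(x)
  X <- cbind(edu_z = z(d$edu_num), age_z = z(d$age),
             sex_male = as.numeric(d$sex == "male"),
             burden_z = z(d$burden_global_cognition))
  o <- ols_oracle(X, z(d$global_cognition))
  expect_equal(unname(fit$coef), unname(o$beta), tolerance = 1e-8)
  expect_equal(unname(fit$se), unname(o$se), tolerance = 1e-8)
  expect_equal(fit$r2, o$r2, tolerance = 1e-10)
  # noiseless recovery of a 0.5 education slope
  d2 <- random_model_frame(80, seed = 102)
  d2$global_cognition <- 0.5 * scale(d2$edu_num)[, 1] + 0.1 * scale(d2$age)[, 1]
  d2$global_cognition <- d2$global_cognition / sd(d2$global_cognition) # unit outcome
  lambda <- 1 / attr(scale(0.5 * scale(d2$edu_num)[, 1] + 0.1 * scale(d2$age)[, 1]), "scaled:scale")
  fit2 <- suppressWarnings(stratified_education_fit(d2, "global_cognition"))
  expect_equal(fit2$coef[["edu_z"]], 0.5 * lambda, tolerance = 1e-10)
  expect_equal(fit2$r2, 1, tolerance = 1e-10)
})

test_that("permuted outcomes center the education effect on zero", {
  d <- random_model_frame(120, seed = 103)
  set.seed(104)
  betas <- replicate(300, {
    d$global_cognition <- sample(d$global_cognition)
    stratified_education_fit(d, "global_cognition")$coef[["edu_z"]]
  })
  expect_lt(abs(mean(betas)), 3 * sd(betas) / sqrt(length(betas)))
})

test_that("ANCOVA interaction F equals the brute-force nested-RSS formula", {
  set.seed(105)
  d <- random_model_frame(20, seed = 105, groups = c("SCD", "MCI", "AD"))
  a <- ancova_interaction(d, "global_cognition")
  z <- function(x) (x - mean(x)) / sd(x)
  y <- z(d$global_cognition)
  g <- droplevels(d$diagnosis)
  Xr <- model.matrix(~ z(d$edu_num) + g + z(d$age) +
                       I(as.numeric(d$sex == "male")) + z(d$burden_global_cognition))
  Xf <- model.matrix(~ z(d$edu_num) * g + z(d$age) +
                       I(as.numeric(d$sex == "male")) + z(d$burden_global_cognition))
  rss <- function(X) sum(lm.fit(X, y)$residuals^2)
  df_delta <- ncol(Xf) - ncol(Xr)
  df_f <- nrow(Xf) - ncol(Xf)
  F_oracle <- ((rss(Xr) - rss(Xf)) / df_delta) / (rss(Xf) / df_f)
  expect_equal(a$F, F_oracle, tolerance = 1e-8)
  expect_equal(a$df1, df_delta)   # (levels - 1) x 1 for numeric education
  expect_equal(a$df2, df_f)
  expect_equal(a$p, pf(F_oracle, df_delta, df_f, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("Welch slope comparison reproduces the hand-computed formula", {
  mk <- function(beta, se, df, group) structure(
    list(terms = "edu_z", coef = c(edu_z = beta), se = c(edu_z = se),
         df_residual = df, group = group), class = "mod_fit")
  w <- welch_compare_slopes(mk(0.5, 0.1, 100, "SCD"), mk(0.2, 0.1, 100, "MCI"))
  expect_equal(w$t, 0.3 / sqrt(0.02), tolerance = 1e-10)  # 2.1213...
  expect_equal(w$df, 200, tolerance = 1e-10)
  expect_equal(w$p, 2 * pt(w$t, 200, lower.tail = FALSE), tolerance = 1e-12)
  # identity and antisymmetry
  same <- welch_compare_slopes(mk(0.4, 0.2, 50, "a"), mk(0.4, 0.2, 50, "b"))
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  rev <- welch_compare_slopes(mk(0.2, 0.1, 100, "MCI"), mk(0.5, 0.1, 100, "SCD"))
  expect_equal(rev$t, -w$t); expect_equal(rev$p, w$p)
  expect_error(welch_compare_slopes(mk(1, 1, 10, "a"), mk(1, 1, 10, "b"), "nope"),
               "not present")
})

test_that("interaction fits recover noiseless coefficients exactly", {
  d <- random_model_frame(90, seed = 106)
  z <- function(x) (x - mean(x)) / sd(x)
  ez <- z(d$edu_num); bz <- z(d$burden_global_cognition)
  y <- 0.4 * ez + 0.2 * bz - 0.25 * ez * bz
  d$global_cognition <- y / sd(y)
  lam <- 1 / sd(y)
  fit <- suppressWarnings(
    education_burden_interaction_fit(d, "global_cognition", adjusted = FALSE))
  expect_equal(fit$coef[["edu_z"]], 0.4 * lam, tolerance = 1e-9)
  expect_equal(fit$coef[["burden_z"]], 0.2 * lam, tolerance = 1e-9)
  expect_equal(fit$coef[["edu_x_burden"]], -0.25 * lam, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
})

test_that("simple slopes obey the linear identities and the refit oracle", {
  for (s in 1:10) {
    d <- random_model_frame(60, seed = 200 + s)
    d$global_cognition <- with(d, 0.3 * edu_num - 0.2 * burden_global_cognition) +
      0.1 * d$edu_num * d$burden_global_cognition + rnorm(60)
    fit <- education_burden_interaction_fit(d, "global_cognition")
    ss <- simple_slopes(fit)
    expect_equal(ss$slope[ss$level == 0], fit$coef[["edu_z"]])
    expect_equal(ss$slope[ss$level == -1] - ss$slope[ss$level == 1],
                 -2 * fit$coef[["edu_x_burden"]], tolerance = 1e-12)
    # refit oracle: re-center the standardized burden at +/-1 SD
    frame <- cogreserve:::build_model_frame(d, "global_cognition")
    for (m in c(-1, 1)) {
      frame$b_shift <- frame$burden_z - m
      refit <- lm(y ~ edu_z + b_shift + I(edu_z * b_shift) + age_z + sex_male,
                  data = frame)
      expect_equal(ss$slope[ss$level == m], unname(coef(refit)["edu_z"]),
                   tolerance = 1e-10)
      expect_equal(ss$se[ss$level == m],
                   unname(sqrt(diag(vcov(refit))["edu_z"])), tolerance = 1e-10)
    }
  }
})

test_that("Cohen's f2 follows its definition, errors, and thresholds", {
  expect_equal(cohens_f2(0.5, 0.25), 0.5)
  expect_equal(cohens_f2(0.3, 0.3), 0)
  expect_error(cohens_f2(1, 0.5), "< 1")
  expect_error(cohens_f2(0.3, 0.5), "exceed")
  expect_equal(as.character(f2_label(c(0.01, 0.05, 0.2, 0.4))),
               c("negligible", "small", "medium", "large"))
})

test_that("BH adjustment matches the hand-computed example and bounds", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  p <- c(0.001, 0.2, 0.04, 0.9, 0.04)
  adj <- fdr_adjust(p, family = "demo")
  expect_true(all(adj >= p) && all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= 0))  # monotone in raw p
  expect_identical(attr(adj, "family"), "demo")
})

test_that("borderline interaction p-values do not survive a 9-test FDR family", {
  family_d <- c(0.02, 0.04, 0.3, 0.5, 0.6, 0.7, 0.8, 0.9, 0.95)
  adj <- fdr_adjust(family_d)
  expect_true(all(adj[1:2] > 0.05))
})

test_that("the full moderation battery produces coherent tidy tables", {
  coh <- score_cohort(generate_cohort(small_spec(seed = 55)))
  wb <- add_burden_scores(coh, n_replications = 10, per_group_draw = 30, seed = 1)
  res <- run_moderation_analysis(wb$scored)
  expect_equal(nrow(res$ancova), 3)
  expect_equal(nrow(res$stratified), 9)
  expect_equal(nrow(res$slope_comparisons), 9)
  expect_equal(nrow(res$interactions), 9)
  expect_equal(nrow(res$simple_slopes), 27)
  expect_true(all(res$stratified$p_fdr >= res$stratified$p_raw))
  expect_true(all(res$interactions$n <= c(SCD = 40, MCI = 60, AD = 80)[res$interactions$group]))
  # slope at 0 SD equals the stratified-model style education main effect
  one <- res$fits$interaction[["global_cognition.SCD"]]
  expect_equal(res$simple_slopes$slope[res$simple_slopes$domain == "global_cognition" &
                                         res$simple_slopes$group == "SCD" &
                                         res$simple_slopes$level == 0],
               one$coef[["edu_z"]])
})
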