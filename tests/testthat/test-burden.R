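test_that("LOOCV-averaged OLS equals a brute-force leave-one-out loop", {
  # n = 6 integer design: oracle loops over the 6 closed-form fits
  X <- cbind(mta = c(0, 1, 2, 3, 1, 2), ga = c(1, 0, 2, 1, 3, 0),
             wmh = c(2, 1, 0, 2, 1, 3))
  y <- c(5, 3, 1, -2, 0, 2)
  brute <- rowMeans(sapply(seq_len(nrow(X)), function(i) {
    Xi <- cbind(1, X[-i, , drop = FALSE])
    drop(solve(crossprod(Xi), crossprod(Xi, y[-i])))
  }))
  fit <- loocv_average_fit(X, y)
  expect_equal(c(fit$intercept, fit$weights), brute,
               tolerance = 1e-10, ignore_attr = TRUE)
  # random designs
  for (s in 1:10) {
    set.seed(s)
    n <- sample(8:20, 1)
    Xr <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("mta", "ga", "wmh")))
    yr <- rnorm(n)
    br <- rowMeans(sapply(seq_len(n), function(i) {
      Xi <- cbind(1, Xr[-i, , drop = FALSE])
      drop(solve(crossprod(Xi), crossprod(Xi, yr[-i])))
    }))
    f <- loocv_average_fit(Xr, yr)
    expect_equal(c(f$intercept, f$weights), br, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("LOOCV averaging is exact on noiseless data and degenerate on constants", {
  set.seed(2)
  X <- matrix(sample(0:4, 45, replace = TRUE), 15, 3,
              dimnames = list(NULL, c("mta", "ga", "wmh")))
  y <- 2 - 0.3 * X[, 1] - 0.2 * X[, 2] - 0.15 * X[, 3]
  fit <- loocv_average_fit(X, y)
  expect_equal(fit$intercept, 2, tolerance = 1e-10)
  expect_equal(unname(fit$weights), c(-0.3, -0.2, -0.15), tolerance = 1e-10)
  const <- loocv_average_fit(X, rep(3, 15))
  expect_equal(unname(const$weights), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(const$intercept, 3, tolerance = 1e-12)
  # rank deficiency is a named error
  Xbad <- X; Xbad[, 3] <- Xbad[, 1]
  expect_error(loocv_average_fit(Xbad, y), "singular")
})

test_that("burden bootstrap stratifies, is deterministic, and errors on small groups", {
  coh <- score_cohort(generate_cohort(small_spec(seed = 21)))
  m1 <- fit_burden_model(coh, "global_cognition", n_replications = 8,
                         per_group_draw = 30, seed = 5)
  m2 <- fit_burden_model(coh, "global_cognition", n_replications = 8,
                         per_group_draw = 30, seed = 5)
  expect_identical(m1$replication_coefs, m2$replication_coefs)
  expect_equal(dim(m1$replication_coefs), c(8L, 4L))
  expect_equal(unname(m1$weights), unname(colMeans(m1$replication_coefs)[-1]))
  expect_error(fit_burden_model(coh, "global_cognition", per_group_draw = 50),
               "SCD")
})

test_that("degenerate bootstrap (1 rep, full groups) equals pooled LOOCV fit", {
  coh <- score_cohort(generate_cohort(small_spec(seed = 22)))
  keep <- complete.cases(coh[, c("global_cognition", "mta", "ga", "wmh")])
  d <- coh[keep, ]
  sizes <- table(d$diagnosis)
  expect_true(length(unique(sizes)) > 1)  # guard: groups really differ in size
  m <- fit_burden_model(d, "global_cognition", n_replications = 1,
                        per_group_draw = min(sizes), seed = 1)
  # draw = full group size only matches when all groups are equal; subset to equal groups
  eq <- do.call(rbind, lapply(split(d, d$diagnosis), function(g) g[seq_len(min(sizes)), ]))
  m_eq <- fit_burden_model(eq, "global_cognition", n_replications = 1,
                           per_group_draw = min(sizes), seed = 1)
  pooled <- loocv_average_fit(as.matrix(eq[, c("mta", "ga", "wmh")]),
                              eq$global_cognition)
  expect_equal(m_eq$intercept, pooled$intercept, tolerance = 1e-12)
  expect_equal(m_eq$weights, pooled$weights, tolerance = 1e-12)
  expect_s3_class(m, "burden_model")
})

test_that("burden scores invert the predictor and ignore the intercept after scaling", {
  coh <- score_cohort(generate_cohort(small_spec(seed = 23)))
  m <- fit_burden_model(coh, "global_cognition", n_replications = 5,
                        per_group_draw = 30, seed = 2)
  m_toy <- m
  m_toy$intercept <- 0
  m_toy$weights <- c(mta = -1, ga = 0, wmh = 0)
  ratings <- data.frame(mta = c(0, 1, 2), ga = c(1, 1, 1), wmh = c(2, 0, 1))
  b <- compute_burden(m_toy, ratings, standardize = FALSE)
  expect_equal(as.numeric(b), c(0, 1, 2))  # burden increases with MTA
  # identical ratings -> identical burden
  same <- compute_burden(m, data.frame(mta = c(2, 2), ga = c(1, 1), wmh = c(3, 3)),
                         standardize = FALSE)
  expect_equal(same[1], same[2])
  # the intercept is inconsequential once standardized
  shifted <- m; shifted$intercept <- m$intercept + 5
  expect_equal(as.numeric(compute_burden(m, coh)),
               as.numeric(compute_burden(shifted, coh)), tolerance = 1e-12)
  # negative weights: burden strictly increasing in each rating
  neg <- m; neg$weights <- c(mta = -0.3, ga = -0.2, wmh = -0.15); neg$intercept <- 1
  grid <- expand.grid(mta = 0:4, ga = 0:3, wmh = 0:3)
  raw <- attr(compute_burden(neg, grid), "raw")
  for (v in c("mta", "ga", "wmh")) {
    others <- setdiff(c("mta", "ga", "wmh"), v)
    key <- interaction(grid[, others])
    expect_true(all(tapply(seq_len(nrow(grid)), key, function(i)
      all(diff(raw[i][order(grid[[v]][i])]) > 0))))
  }
})

test_that("burden parameters converge to full-sample OLS in large homogeneous cohorts", {
  zero <- stats::setNames(rep(0, 3), cognitive_domains())
  spec <- sim_spec(group_sizes = c(SCD = 667L, MCI = 667L, AD = 666L),
                   domain_means = list(SCD = zero, MCI = zero, AD = zero),
                   education_slopes = list(SCD = zero, MCI = zero, AD = zero),
                   interaction_coefs = list(SCD = zero, MCI = zero, AD = zero),
                   age_slope = 0, sex_effect = 0, seed = 13)
  coh <- generate_cohort(spec)
  m <- fit_burden_model(coh, "latent_global_cognition", n_replications = 100,
                        per_group_draw = 300, seed = 7)
  full <- lm(latent_global_cognition ~ mta + ga + wmh, data = coh)
  expect_lt(max(abs(m$weights - coef(full)[-1])), 0.02)
})

test_that("parameter spread across seeds shrinks as replications grow", {
  coh <- score_cohort(generate_cohort(default_sim_spec(seed = 29)))
  spread <- function(reps) {
    w <- sapply(1:12, function(s)
      fit_burden_model(coh, "global_cognition", n_replications = reps,
                       per_group_draw = 75, seed = s)$weights["mta"])
    sd(w)
  }
  expect_lt(spread(100), spread(10))
})
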