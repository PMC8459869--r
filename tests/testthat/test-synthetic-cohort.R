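test_that("the default spec yields 543 participants in 108/190/245 groups", {
  coh <- generate_cohort(default_sim_spec(seed = 3))
  expect_equal(nrow(coh), 543)
  expect_equal(as.integer(table(coh$diagnosis)), c(108, 190, 245))
  expect_equal(anyDuplicated(coh$id), 0)
})

test_that("cohort generation is deterministic and seed-sensitive", {
  expect_identical(generate_cohort(default_sim_spec(seed = 7)),
                   generate_cohort(default_sim_spec(seed = 7)))
  expect_false(identical(generate_cohort(small_spec(seed = 1)),
                         generate_cohort(small_spec(seed = 2))))
  # generation does not perturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_cohort(small_spec())); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("invalid specs fail with errors naming the field", {
  expect_error(sim_spec(group_sizes = c(SCD = -1L, MCI = 10L, AD = 10L)),
               "group_sizes")
  bad_edu <- list(SCD = rep(1 / 7, 7), MCI = rep(1 / 7, 7),
                  AD = c(rep(0.2, 5), 0.1, 0))
  expect_error(sim_spec(education_probs = bad_edu), "education_probs")
  expect_error(sim_spec(rating_params = modifyList(
    formals(sim_spec)$rating_params |> eval(),
    list(mta = list(SCD = c(0.5, 0.5), MCI = c(0.5, 0.5), AD = c(0.5, 0.5))))),
    "rating_params\\$mta")
  expect_error(sim_spec(domain_noise_sd = c(global_cognition = 0,
                                            episodic_memory = 0.5,
                                            executive = 0.5)),
               "domain_noise_sd")
})

test_that("with zero noise and degenerate covariates, scores depend on ratings only", {
  zero <- stats::setNames(rep(0, 3), cognitive_domains())
  one_level <- c(0, 0, 0, 1, 0, 0, 0)  # everyone Verhage 4
  tn <- c("mmse", "vat", "word8_imm", "word8_del", "fluency", "fab",
          "tmt_a_sec", "tmt_b_sec")
  spec <- sim_spec(
    group_sizes = c(SCD = 60L, MCI = 0L, AD = 0L),
    education_probs = list(SCD = one_level, MCI = one_level, AD = one_level),
    age_params = list(SCD = c(median = 70, q1 = 69.999, q3 = 70.001),
                      MCI = c(median = 78, q1 = 73, q3 = 82),
                      AD = c(median = 80, q1 = 76, q3 = 84)),
    sex_prob = c(SCD = 0, MCI = 0, AD = 0),
    interaction_coefs = list(SCD = zero, MCI = zero, AD = zero),
    domain_noise_sd = stats::setNames(rep(1e-12, 3), cognitive_domains()),
    noise_sd = stats::setNames(rep(1e-12, length(tn)), tn),
    seed = 5L)
  coh <- generate_cohort(spec)
  key <- paste(coh$mta, coh$ga, coh$wmh)
  # latent scores are a pure function of the ratings
  for (d in cognitive_domains()) {
    spread <- tapply(coh[[paste0("latent_", d)]], key,
                     function(v) diff(range(v)))
    expect_lt(max(spread), 1e-9)
  }
  # and so are raw scores, up to rounding of the noiseless affine map
  for (t in c("mmse", "fluency"))
    expect_true(all(tapply(coh[[t]], key,
                           function(v) diff(range(v))) <= 1))
})

test_that("default marginals hit the documented medians, IQRs within one unit", {
  spec <- default_sim_spec(seed = 1)
  spec$group_sizes <- spec$group_sizes * 20L   # n scaled x20 for calibration
  coh <- generate_cohort(spec)
  targets <- cohort_marginal_targets()
  for (i in seq_len(nrow(targets))) {
    x <- coh[coh$diagnosis == targets$group[i], targets$variable[i]]
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 1)
    expect_equal(unname(q[2]), targets$median[i],
                 label = sprintf("%s/%s median", targets$variable[i], targets$group[i]))
    expect_lte(abs(q[1] - targets$q1[i]), 1)
    expect_lte(abs(q[3] - targets$q3[i]), 1)
  }
})

test_that("rating draws respect the scale supports and rank-correlate", {
  coh <- generate_cohort(default_sim_spec(seed = 2))
  expect_true(all(coh$mta %in% 0:4))
  expect_true(all(coh$ga %in% 0:3))
  expect_true(all(coh$wmh %in% 0:3))
  expect_true(all(coh$verhage %in% 1:7))
  rho <- cor(coh$mta, coh$ga, method = "spearman")
  expect_gt(rho, 0.2); expect_lt(rho, 0.6)
})

test_that("education slopes are recovered from the latent domain scores", {
  spec <- sim_spec(group_sizes = c(SCD = 5000L, MCI = 0L, AD = 0L), seed = 31)
  coh <- generate_cohort(spec)
  z_edu <- as.numeric(scale(coh$verhage))
  fit <- lm(coh$latent_global_cognition ~ z_edu)
  mc_se <- summary(fit)$coefficients["z_edu", "Std. Error"]
  expect_lt(abs(coef(fit)[["z_edu"]] - 0.60), 2 * mc_se)
})

test_that("TMT-B non-completion concentrates in MCI/AD and poor executives", {
  coh <- generate_cohort(default_sim_spec(seed = 17))
  rates <- tapply(!coh$tmt_b_completed, coh$diagnosis, mean)
  expect_lt(rates[["SCD"]], rates[["MCI"]])
  expect_true(is.na(coh$tmt_b_sec[!coh$tmt_b_completed]) |> all())
  expect_lt(mean(coh$latent_executive[!coh$tmt_b_completed]),
            mean(coh$latent_executive[coh$tmt_b_completed]))
})

test_that("the synthetic norm table is deterministic with positive SDs", {
  spec <- default_sim_spec(seed = 4)
  nt1 <- synthetic_norm_table(spec, n_reference = 2000L)
  nt2 <- synthetic_norm_table(spec, n_reference = 2000L)
  expect_identical(nt1, nt2)
  expect_true(all(nt1$sd > 0))
  expect_setequal(unique(nt1$test),
                  c("mmse", "vat", "word8_imm", "word8_del", "fluency", "fab",
                    "tmt_a_sec", "tmt_b_sec", "tmt_ratio"))
  # a score equal to its cell mean has norm z 0; one SD above has norm z 1
  cell <- nt1[nt1$test == "mmse" & nt1$age_band == "65-74" &
                nt1$education == "average", ]
  coh <- data.frame(age = c(70, 70), verhage = c(4, 4),
                    mmse = c(cell$mean, cell$mean + cell$sd))
  z <- norm_scores(coh, nt1[nt1$test == "mmse", ])
  expect_equal(z$mmse, c(0, 1))
})

test_that("sim specs survive a JSON round trip", {
  spec <- small_spec(seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_sim_spec(spec, path)
  back <- read_sim_spec(path)
  expect_equal(back, spec)
  expect_identical(generate_cohort(back), generate_cohort(spec))
})
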