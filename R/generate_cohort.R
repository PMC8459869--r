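# Synthetic cohort generation. Draw order within a call is fixed and
# documented so adding downstream fields never reshuffles earlier draws:
# per group (SCD, MCI, AD): age -> sex -> education -> rating copula;
# then cohort-wide: per-domain latent noise (domain order of
# cognitive_domains()) -> per-test noise (test order of test_names()) ->
# TMT-B completion.

draw_two_piece <- function(n, params) {
  m <- params[["median"]]
  s_lo <- (m - params[["q1"]]) / stats::qnorm(0.75)
  s_hi <- (params[["q3"]] - m) / stats::qnorm(0.75)
  side <- stats::runif(n) < 0.5
  dev <- abs(stats::rnorm(n))
  x <- ifelse(side, m - dev * s_lo, m + dev * s_hi)
  pmin(pmax(round(x), 50), 98)
}

# Gaussian copula draw of the three ordinal ratings with Spearman rank
# correlation rho_s between every pair (converted to the latent Pearson
# correlation with the standard 2*sin(pi*rho_s/6) identity).
draw_ratings <- function(n, rating_params, group, rank_cor) {
  rho <- 2 * sin(pi * rank_cor / 6)
  R <- matrix(rho, 3, 3); diag(R) <- 1
  z <- matrix(stats::rnorm(3 * n), n, 3) %*% chol(R)
  u <- stats::pnorm(z)
  out <- list()
  for (j in seq_along(c("mta", "ga", "wmh"))) {
    r <- c("mta", "ga", "wmh")[j]
    p <- rating_params[[r]][[group]]
    out[[r]] <- as.integer(cut(u[, j], breaks = c(0, cumsum(p) / sum(p)),
                               labels = FALSE, include.lowest = TRUE)) - 1L
  }
  out
}

#' Generate a synthetic memory-clinic cohort
#'
#' Draws a cohort of participant records from a [sim_spec()]: demographics,
#' Verhage education level, visual MRI ratings (MTA, GA, WMH), latent
#' cognitive domain scores and raw neuropsychological test scores, with Trail
#' Making Test part B non-completion concentrated in poor executive
#' performers and in the MCI/AD groups. The output is a deterministic
#' function of the spec (including its seed).
#'
#' Besides the observable columns, the cohort carries the generating truths
#' needed for method validation: `latent_<domain>` (the latent domain score
#' the raw tests are noisy maps of) and `latent_path_<domain>` (the
#' cognition-relevant pathology contribution `w'x`; lower = more pathology).
#' These columns exist only in synthetic data and are excluded from the
#' pipeline's cohort CSV.
#'
#' @param spec a [sim_spec()].
#' @return data.frame with one row per participant; attribute `n_clipped`
#'   records per-test counts of scores clipped to the instrument range.
#' @examples
#' coh <- generate_cohort(sim_spec(seed = 7))
#' nrow(coh)              # 543
#' table(coh$diagnosis)
#' @export
generate_cohort <- function(spec) {
  validate_sim_spec(spec)
  with_seed(spec$seed, {
    parts <- list()
    for (g in diagnosis_levels()) {
      n <- spec$group_sizes[[g]]
      if (n == 0L) next
      age <- draw_two_piece(n, spec$age_params[[g]])
      sex <- ifelse(stats::runif(n) < spec$sex_prob[[g]], "male", "female")
      verhage <- sample.int(7L, n, replace = TRUE, prob = spec$education_probs[[g]])
      rt <- draw_ratings(n, spec$rating_params, g, spec$rating_rank_cor)
      parts[[g]] <- data.frame(diagnosis = g, age = age, sex = sex,
                               verhage = verhage, mta = rt$mta, ga = rt$ga,
                               wmh = rt$wmh, stringsAsFactors = FALSE)
    }
    coh <- do.call(rbind, parts)
    rownames(coh) <- NULL
    coh <- cbind(id = sprintf("P%04d", seq_len(nrow(coh))), coh,
                 stringsAsFactors = FALSE)
    coh$diagnosis <- factor(coh$diagnosis, levels = diagnosis_levels())
    male <- as.numeric(coh$sex == "male")
    X <- as.matrix(coh[, c("mta", "ga", "wmh")])
    z_edu <- group_zscore(coh$verhage, coh$diagnosis)
    z_age <- group_zscore(coh$age, coh$diagnosis)

    pick <- function(field, d)
      vapply(as.character(coh$diagnosis), function(g) spec[[field]][[g]][[d]], 0)
    for (d in cognitive_domains()) {
      w <- spec$true_pathology_weights[[d]][c("mta", "ga", "wmh")]
      path <- drop(X %*% w)
      z_burden <- group_zscore(-path, coh$diagnosis)
      lat <- pick("domain_means", d) + path +
        pick("education_slopes", d) * z_edu +
        pick("interaction_coefs", d) * z_edu * z_burden +
        spec$age_slope * z_age + spec$sex_effect * male +
        stats::rnorm(nrow(coh), 0, spec$domain_noise_sd[[d]])
      coh[[paste0("latent_", d)]] <- lat
      coh[[paste0("latent_path_", d)]] <- path
    }

    n_clipped <- stats::setNames(integer(length(test_names())), test_names())
    for (t in test_names()) {
      tp <- spec$test_params[[t]]
      raw <- tp$intercept + tp$loading * coh[[paste0("latent_", tp$domain)]] +
        stats::rnorm(nrow(coh), 0, spec$noise_sd[[t]])
      raw <- round(raw)
      clip <- raw < tp$range[1] | raw > tp$range[2]
      n_clipped[[t]] <- sum(clip)
      coh[[t]] <- pmin(pmax(raw, tp$range[1]), tp$range[2])
    }

    lat_ex <- coh$latent_executive
    centred <- lat_ex - stats::ave(lat_ex, coh$diagnosis)
    off <- spec$tmt_b_dropout$offsets[as.character(coh$diagnosis)]
    p_non <- stats::plogis(off - spec$tmt_b_dropout$slope * centred)
    non <- stats::runif(nrow(coh)) < p_non
    coh$tmt_b_completed <- !non
    coh$tmt_b_sec[non] <- NA_real_
    attr(coh, "n_clipped") <- n_clipped
    coh
  })
}

#' Synthetic normative table for norm-score sensitivity analyses
#'
#' Builds a per-test normative table (age band x education category cells,
#' each with a mean and SD) from a large simulated healthy reference sample,
#' standing in for population normative databases that adjust test scores for
#' age and education. The reference sample reuses the spec's SCD (cognitively
#' healthiest) generating parameters with a widened age distribution so all
#' cohort age bands are populated, and is drawn under a fixed internal seed:
#' the table is a deterministic function of the spec alone. The table is
#' explicitly synthetic; it is not derived from any published norms.
#'
#' @param spec a [sim_spec()]; cell statistics reflect its SCD parameters.
#' @param n_reference size of the simulated reference sample.
#' @return data.frame with columns `test`, `age_band`, `education`, `mean`,
#'   `sd`, `n`; covers the derived TMT ratio as well as the raw tests. Age
#'   bands are `50-64`, `65-74`, `75+`; education categories follow
#'   [categorize_education()].
#' @export
synthetic_norm_table <- function(spec, n_reference = 6000L) {
  validate_sim_spec(spec)
  ref_spec <- spec
  ref_spec$group_sizes <- c(SCD = as.integer(n_reference), MCI = 0L, AD = 0L)
  ref_spec$age_params$SCD <- c(median = 73, q1 = 64, q3 = 81)
  ref_spec$seed <- 987654301L  # fixed internal seed, independent of spec$seed
  ref <- generate_cohort(ref_spec)
  ref$tmt_ratio <- ifelse(ref$tmt_b_completed, ref$tmt_b_sec / ref$tmt_a_sec, NA_real_)
  bands <- age_band(ref$age)
  edu <- categorize_education(ref$verhage)
  tests <- c(test_names(), "tmt_ratio")
  rows <- list()
  for (t in tests) {
    agg <- stats::aggregate(ref[[t]],
                            by = list(age_band = bands, education = edu),
                            FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                                sd = stats::sd(v, na.rm = TRUE),
                                                n = sum(!is.na(v))))
    rows[[t]] <- data.frame(test = t, age_band = agg$age_band,
                            education = agg$education,
                            mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                            n = agg$x[, "n"], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(all(out$sd > 0))
  out
}

#' @keywords internal
age_band <- function(age) {
  cut(age, breaks = c(-Inf, 64.5, 74.5, Inf),
      labels = c("50-64", "65-74", "75+"))
}
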