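# Sensitivity analyses: each variant re-runs the main scoring/burden/
# inference code paths under altered inputs and summarizes concordance with
# the main analysis, so a fix in the pipeline propagates to every variant.

variant_analysis <- function(scored_main, cohort, map = default_domain_map(),
                             norm_table = NULL, burden_reps = 100L,
                             burden_draw = 75L, seed = 1L) {
  scored <- score_cohort(cohort, map = map, norm_table = norm_table)
  wb <- add_burden_scores(scored, n_replications = burden_reps,
                          per_group_draw = burden_draw, seed = seed)
  list(scored = wb$scored, models = wb$models,
       results = run_moderation_analysis(wb$scored))
}

#' Concordance between a variant's results and the main analysis
#'
#' Counts, across the stratified education effects and the
#' education-by-burden interactions, how often the variant agrees with the
#' main analysis in coefficient sign and in uncorrected significance at
#' alpha = 0.05.
#'
#' @param main,variant `moderation_results` objects.
#' @return data.frame with one row per result set: proportion of sign
#'   agreement, number of sign flips, and proportion of significance
#'   agreement.
#' @export
concordance_summary <- function(main, variant) {
  one <- function(name, beta_col) {
    a <- main[[name]]; b <- variant[[name]]
    key <- paste(a$domain, a$group)
    m <- match(key, paste(b$domain, b$group))
    sa <- sign(a[[beta_col]]) == sign(b[[beta_col]][m])
    ga <- (a$p_raw < 0.05) == (b$p_raw[m] < 0.05)
    data.frame(result_set = name, n = length(sa),
               sign_agreement = mean(sa), sign_flips = sum(!sa),
               significance_agreement = mean(ga))
  }
  out <- rbind(one("stratified", "beta_edu"), one("interactions", "beta_int"))
  rownames(out) <- NULL
  out
}

new_sensitivity_report <- function(variant, analysis, main_results, extra = list()) {
  structure(c(list(variant = variant, results = analysis$results,
                   models = analysis$models,
                   concordance = concordance_summary(main_results,
                                                     analysis$results)),
              extra),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity analysis: %s\n\nConcordance with the main analysis:\n",
              x$variant))
  print(x$concordance, row.names = FALSE)
  if (!is.null(x$drivers)) {
    cat("\nInteraction driver flags:\n")
    print(x$drivers, row.names = FALSE)
  }
  invisible(x)
}

#' Norm-score sensitivity analysis
#'
#' Re-runs the whole pipeline with compound scores built from normative
#' (age-band x education-cell) z-scores instead of whole-sample z-scores.
#' Because norms condition on education, education-related variance is
#' partly absorbed and education effects are expected to attenuate.
#'
#' @param cohort raw cohort.
#' @param norm_table normative table ([synthetic_norm_table()]).
#' @param main_results main-analysis `moderation_results`; computed from the
#'   cohort if omitted.
#' @param burden_reps,burden_draw,seed burden-model settings (matched to the
#'   main analysis for comparability).
#' @return a `sensitivity_report`.
#' @export
run_norm_score_variant <- function(cohort, norm_table, main_results = NULL,
                                   burden_reps = 100L, burden_draw = 75L,
                                   seed = 1L) {
  if (is.null(main_results))
    main_results <- variant_analysis(NULL, cohort, burden_reps = burden_reps,
                                     burden_draw = burden_draw, seed = seed)$results
  a <- variant_analysis(NULL, cohort, norm_table = norm_table,
                        burden_reps = burden_reps, burden_draw = burden_draw,
                        seed = seed)
  new_sensitivity_report("norm_scores", a, main_results)
}

#' Reduced-compound sensitivity analysis
#'
#' Re-runs the pipeline with compound scores that exclude the two
#' floor-prone sub-tests (TMT ratio and 8-Word delayed recall); episodic
#' memory becomes VAT + immediate recall, executive becomes fluency + FAB.
#'
#' @inheritParams run_norm_score_variant
#' @return a `sensitivity_report`.
#' @export
run_reduced_compound_variant <- function(cohort, main_results = NULL,
                                         burden_reps = 100L, burden_draw = 75L,
                                         seed = 1L) {
  if (is.null(main_results))
    main_results <- variant_analysis(NULL, cohort, burden_reps = burden_reps,
                                     burden_draw = burden_draw, seed = seed)$results
  a <- variant_analysis(NULL, cohort, map = reduced_domain_map(),
                        burden_reps = burden_reps, burden_draw = burden_draw,
                        seed = seed)
  new_sensitivity_report("reduced_compounds", a, main_results)
}

#' Single-rating sensitivity analysis
#'
#' Replaces the composite burden moderator with one visual MRI rating
#' (z-scored) in the education interaction, adjusting for the other two
#' ratings, for every domain and diagnosis group.
#'
#' @param cohort raw cohort.
#' @param rating one of `"mta"`, `"ga"`, `"wmh"`.
#' @param main_results main-analysis `moderation_results` (computed if
#'   omitted); concordance is reported against its interaction table.
#' @param burden_reps,burden_draw,seed burden-model settings for the
#'   covariate burden scores of the stratified models.
#' @return a `sensitivity_report` whose `results$interactions` table holds
#'   the education-by-rating interactions.
#' @export
run_single_rating_variant <- function(cohort, rating = c("mta", "ga", "wmh"),
                                      main_results = NULL,
                                      burden_reps = 100L, burden_draw = 75L,
                                      seed = 1L) {
  rating <- match.arg(rating)
  others <- setdiff(c("mta", "ga", "wmh"), rating)
  scored <- score_cohort(cohort)
  wb <- add_burden_scores(scored, n_replications = burden_reps,
                          per_group_draw = burden_draw, seed = seed)
  scored <- wb$scored
  if (is.null(main_results)) main_results <- run_moderation_analysis(scored)
  groups <- levels(droplevels(factor(scored$diagnosis)))
  rows <- list(); ss <- list(); fits <- list()
  for (d in cognitive_domains()) {
    for (g in groups) {
      gd <- scored[scored$diagnosis == g, , drop = FALSE]
      fi <- education_burden_interaction_fit(gd, d, moderator_col = rating,
                                             covariate_cols = others)
      fits[[paste(d, g, sep = ".")]] <- fi
      rows[[paste(d, g)]] <- data.frame(
        domain = d, group = g, rating = rating,
        beta_int = fi$coef[["edu_x_burden"]], se = fi$se[["edu_x_burden"]],
        p_raw = fi$p[["edu_x_burden"]], ci_low = fi$ci_int[1],
        ci_high = fi$ci_int[2], n = fi$n, f2 = fi$f2_int)
      s <- simple_slopes(fi)
      ss[[paste(d, g)]] <- cbind(domain = d, group = g, rating = rating,
                                 as.data.frame(s))
    }
  }
  interactions <- do.call(rbind, rows); rownames(interactions) <- NULL
  interactions$p_fdr <- fdr_adjust(interactions$p_raw,
                                   family = paste0("D:", rating))
  results <- structure(list(ancova = main_results$ancova,
                            stratified = main_results$stratified,
                            slope_comparisons = main_results$slope_comparisons,
                            interactions = interactions,
                            simple_slopes = do.call(rbind, ss),
                            fits = list(interaction = fits)),
                       class = "moderation_results")
  analysis <- list(scored = scored, models = wb$models, results = results)
  new_sensitivity_report(paste0("single_rating_", rating), analysis, main_results)
}

#' Flag the rating driving each education-by-neuropathology interaction
#'
#' Runs the single-rating variant for all three visual ratings and flags,
#' per domain and diagnosis group, the rating with the largest-magnitude
#' standardized interaction coefficient among those with uncorrected
#' p < 0.05 (no rating is flagged when none reaches significance).
#'
#' @inheritParams run_single_rating_variant
#' @param alpha uncorrected significance threshold for flagging.
#' @return data.frame with one row per domain x group: the candidate
#'   interactions and the flagged `driver` (`NA` when none qualifies).
#' @export
find_interaction_drivers <- function(cohort, main_results = NULL,
                                     burden_reps = 100L, burden_draw = 75L,
                                     seed = 1L, alpha = 0.05) {
  reps <- lapply(c("mta", "ga", "wmh"), function(r)
    run_single_rating_variant(cohort, r, main_results = main_results,
                              burden_reps = burden_reps,
                              burden_draw = burden_draw, seed = seed))
  all_int <- do.call(rbind, lapply(reps, function(r) r$results$interactions))
  out <- list()
  for (key in unique(paste(all_int$domain, all_int$group))) {
    sub <- all_int[paste(all_int$domain, all_int$group) == key, ]
    eligible <- sub[sub$p_raw < alpha, ]
    driver <- if (nrow(eligible) > 0)
      eligible$rating[which.max(abs(eligible$beta_int))] else NA_character_
    out[[key]] <- data.frame(domain = sub$domain[1], group = sub$group[1],
                             driver = driver,
                             beta_mta = sub$beta_int[sub$rating == "mta"],
                             p_mta = sub$p_raw[sub$rating == "mta"],
                             beta_ga = sub$beta_int[sub$rating == "ga"],
                             p_ga = sub$p_raw[sub$rating == "ga"],
                             beta_wmh = sub$beta_int[sub$rating == "wmh"],
                             p_wmh = sub$p_raw[sub$rating == "wmh"])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
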