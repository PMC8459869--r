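# Moderation-inference battery: ANCOVA interaction, stratified education
# models, Welch slope comparisons, education x burden interactions, simple
# slopes, Cohen's f2, BH-FDR. All model variables are z-scored on the rows
# entering each model (listwise deletion first), education is the 3-level
# category coded 1/2/3 and then z-scored, sex stays a binary indicator.

#' Z-score selected columns of a table
#'
#' Standardizes the listed numeric columns in place using the whole-table
#' mean and sample SD; intended to be applied after listwise deletion so the
#' scaling sample equals the modeling sample.
#'
#' @param table data.frame.
#' @param variables character vector of column names.
#' @return `table` with the listed columns z-scored.
#' @export
scale_variables <- function(table, variables) {
  for (v in variables) {
    if (!v %in% names(table))
      stop(sprintf("scale_variables(): no column '%s'", v), call. = FALSE)
    table[[v]] <- zscore_sample(table[[v]])
  }
  table
}

# Assemble the standardized modeling frame for one domain within one group
# (or pooled). Listwise deletion over the needed columns, then z-scoring.
build_model_frame <- function(data, domain, extra_cols = character()) {
  burden_col <- paste0("burden_", domain)
  need <- c(domain, "edu_num", "age", "sex", burden_col, extra_cols)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop(sprintf("missing columns: %s", paste(miss, collapse = ", ")), call. = FALSE)
  d <- data[stats::complete.cases(data[, need]), , drop = FALSE]
  if (nrow(d) < 10L)
    stop(sprintf("fewer than 10 complete rows for %s", domain), call. = FALSE)
  out <- data.frame(y = zscore_sample(d[[domain]]),
                    edu_z = zscore_sample(as.numeric(d$edu_num)),
                    age_z = zscore_sample(d$age),
                    sex_male = as.numeric(d$sex == "male"),
                    burden_z = zscore_sample(d[[burden_col]]))
  for (v in extra_cols) out[[paste0(v, "_z")]] <- zscore_sample(as.numeric(d[[v]]))
  if ("diagnosis" %in% names(d)) out$diagnosis <- factor(d$diagnosis)
  out
}

# f2 for nested fits, tolerating the numerically perfect fits that arise in
# noiseless validation data (f2 is infinite there, not an error)
nested_f2 <- function(r2_full, r2_reduced) {
  if (r2_full >= 1 - 1e-12) return(Inf)
  cohens_f2(min(r2_full, 1), min(r2_reduced, r2_full))
}

new_mod_fit <- function(fit, outcome, n, extra = list()) {
  s <- summary(fit)
  cf <- s$coefficients
  structure(c(list(outcome = outcome, terms = rownames(cf),
                   coef = cf[, "Estimate"], se = cf[, "Std. Error"],
                   t = cf[, "t value"], p = cf[, "Pr(>|t|)"],
                   df_residual = fit$df.residual, r2 = s$r.squared,
                   vcov = stats::vcov(fit), n = n), extra),
            class = "mod_fit")
}

#' @export
print.mod_fit <- function(x, ...) {
  cat(sprintf("Linear model for %s (n = %d, residual df = %d, R2 = %.3f)\n",
              x$outcome, x$n, x$df_residual, x$r2))
  print(data.frame(term = x$terms, beta = round(x$coef, 4),
                   se = round(x$se, 4), t = round(x$t, 3),
                   p = signif(x$p, 3), row.names = NULL))
  invisible(x)
}

#' Education-by-diagnosis ANCOVA interaction test
#'
#' Tests whether the association between education and a cognitive domain
#' differs across diagnosis groups: the domain score is regressed on
#' z-scored education, diagnosis, their interaction, and z-scored age, sex
#' and domain-specific burden; the interaction block is tested with a
#' nested-model F, `F = ((RSS_r - RSS_f)/df_delta) / (RSS_f/df_f)`, with
#' numerator df = (number of diagnosis levels - 1).
#'
#' @param data scored cohort with burden columns (pooled across groups).
#' @param domain cognitive domain column name.
#' @param adjusted include age, sex and burden covariates (default `TRUE`).
#' @return list of class `ancova_interaction`: `F`, `df1`, `df2`, `p`, `n`,
#'   `r2_full`, `r2_reduced` and the two underlying `lm` fits.
#' @export
ancova_interaction <- function(data, domain, adjusted = TRUE) {
  d <- build_model_frame(data, domain)
  if (nlevels(droplevels(d$diagnosis)) < 2L)
    stop("ancova_interaction() needs at least 2 diagnosis levels", call. = FALSE)
  d$diagnosis <- droplevels(d$diagnosis)
  rhs <- if (adjusted) "age_z + sex_male + burden_z" else "1"
  f_full <- stats::as.formula(paste("y ~ edu_z * diagnosis +", rhs))
  f_red  <- stats::as.formula(paste("y ~ edu_z + diagnosis +", rhs))
  fit_full <- stats::lm(f_full, data = d)
  fit_red <- stats::lm(f_red, data = d)
  an <- stats::anova(fit_red, fit_full)
  structure(list(domain = domain, F = an$F[2], df1 = an$Df[2],
                 df2 = fit_full$df.residual, p = an$`Pr(>F)`[2],
                 n = nrow(d),
                 r2_full = summary(fit_full)$r.squared,
                 r2_reduced = summary(fit_red)$r.squared,
                 fit_full = fit_full, fit_reduced = fit_red),
            class = "ancova_interaction")
}

#' @export
print.ancova_interaction <- function(x, ...) {
  cat(sprintf("Education x diagnosis interaction on %s: F(%d, %d) = %.3f, p = %.4g (n = %d)\n",
              x$domain, x$df1, x$df2, x$F, x$p, x$n))
  invisible(x)
}

#' Stratified education model within one diagnosis group
#'
#' OLS of the standardized domain score on z-scored education, adjusted for
#' z-scored age, sex and the domain's z-scored neuropathological burden,
#' within a single diagnosis group. The Cohen's f2 of the education term
#' (full vs education-free model) is attached.
#'
#' @param group_data scored rows of one diagnosis group, with burden columns.
#' @param domain cognitive domain column name.
#' @return a `mod_fit` with elements `f2_edu` and `group`.
#' @export
stratified_education_fit <- function(group_data, domain) {
  d <- build_model_frame(group_data, domain)
  fit <- stats::lm(y ~ edu_z + age_z + sex_male + burden_z, data = d)
  fit0 <- stats::lm(y ~ age_z + sex_male + burden_z, data = d)
  grp <- if ("diagnosis" %in% names(d)) as.character(unique(d$diagnosis)) else NA_character_
  new_mod_fit(fit, domain, nrow(d),
              extra = list(group = if (length(grp) == 1) grp else NA_character_,
                           f2_edu = nested_f2(summary(fit)$r.squared,
                                              summary(fit0)$r.squared)))
}

#' Welch t-test comparing a coefficient between two stratified fits
#'
#' Compares the same term (by default the education slope) between two
#' independently fitted group models: `t = (b1 - b2) / sqrt(se1^2 + se2^2)`
#' with Welch-Satterthwaite degrees of freedom computed from each model's
#' residual df, and a two-sided p-value.
#'
#' @param fit1,fit2 `mod_fit` objects.
#' @param term coefficient name present in both fits.
#' @return list of class `slope_comparison`: `pair`, `delta`, `se`, `t`,
#'   `df`, `p`.
#' @export
welch_compare_slopes <- function(fit1, fit2, term = "edu_z") {
  for (f in list(fit1, fit2))
    if (!term %in% f$terms)
      stop(sprintf("term '%s' not present in both fits", term), call. = FALSE)
  b1 <- fit1$coef[[term]]; b2 <- fit2$coef[[term]]
  v1 <- fit1$se[[term]]^2; v2 <- fit2$se[[term]]^2
  se <- sqrt(v1 + v2)
  tval <- (b1 - b2) / se
  df <- (v1 + v2)^2 / (v1^2 / fit1$df_residual + v2^2 / fit2$df_residual)
  structure(list(pair = c(fit1$group %||% "fit1", fit2$group %||% "fit2"),
                 term = term, delta = b1 - b2, se = se, t = tval, df = df,
                 p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE)),
            class = "slope_comparison")
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf("Welch comparison of %s (%s vs %s): delta = %.3f, t = %.3f, df = %.1f, p = %.4g\n",
              x$term, x$pair[1], x$pair[2], x$delta, x$t, x$df, x$p))
  invisible(x)
}

#' Education-by-burden interaction model within one diagnosis group
#'
#' OLS of the standardized domain score on z-scored education, z-scored
#' burden and their product, optionally adjusted for z-scored age and sex.
#' The interaction term is the product of the two z-scored main effects and
#' is deliberately left unstandardized so the simple-slope algebra
#' `slope(m) = b_edu + m * b_int` is exact. The full coefficient covariance
#' is retained for [simple_slopes()]; a 95% CI and the interaction's Cohen's
#' f2 are attached.
#'
#' @param group_data scored rows of one diagnosis group, with burden columns.
#' @param domain cognitive domain column name.
#' @param adjusted include age and sex covariates (default `TRUE`).
#' @param moderator_col optional column to use as the moderator instead of
#'   the domain's burden score (used by the single-rating sensitivity
#'   variant); it is z-scored like every other model variable.
#' @param covariate_cols extra covariate columns, z-scored.
#' @return a `mod_fit` with term names `edu_z`, `burden_z`, `edu_x_burden`
#'   and elements `f2_int`, `ci_int`, `group`.
#' @export
education_burden_interaction_fit <- function(group_data, domain,
                                             adjusted = TRUE,
                                             moderator_col = NULL,
                                             covariate_cols = character()) {
  d <- build_model_frame(group_data, domain,
                         extra_cols = c(moderator_col, covariate_cols))
  if (!is.null(moderator_col)) d$burden_z <- d[[paste0(moderator_col, "_z")]]
  d$edu_x_burden <- d$edu_z * d$burden_z
  rhs <- c("edu_z", "burden_z", "edu_x_burden",
           if (adjusted) c("age_z", "sex_male"),
           if (length(covariate_cols)) paste0(covariate_cols, "_z"))
  fit <- stats::lm(stats::as.formula(paste("y ~", paste(rhs, collapse = " + "))),
                   data = d)
  fit0 <- stats::lm(stats::as.formula(
    paste("y ~", paste(setdiff(rhs, "edu_x_burden"), collapse = " + "))), data = d)
  s <- summary(fit)
  b <- s$coefficients["edu_x_burden", "Estimate"]
  se <- s$coefficients["edu_x_burden", "Std. Error"]
  ci <- b + c(-1, 1) * stats::qt(0.975, fit$df.residual) * se
  grp <- if ("diagnosis" %in% names(d)) as.character(unique(d$diagnosis)) else NA_character_
  new_mod_fit(fit, domain, nrow(d),
              extra = list(group = if (length(grp) == 1) grp else NA_character_,
                           moderator = moderator_col %||% "burden",
                           f2_int = nested_f2(s$r.squared, summary(fit0)$r.squared),
                           ci_int = ci))
}

#' Simple slopes of education at fixed moderator levels
#'
#' Conditional education slopes at moderator values of -1, 0 and +1 SD from
#' an [education_burden_interaction_fit()]:
#' `slope(m) = b_edu + m * b_int`, with
#' `SE(m)^2 = Var(b_edu) + m^2 Var(b_int) + 2 m Cov(b_edu, b_int)` and
#' two-sided p-values on the fit's residual df.
#'
#' @param fit a `mod_fit` containing `edu_z` and `edu_x_burden` terms and
#'   their covariance.
#' @param levels moderator levels in SD units.
#' @return data.frame of class `simple_slopes` with columns `level`,
#'   `slope`, `se`, `t`, `p`.
#' @export
simple_slopes <- function(fit, levels = c(-1, 0, 1)) {
  need <- c("edu_z", "edu_x_burden")
  if (!all(need %in% fit$terms) || is.null(fit$vcov))
    stop("simple_slopes() needs edu_z and edu_x_burden terms with their covariance",
         call. = FALSE)
  V <- fit$vcov
  slope <- fit$coef[["edu_z"]] + levels * fit$coef[["edu_x_burden"]]
  se <- sqrt(V["edu_z", "edu_z"] + levels^2 * V["edu_x_burden", "edu_x_burden"] +
               2 * levels * V["edu_z", "edu_x_burden"])
  tval <- slope / se
  out <- data.frame(level = levels, slope = slope, se = se, t = tval,
                    p = 2 * stats::pt(abs(tval), fit$df_residual, lower.tail = FALSE))
  class(out) <- c("simple_slopes", "data.frame")
  out
}

#' Cohen's f-squared effect size
#'
#' `f2 = (R2_full - R2_reduced) / (1 - R2_full)`; conventional thresholds
#' 0.02, 0.15 and 0.35 mark small, medium and large effects (see
#' [f2_label()]).
#'
#' @param r2_full,r2_reduced R-squared of the full and reduced models.
#' @return numeric f-squared.
#' @export
cohens_f2 <- function(r2_full, r2_reduced) {
  if (any(r2_full >= 1)) stop("cohens_f2(): r2_full must be < 1", call. = FALSE)
  if (any(r2_reduced < 0) || any(r2_full < 0))
    stop("cohens_f2(): R-squared values must be non-negative", call. = FALSE)
  if (any(r2_reduced > r2_full + 1e-12))
    stop("cohens_f2(): r2_reduced cannot exceed r2_full", call. = FALSE)
  pmax(r2_full - r2_reduced, 0) / (1 - r2_full)
}

#' @rdname cohens_f2
#' @param f2 numeric f-squared values.
#' @export
f2_label <- function(f2) {
  cut(f2, breaks = c(-Inf, 0.02, 0.15, 0.35, Inf),
      labels = c("negligible", "small", "medium", "large"), right = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up FDR adjustment of a family of p-values (sort ascending, multiply
#' `p_(i)` by `m/i`, take the cumulative minimum from the largest, cap at 1,
#' restore the original order), delegated to [stats::p.adjust()] after
#' validation.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param family optional family label attached to the result, making the
#'   multiplicity family an explicit, reportable choice.
#' @return adjusted p-values in the original order.
#' @export
fdr_adjust <- function(pvalues, family = NULL) {
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1)))
    stop("fdr_adjust(): p-values must lie in [0, 1]", call. = FALSE)
  out <- stats::p.adjust(pvalues, method = "BH")
  if (!is.null(family)) attr(out, "family") <- family
  out
}

#' Run the full moderation-inference battery on a scored cohort
#'
#' Orchestrates, for every cognitive domain: the education-by-diagnosis
#' ANCOVA interaction, diagnosis-stratified education models, pairwise Welch
#' comparisons of the education slopes, education-by-burden interaction
#' models per group, and simple slopes at -1/0/+1 SD of burden. FDR
#' adjustment is applied within four explicit families: (A) the ANCOVA
#' interaction p-values across domains, (B) the stratified education
#' effects, (C) the slope comparisons, (D) the education-by-burden
#' interactions.
#'
#' @param scored scored cohort with `burden_<domain>` columns (see
#'   [add_burden_scores()]).
#' @param domains domain columns to analyse.
#' @param pairs list of diagnosis pairs for the Welch slope comparisons.
#' @return list of class `moderation_results` with tidy data.frames
#'   `ancova`, `stratified`, `slope_comparisons`, `interactions`,
#'   `simple_slopes`, plus the underlying fits in `fits`.
#' @export
run_moderation_analysis <- function(scored, domains = cognitive_domains(),
                                    pairs = list(c("SCD", "MCI"),
                                                 c("SCD", "AD"),
                                                 c("MCI", "AD"))) {
  groups <- levels(droplevels(factor(scored$diagnosis)))
  anc <- list(); strat <- list(); comp <- list(); intr <- list(); ss <- list()
  fits <- list(stratified = list(), interaction = list())
  for (d in domains) {
    a <- ancova_interaction(scored, d)
    anc[[d]] <- data.frame(domain = d, F = a$F, df1 = a$df1, df2 = a$df2,
                           p_raw = a$p, n = a$n,
                           f2 = cohens_f2(a$r2_full, a$r2_reduced))
    gfits <- list()
    for (g in groups) {
      gd <- scored[scored$diagnosis == g, , drop = FALSE]
      f <- stratified_education_fit(gd, d)
      gfits[[g]] <- f
      strat[[paste(d, g)]] <- data.frame(
        domain = d, group = g, beta_edu = f$coef[["edu_z"]],
        se = f$se[["edu_z"]], t = f$t[["edu_z"]], p_raw = f$p[["edu_z"]],
        df = f$df_residual, n = f$n, f2 = f$f2_edu)
      fi <- education_burden_interaction_fit(gd, d)
      fits$interaction[[paste(d, g, sep = ".")]] <- fi
      intr[[paste(d, g)]] <- data.frame(
        domain = d, group = g, beta_int = fi$coef[["edu_x_burden"]],
        se = fi$se[["edu_x_burden"]], p_raw = fi$p[["edu_x_burden"]],
        ci_low = fi$ci_int[1], ci_high = fi$ci_int[2], n = fi$n,
        f2 = fi$f2_int)
      s <- simple_slopes(fi)
      ss[[paste(d, g)]] <- cbind(domain = d, group = g, as.data.frame(s))
    }
    fits$stratified[[d]] <- gfits
    for (pr in pairs) {
      if (!all(pr %in% names(gfits))) next
      w <- welch_compare_slopes(gfits[[pr[1]]], gfits[[pr[2]]])
      comp[[paste(d, pr[1], pr[2])]] <- data.frame(
        domain = d, group1 = pr[1], group2 = pr[2], delta = w$delta,
        se = w$se, t = w$t, df = w$df, p_raw = w$p)
    }
  }
  bind <- function(l) {x <- do.call(rbind, l); rownames(x) <- NULL; x}
  ancova <- bind(anc); stratified <- bind(strat)
  comparisons <- bind(comp); interactions <- bind(intr)
  ancova$p_fdr <- fdr_adjust(ancova$p_raw, family = "A:ancova")
  stratified$p_fdr <- fdr_adjust(stratified$p_raw, family = "B:stratified")
  comparisons$p_fdr <- fdr_adjust(comparisons$p_raw, family = "C:slopes")
  interactions$p_fdr <- fdr_adjust(interactions$p_raw, family = "D:interactions")
  structure(list(ancova = ancova, stratified = stratified,
                 slope_comparisons = comparisons, interactions = interactions,
                 simple_slopes = bind(ss), fits = fits),
            class = "moderation_results")
}

#' @export
print.moderation_results <- function(x, ...) {
  cat("Moderation analysis\n\nEducation x diagnosis ANCOVA interactions:\n")
  print(within(x$ancova, {F <- round(F, 3); p_raw <- signif(p_raw, 3)
                          p_fdr <- signif(p_fdr, 3); f2 <- round(f2, 4)}),
        row.names = FALSE)
  cat("\nStratified education effects (adjusted for age, sex, burden):\n")
  print(within(x$stratified, {beta_edu <- round(beta_edu, 3); se <- round(se, 3)
                              t <- round(t, 2); p_raw <- signif(p_raw, 3)
                              p_fdr <- signif(p_fdr, 3); f2 <- round(f2, 4)}),
        row.names = FALSE)
  cat("\nEducation x burden interactions:\n")
  print(within(x$interactions, {beta_int <- round(beta_int, 3); se <- round(se, 3)
                                p_raw <- signif(p_raw, 3); p_fdr <- signif(p_fdr, 3)
                                ci_low <- round(ci_low, 3); ci_high <- round(ci_high, 3)
                                f2 <- round(f2, 4)}),
        row.names = FALSE)
  invisible(x)
}
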