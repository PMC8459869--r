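#' Whole-sample z-standardization
#'
#' Standardizes raw scores with the mean and standard deviation of the whole
#' study sample (sample SD, n-1 denominator). Missing entries are preserved.
#'
#' @param values numeric vector with at least two non-missing entries.
#' @return numeric vector of z-units; non-missing entries have mean 0 and
#'   SD 1.
#' @export
zscore_sample <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L)
    stop("zscore_sample() needs at least 2 non-missing values", call. = FALSE)
  s <- stats::sd(values[ok])
  if (s == 0)
    stop("zscore_sample(): zero variance, scores cannot be standardized", call. = FALSE)
  (values - mean(values[ok])) / s
}

#' Trail Making Test ratio score
#'
#' Time to complete part B divided by time for part A, an executive index
#' relatively robust to psychomotor speed.
#'
#' @param tmt_a_sec,tmt_b_sec completion times in seconds; part A must be
#'   positive.
#' @return `tmt_b_sec / tmt_a_sec` (dimensionless).
#' @export
tmt_ratio <- function(tmt_a_sec, tmt_b_sec) {
  if (any(tmt_a_sec <= 0, na.rm = TRUE))
    stop("tmt_ratio(): tmt_a_sec must be positive", call. = FALSE)
  tmt_b_sec / tmt_a_sec
}

#' Floor rule for Trail Making Test part B non-completers
#'
#' Participants unable to complete part B are assigned the lowest (worst)
#' z-score observed among completers. The input must already be on the
#' inverted scale where higher z means better performance, so the sample
#' minimum is the worst observed performance. Completers are unchanged and
#' the rule is idempotent.
#'
#' @param z_tmt_ratio vector of inverted TMT-ratio z-scores (NA for
#'   non-completers).
#' @param completed logical vector, aligned with `z_tmt_ratio`.
#' @return vector with non-completers set to `min(z_tmt_ratio[completed])`.
#' @export
apply_tmt_floor <- function(z_tmt_ratio, completed) {
  stopifnot(length(z_tmt_ratio) == length(completed))
  if (!any(completed))
    stop("apply_tmt_floor(): no completers, floor z-score undefined", call. = FALSE)
  floor_z <- min(z_tmt_ratio[completed], na.rm = TRUE)
  z_tmt_ratio[!completed] <- floor_z
  z_tmt_ratio
}

#' Default mapping of tests to cognitive domains
#'
#' Global cognition averages all contributing tests; episodic memory the VAT
#' and the immediate and delayed recall of the 8-Word test; executive
#' functioning verbal fluency, the FAB and the TMT ratio. The two timed TMT
#' variables are inversion-flagged so that higher z always means better
#' performance. The immediate and delayed 8-Word recalls enter as separate
#' contributing sub-tasks.
#'
#' @return list with elements `domains` (named list of contributing test
#'   names per domain) and `inverted` (tests whose z-scores are negated).
#' @export
default_domain_map <- function() {
  list(domains = list(
         global_cognition = c("mmse", "vat", "word8_imm", "word8_del",
                              "fluency", "fab", "tmt_a_sec", "tmt_ratio"),
         episodic_memory = c("vat", "word8_imm", "word8_del"),
         executive = c("fluency", "fab", "tmt_ratio")),
       inverted = c("tmt_a_sec", "tmt_ratio"))
}

#' Reduced domain map excluding floor-prone sub-tests
#'
#' Domain map without the TMT ratio and the delayed recall of the 8-Word
#' test, the two sub-tests most affected by floor performance in MCI and AD;
#' used by the reduced-compound sensitivity analysis.
#'
#' @return list in the same format as [default_domain_map()].
#' @export
reduced_domain_map <- function() {
  list(domains = list(
         global_cognition = c("mmse", "vat", "word8_imm", "fluency", "fab",
                              "tmt_a_sec"),
         episodic_memory = c("vat", "word8_imm"),
         executive = c("fluency", "fab")),
       inverted = "tmt_a_sec")
}

#' Compound cognitive-domain scores
#'
#' Averages per-test z-scores into the compound domain scores. Inverted tests
#' must already be negated. Each compound is the mean of the participant's
#' available contributing tests; it is missing only if all contributing tests
#' are missing. The number of tests used is recorded per domain.
#'
#' @param test_z data.frame of per-test z-scores (columns named as in the
#'   domain map).
#' @param map domain map, see [default_domain_map()].
#' @return data.frame with one column per domain plus `n_tests_<domain>`.
#' @export
compound_scores <- function(test_z, map = default_domain_map()) {
  out <- data.frame(row.names = seq_len(nrow(test_z)))
  for (d in names(map$domains)) {
    cols <- map$domains[[d]]
    missing_cols <- setdiff(cols, names(test_z))
    if (length(missing_cols) > 0)
      stop(sprintf("compound_scores(): missing test columns: %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    m <- as.matrix(test_z[, cols, drop = FALSE])
    n_used <- rowSums(!is.na(m))
    out[[d]] <- ifelse(n_used > 0, rowMeans(m, na.rm = TRUE), NA_real_)
    out[[paste0("n_tests_", d)]] <- n_used
  }
  out
}

#' Categorize Verhage education levels
#'
#' Collapses the 7-level Dutch Verhage education classification into three
#' categories: low (1-3), average (4-5), high (6-7).
#'
#' @param verhage integer vector of Verhage levels, each in 1-7.
#' @return factor with levels `low`, `average`, `high`.
#' @export
categorize_education <- function(verhage) {
  ok <- is.na(verhage) | (verhage >= 1 & verhage <= 7 & verhage == round(verhage))
  if (!all(ok))
    stop("categorize_education(): verhage levels must be integers in 1-7", call. = FALSE)
  cut(verhage, breaks = c(0.5, 3.5, 5.5, 7.5),
      labels = c("low", "average", "high"))
}

#' Norm-based z-scores from a normative table
#'
#' Standardizes each raw test score against the mean and SD of its
#' participant's age-band x education-category normative cell, as done when
#' scoring against population norms instead of the study sample.
#'
#' @param cohort data.frame with `age`, `verhage` and raw test columns
#'   (including a derivable TMT ratio).
#' @param norm_table normative table as returned by
#'   [synthetic_norm_table()].
#' @return data.frame of per-test norm z-scores (one column per test present
#'   in the table), aligned with `cohort` rows.
#' @export
norm_scores <- function(cohort, norm_table) {
  bands <- as.character(age_band(cohort$age))
  edu <- as.character(categorize_education(cohort$verhage))
  tests <- unique(norm_table$test)
  work <- cohort
  if (!"tmt_ratio" %in% names(work) && "tmt_ratio" %in% tests)
    work$tmt_ratio <- ifelse(work$tmt_b_completed,
                             tmt_ratio(work$tmt_a_sec, work$tmt_b_sec), NA_real_)
  out <- data.frame(row.names = seq_len(nrow(work)))
  key <- paste(norm_table$test, norm_table$age_band, norm_table$education)
  for (t in tests) {
    idx <- match(paste(t, bands, edu), key)
    if (any(is.na(idx) & !is.na(work[[t]])))
      stop(sprintf("norm_scores(): no normative cell for test %s, cells %s", t,
                   paste(unique(paste(bands, edu)[is.na(idx) & !is.na(work[[t]])]),
                         collapse = "; ")), call. = FALSE)
    sds <- norm_table$sd[idx]
    if (any(!is.na(sds) & sds == 0))
      stop(sprintf("norm_scores(): zero-SD normative cell for test %s", t), call. = FALSE)
    out[[t]] <- (work[[t]] - norm_table$mean[idx]) / sds
  }
  out
}

#' Score a cohort: test z-scores, compounds, education category
#'
#' Runs the full scoring sequence on a cohort of raw records: compute the TMT
#' ratio, z-standardize every test against the whole study sample (or against
#' a normative table if one is supplied), negate the inversion-flagged tests
#' so higher z is always better, assign TMT part-B non-completers the lowest
#' completer z on the inverted ratio scale, and average the available tests
#' into the three compound domain scores. The fixed order of operations
#' (ratio, standardize, invert, floor) changes values and is therefore part
#' of the contract.
#'
#' @param cohort data.frame of participant records (see [generate_cohort()]
#'   for the schema).
#' @param map domain map, see [default_domain_map()].
#' @param norm_table optional normative table ([synthetic_norm_table()]);
#'   when supplied, per-test standardization uses normative cells instead of
#'   the whole-sample mean/SD.
#' @return `cohort` with appended per-test z columns (`<test>_z`), compound
#'   domain scores, per-domain counts of contributing tests, `edu_category`
#'   and its ordinal coding `edu_num` (low = 1, average = 2, high = 3).
#' @export
score_cohort <- function(cohort, map = default_domain_map(), norm_table = NULL) {
  coh <- cohort
  coh$tmt_ratio <- ifelse(coh$tmt_b_completed,
                          tmt_ratio(coh$tmt_a_sec, coh$tmt_b_sec), NA_real_)
  tests <- unique(unlist(map$domains))
  if (is.null(norm_table)) {
    test_z <- data.frame(row.names = seq_len(nrow(coh)))
    for (t in tests) test_z[[t]] <- zscore_sample(coh[[t]])
  } else {
    test_z <- norm_scores(coh, norm_table)[, tests, drop = FALSE]
  }
  for (t in intersect(map$inverted, names(test_z)))
    test_z[[t]] <- -test_z[[t]]
  if ("tmt_ratio" %in% names(test_z))
    test_z$tmt_ratio <- apply_tmt_floor(test_z$tmt_ratio, coh$tmt_b_completed)
  comp <- compound_scores(test_z, map)
  zcols <- stats::setNames(test_z, paste0(names(test_z), "_z"))
  out <- cbind(coh, zcols, comp)
  out$edu_category <- categorize_education(out$verhage)
  out$edu_num <- as.integer(out$edu_category)
  out
}
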