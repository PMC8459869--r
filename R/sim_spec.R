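#' @keywords internal
diagnosis_levels <- function() c("SCD", "MCI", "AD")

#' Cognitive domain names used throughout the package
#'
#' @return character vector of the three compound cognitive domains.
#' @export
cognitive_domains <- function() c("global_cognition", "episodic_memory", "executive")

#' @keywords internal
test_names <- function() {
  c("mmse", "vat", "word8_imm", "word8_del", "fluency", "fab",
    "tmt_a_sec", "tmt_b_sec")
}

#' Specification of a synthetic memory-clinic cohort
#'
#' Builds the generating parameters for [generate_cohort()]. The defaults
#' emulate a cross-sectional Dutch memory-clinic cohort of 543 patients
#' (108 subjective cognitive decline, 190 mild cognitive impairment,
#' 245 Alzheimer's dementia) with realistic marginal distributions for age,
#' Verhage education level (1-7) and the three visual MRI ratings (MTA 0-4,
#' GA 0-3, WMH 0-3); see [cohort_marginal_targets()] for the calibration
#' targets the defaults are tested against.
#'
#' The generative model per participant and cognitive domain is
#' \deqn{y_d = \mu_{gd} + w_d' x + \beta_{gd} z_g(edu) +
#'       \gamma_{gd} z_g(edu) z_g(b_d) + a\, z_g(age) + s\, male + \epsilon_d}
#' where `x` are the three ratings, `w_d` the (negative) cognition-relevant
#' pathology weights, `b_d = -w_d' x` the latent burden (higher = more
#' cognition-relevant pathology), `z_g()` denotes z-scoring within diagnosis
#' group, and `\epsilon_d` is Gaussian with SD `domain_noise_sd[d]`. Raw test
#' scores are affine maps of their domain's latent plus test-specific noise,
#' rounded and clipped to instrument ranges (clipping counts are recorded on
#' the cohort as attribute `n_clipped`). Trail Making Test part B
#' non-completion follows a logistic model of the (group-centred) latent
#' executive score with per-group offsets, so non-completion concentrates in
#' MCI/AD and in poor executive performers.
#'
#' @param group_sizes named integer vector of participants per diagnosis
#'   (names `SCD`, `MCI`, `AD`).
#' @param age_params per-group list with `median`, `q1`, `q3` of age in years;
#'   ages are drawn from a two-piece Gaussian matching those quartiles, rounded
#'   to whole years and restricted to 50-98.
#' @param sex_prob per-group probability that a participant is male.
#' @param education_probs per-group probability vector over Verhage levels 1-7.
#' @param rating_params list with elements `mta`, `ga`, `wmh`, each a per-group
#'   probability vector over the scale's support (MTA 0-4, GA 0-3, WMH 0-3).
#' @param rating_rank_cor Spearman rank correlation between the three ratings,
#'   induced through a Gaussian copula. The joint distribution of the ratings
#'   is a free parameter of the generator, not an empirical estimate.
#' @param true_pathology_weights per-domain named vector `(mta, ga, wmh)` of
#'   cognition-relevant pathology weights (z-units of latent cognition per
#'   rating point; negative = pathology hurts cognition).
#' @param domain_means per-group named vector of latent domain intercepts.
#' @param education_slopes per-group named vector (one entry per domain) of
#'   standardized education effects on the latent domain score.
#' @param interaction_coefs per-group named vector (one entry per domain) of
#'   education-by-burden interaction coefficients on the standardized scale.
#' @param age_slope,sex_effect nuisance effects of z(age) and male sex on
#'   every latent domain score.
#' @param domain_noise_sd named vector of residual SDs of the latent domain
#'   scores.
#' @param noise_sd named vector of test-level residual SDs, in raw test units.
#' @param test_params per-test list with `domain`, `intercept`, `loading`
#'   (raw units per latent z-unit; negative for timed tests where higher is
#'   worse) and `range`.
#' @param tmt_b_dropout list with per-group logistic `offsets` and a common
#'   `slope` on the group-centred latent executive score.
#' @param seed integer RNG seed; the whole cohort is a deterministic function
#'   of the spec including this seed.
#' @return an object of class `sim_spec`.
#' @seealso [generate_cohort()], [default_sim_spec()], [synthetic_norm_table()]
#' @export
sim_spec <- function(group_sizes = c(SCD = 108L, MCI = 190L, AD = 245L),
                     age_params = list(
                       SCD = c(median = 71, q1 = 66, q3 = 78),
                       MCI = c(median = 78, q1 = 73, q3 = 82),
                       AD  = c(median = 80, q1 = 76, q3 = 84)),
                     sex_prob = c(SCD = 0.43, MCI = 0.44, AD = 0.35),
                     education_probs = list(
                       SCD = c(0.01, 0.05, 0.20, 0.18, 0.32, 0.20, 0.04),
                       MCI = c(0.01, 0.05, 0.16, 0.32, 0.22, 0.19, 0.05),
                       AD  = c(0.02, 0.08, 0.25, 0.27, 0.20, 0.15, 0.03)),
                     rating_params = list(
                       mta = list(SCD = c(0.55, 0.30, 0.10, 0.04, 0.01),
                                  MCI = c(0.15, 0.45, 0.25, 0.12, 0.03),
                                  AD  = c(0.08, 0.30, 0.40, 0.17, 0.05)),
                       ga  = list(SCD = c(0.35, 0.45, 0.15, 0.05),
                                  MCI = c(0.15, 0.45, 0.30, 0.10),
                                  AD  = c(0.10, 0.42, 0.35, 0.13)),
                       wmh = list(SCD = c(0.30, 0.35, 0.25, 0.10),
                                  MCI = c(0.12, 0.25, 0.35, 0.28),
                                  AD  = c(0.10, 0.25, 0.35, 0.30))),
                     rating_rank_cor = 0.4,
                     true_pathology_weights = list(
                       global_cognition = c(mta = -0.30, ga = -0.20, wmh = -0.15),
                       episodic_memory  = c(mta = -0.35, ga = -0.15, wmh = -0.10),
                       executive        = c(mta = -0.20, ga = -0.15, wmh = -0.25)),
                     domain_means = list(
                       SCD = c(global_cognition = 0.90, episodic_memory = 1.10, executive = 0.70),
                       MCI = c(global_cognition = 0.10, episodic_memory = 0.10, executive = 0.15),
                       AD  = c(global_cognition = -0.70, episodic_memory = -0.55, executive = -0.55)),
                     education_slopes = list(
                       SCD = c(global_cognition = 0.60, episodic_memory = 0.36, executive = 0.55),
                       MCI = c(global_cognition = 0.35, episodic_memory = 0.17, executive = 0.35),
                       AD  = c(global_cognition = 0.15, episodic_memory = 0.05, executive = 0.20)),
                     interaction_coefs = list(
                       SCD = c(global_cognition = 0, episodic_memory = -0.23, executive = 0),
                       MCI = c(global_cognition = 0, episodic_memory = 0.15, executive = 0),
                       AD  = c(global_cognition = 0, episodic_memory = 0, executive = 0)),
                     age_slope = -0.20,
                     sex_effect = 0.10,
                     domain_noise_sd = c(global_cognition = 0.5,
                                         episodic_memory = 0.5,
                                         executive = 0.5),
                     noise_sd = c(mmse = 1.2, vat = 1.2, word8_imm = 2.5,
                                  word8_del = 1.0, fluency = 2.5, fab = 1.2,
                                  tmt_a_sec = 12, tmt_b_sec = 35),
                     test_params = list(
                       mmse      = list(domain = "global_cognition", intercept = 25.8, loading = 3.2,  range = c(0, 30)),
                       vat       = list(domain = "episodic_memory",  intercept = 7.5,  loading = 3.0,  range = c(0, 12)),
                       word8_imm = list(domain = "episodic_memory",  intercept = 21,   loading = 6.0,  range = c(0, 40)),
                       word8_del = list(domain = "episodic_memory",  intercept = 3.2,  loading = 2.2,  range = c(0, 8)),
                       fluency   = list(domain = "executive",        intercept = 16,   loading = 4.5,  range = c(0, 60)),
                       fab       = list(domain = "executive",        intercept = 13.5, loading = 2.8,  range = c(0, 18)),
                       tmt_a_sec = list(domain = "executive",        intercept = 65,   loading = -25,  range = c(10, 300)),
                       tmt_b_sec = list(domain = "executive",        intercept = 190,  loading = -80,  range = c(20, 600))),
                     tmt_b_dropout = list(
                       offsets = c(SCD = -2.90, MCI = -1.45, AD = -1.12),
                       slope = 1.0),
                     seed = 1L) {
  spec <- structure(
    list(group_sizes = group_sizes, age_params = age_params,
         sex_prob = sex_prob, education_probs = education_probs,
         rating_params = rating_params, rating_rank_cor = rating_rank_cor,
         true_pathology_weights = true_pathology_weights,
         domain_means = domain_means, education_slopes = education_slopes,
         interaction_coefs = interaction_coefs, age_slope = age_slope,
         sex_effect = sex_effect, domain_noise_sd = domain_noise_sd,
         noise_sd = noise_sd, test_params = test_params,
         tmt_b_dropout = tmt_b_dropout, seed = as.integer(seed)),
    class = "sim_spec")
  validate_sim_spec(spec)
  spec
}

#' Default cohort specification
#'
#' Convenience wrapper returning [sim_spec()] with all defaults: a 543-patient
#' memory-clinic cohort whose marginal medians and interquartile ranges for
#' age, education and the MRI ratings hit the targets in
#' [cohort_marginal_targets()].
#'
#' @param seed integer seed stored in the spec.
#' @return a `sim_spec`.
#' @export
default_sim_spec <- function(seed = 1L) sim_spec(seed = seed)

#' Validate a cohort specification
#'
#' Checks the structural invariants of a [sim_spec()]: positive group sizes,
#' probability vectors that sum to one, rating supports that respect the scale
#' maxima (MTA 0-4, GA 0-3, WMH 0-3), positive noise SDs. Errors name the
#' offending field.
#'
#' @param spec object to validate.
#' @return `spec`, invisibly, if valid.
#' @export
validate_sim_spec <- function(spec) {
  fail <- function(field, msg)
    stop(sprintf("invalid sim_spec field '%s': %s", field, msg), call. = FALSE)
  if (!inherits(spec, "sim_spec")) stop("not a sim_spec object", call. = FALSE)
  dg <- diagnosis_levels()
  if (!identical(names(spec$group_sizes), dg))
    fail("group_sizes", "must be named SCD, MCI, AD")
  if (any(spec$group_sizes < 0) || any(spec$group_sizes != round(spec$group_sizes)))
    fail("group_sizes", "must be non-negative integers")
  if (sum(spec$group_sizes) <= 0) fail("group_sizes", "at least one group must be non-empty")
  for (g in dg) {
    ap <- spec$age_params[[g]]
    if (is.null(ap) || !all(c("median", "q1", "q3") %in% names(ap)))
      fail("age_params", sprintf("group %s needs median, q1, q3", g))
    if (!(ap[["q1"]] < ap[["median"]] && ap[["median"]] < ap[["q3"]]))
      fail("age_params", sprintf("group %s must satisfy q1 < median < q3", g))
    sp <- spec$sex_prob[[g]]
    if (!is_scalar_number(sp) || sp < 0 || sp > 1)
      fail("sex_prob", sprintf("group %s must be a probability", g))
    ep <- spec$education_probs[[g]]
    if (length(ep) != 7L) fail("education_probs", sprintf("group %s must have 7 entries (Verhage 1-7)", g))
    assert_prob_vector(ep, paste0("education_probs$", g))
  }
  supp <- c(mta = 5L, ga = 4L, wmh = 4L)
  for (r in names(supp)) {
    for (g in dg) {
      rp <- spec$rating_params[[r]][[g]]
      if (length(rp) != supp[[r]])
        fail(paste0("rating_params$", r),
             sprintf("group %s must have %d entries (support 0-%d)", g, supp[[r]], supp[[r]] - 1L))
      assert_prob_vector(rp, paste0("rating_params$", r, "$", g))
    }
  }
  if (!is_scalar_number(spec$rating_rank_cor) ||
      spec$rating_rank_cor <= -1 || spec$rating_rank_cor >= 1)
    fail("rating_rank_cor", "must be in (-1, 1)")
  dom <- cognitive_domains()
  for (d in dom) {
    w <- spec$true_pathology_weights[[d]]
    if (is.null(w) || !all(c("mta", "ga", "wmh") %in% names(w)) || any(!is.finite(w)))
      fail("true_pathology_weights", sprintf("domain %s needs finite mta/ga/wmh weights", d))
  }
  for (g in dg) {
    for (fld in c("domain_means", "education_slopes", "interaction_coefs")) {
      v <- spec[[fld]][[g]]
      if (is.null(v) || !all(dom %in% names(v)) || any(!is.finite(v)))
        fail(fld, sprintf("group %s needs finite values for all domains", g))
    }
  }
  if (!is_scalar_number(spec$age_slope)) fail("age_slope", "must be a finite number")
  if (!is_scalar_number(spec$sex_effect)) fail("sex_effect", "must be a finite number")
  if (!all(dom %in% names(spec$domain_noise_sd)) || any(spec$domain_noise_sd <= 0))
    fail("domain_noise_sd", "must be positive for every domain")
  if (!all(test_names() %in% names(spec$noise_sd)) || any(spec$noise_sd <= 0))
    fail("noise_sd", "must be positive for every test")
  for (t in test_names()) {
    tp <- spec$test_params[[t]]
    if (is.null(tp) || !all(c("domain", "intercept", "loading", "range") %in% names(tp)))
      fail("test_params", sprintf("test %s needs domain, intercept, loading, range", t))
    if (!tp$domain %in% dom) fail("test_params", sprintf("test %s has unknown domain", t))
    if (tp$range[1] >= tp$range[2]) fail("test_params", sprintf("test %s has empty range", t))
  }
  off <- spec$tmt_b_dropout$offsets
  if (is.null(off) || !all(dg %in% names(off)))
    fail("tmt_b_dropout", "needs per-group offsets")
  if (!is_scalar_number(spec$tmt_b_dropout$slope))
    fail("tmt_b_dropout", "slope must be a finite number")
  if (!is_scalar_number(spec$seed)) fail("seed", "must be a single integer")
  invisible(spec)
}

#' Marginal calibration targets of the default cohort specification
#'
#' The per-group medians and interquartile ranges that the default generator
#' is calibrated to reproduce for age, Verhage education level and the three
#' visual MRI ratings. Medians of the ordinal/integer variables are expected
#' to match exactly in large samples; IQR endpoints to within one scale unit.
#'
#' @return data.frame with columns `variable`, `group`, `median`, `q1`, `q3`.
#' @export
cohort_marginal_targets <- function() {
  data.frame(
    variable = rep(c("age", "verhage", "mta", "ga", "wmh"), each = 3L),
    group = rep(diagnosis_levels(), times = 5L),
    median = c(71, 78, 80,  5, 4, 4,  0, 1, 2,  1, 1, 1,  1, 2, 2),
    q1     = c(66, 73, 76,  3, 4, 3,  0, 1, 1,  0, 1, 1,  0, 1, 1),
    q3     = c(78, 82, 84,  5, 5, 5,  1, 2, 2,  1, 2, 2,  2, 3, 3),
    stringsAsFactors = FALSE)
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("Synthetic memory-clinic cohort specification\n")
  cat(sprintf("  groups: %s (n = %s, total %d)\n",
              paste(names(x$group_sizes), collapse = "/"),
              paste(x$group_sizes, collapse = "/"), sum(x$group_sizes)))
  cat(sprintf("  rating rank correlation: %.2f; seed: %d\n",
              x$rating_rank_cor, x$seed))
  es <- vapply(x$education_slopes, function(v) v[["global_cognition"]], 0)
  cat(sprintf("  education slopes (global cognition): %s\n",
              paste(sprintf("%s=%.2f", names(es), es), collapse = ", ")))
  invisible(x)
}

#' Serialize / restore a cohort specification as JSON
#'
#' @param spec a `sim_spec`.
#' @param path file path.
#' @return `write_sim_spec()` returns `path` invisibly; `read_sim_spec()`
#'   returns a validated `sim_spec` equal to the one written.
#' @export
write_sim_spec <- function(spec, path) {
  validate_sim_spec(spec)
  jsonlite::write_json(named_to_list(unclass(spec)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# jsonlite drops names of atomic vectors; convert them to lists so field
# names survive the round trip.
named_to_list <- function(x) {
  if (is.list(x)) lapply(x, named_to_list)
  else if (!is.null(names(x))) as.list(x)
  else x
}

#' @rdname write_sim_spec
#' @export
read_sim_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(x) {v <- unlist(x); stats::setNames(as.numeric(v), names(v))}
  spec <- sim_spec(
    group_sizes = stats::setNames(as.integer(unlist(raw$group_sizes)), names(raw$group_sizes)),
    age_params = lapply(raw$age_params, num),
    sex_prob = num(raw$sex_prob),
    education_probs = lapply(raw$education_probs, as.numeric),
    rating_params = lapply(raw$rating_params, function(r) lapply(r, as.numeric)),
    rating_rank_cor = raw$rating_rank_cor,
    true_pathology_weights = lapply(raw$true_pathology_weights, num),
    domain_means = lapply(raw$domain_means, num),
    education_slopes = lapply(raw$education_slopes, num),
    interaction_coefs = lapply(raw$interaction_coefs, num),
    age_slope = raw$age_slope, sex_effect = raw$sex_effect,
    domain_noise_sd = num(raw$domain_noise_sd),
    noise_sd = num(raw$noise_sd),
    test_params = lapply(raw$test_params, function(tp)
      list(domain = tp$domain, intercept = as.numeric(tp$intercept),
           loading = as.numeric(tp$loading), range = as.numeric(unlist(tp$range)))),
    tmt_b_dropout = list(offsets = num(raw$tmt_b_dropout$offsets),
                         slope = as.numeric(raw$tmt_b_dropout$slope)),
    seed = as.integer(raw$seed))
  spec
}
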