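# End-to-end orchestration: simulate -> score -> burden -> inference ->
# descriptives -> sensitivity, with a reproducibility manifest. All
# randomness flows from the config's top-level seed, split into documented
# substreams: cohort generation uses seed, the burden models seed + 100
# (+ domain index), sensitivity variants reuse the burden substream.

#' Pipeline run configuration
#'
#' Bundles everything a full pipeline run needs: the cohort source (a
#' [sim_spec()] or a cohort CSV path), the top-level seed, burden-model
#' settings and the sensitivity-variant toggles. Configurations serialize to
#' JSON and round-trip through [save_run_config()] / [load_run_config()].
#'
#' @param spec a [sim_spec()] used to simulate the cohort, or `NULL` when
#'   `cohort_csv` is given.
#' @param cohort_csv path to a cohort CSV with the [generate_cohort()]
#'   schema (observable columns).
#' @param seed top-level integer seed.
#' @param burden_reps,burden_draw stratified-bootstrap settings of the
#'   burden models.
#' @param burden_method `"loocv"` or `"full_ols"` (see [fit_burden_model()]).
#' @param variants character subset of `c("norm_scores",
#'   "reduced_compounds", "single_rating")`.
#' @param out_dir output directory for [run_pipeline()].
#' @return list of class `run_config`.
#' @export
run_config <- function(spec = default_sim_spec(), cohort_csv = NULL,
                       seed = 1L, burden_reps = 100L, burden_draw = 75L,
                       burden_method = "loocv",
                       variants = c("norm_scores", "reduced_compounds",
                                    "single_rating"),
                       out_dir = "cogreserve_results") {
  if (is.null(spec) && is.null(cohort_csv))
    stop("run_config(): either spec or cohort_csv is required", call. = FALSE)
  variants <- match.arg(variants, several.ok = TRUE)
  structure(list(spec = spec, cohort_csv = cohort_csv,
                 seed = as.integer(seed), burden_reps = as.integer(burden_reps),
                 burden_draw = as.integer(burden_draw),
                 burden_method = burden_method,
                 variants = variants, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
save_run_config <- function(config, path) {
  obj <- unclass(config)
  obj$spec <- if (!is.null(config$spec)) named_to_list(unclass(config$spec))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- if (!is.null(raw$spec)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(raw$spec, tmp, auto_unbox = TRUE, digits = NA)
    read_sim_spec(tmp)
  }
  run_config(spec = spec, cohort_csv = raw$cohort_csv,
             seed = raw$seed, burden_reps = raw$burden_reps,
             burden_draw = raw$burden_draw, burden_method = raw$burden_method,
             variants = raw$variants, out_dir = raw$out_dir)
}

#' Validate a cohort table against the expected schema
#'
#' Checks column presence, value ranges (Verhage 1-7, MTA 0-4, GA 0-3,
#' WMH 0-3, MMSE 0-30, positive TMT times), diagnosis labels and the
#' TMT-B presence/completion consistency. Violations are reported, not
#' raised.
#'
#' @param table cohort data.frame.
#' @return data.frame of class `cohort_validation` with columns `row`
#'   (`NA` for table-level problems), `column` and `problem`; zero rows when
#'   the table is clean.
#' @export
validate_cohort <- function(table) {
  probs <- list()
  add <- function(row, column, problem)
    probs[[length(probs) + 1L]] <<- data.frame(row = row, column = column,
                                               problem = problem)
  required <- c("id", "diagnosis", "age", "sex", "verhage", "mta", "ga",
                "wmh", test_names(), "tmt_b_completed")
  for (col in setdiff(required, names(table)))
    add(NA_integer_, col, "missing column")
  in_range <- function(col, lo, hi) {
    if (!col %in% names(table)) return()
    bad <- which(!is.na(table[[col]]) & (table[[col]] < lo | table[[col]] > hi))
    for (r in bad) add(r, col, sprintf("value %g outside [%g, %g]",
                                       table[[col]][r], lo, hi))
  }
  in_range("verhage", 1, 7); in_range("mta", 0, 4); in_range("ga", 0, 3)
  in_range("wmh", 0, 3); in_range("mmse", 0, 30); in_range("age", 18, 110)
  if ("tmt_a_sec" %in% names(table))
    for (r in which(!is.na(table$tmt_a_sec) & table$tmt_a_sec <= 0))
      add(r, "tmt_a_sec", "must be positive")
  if ("diagnosis" %in% names(table)) {
    bad <- which(!as.character(table$diagnosis) %in% diagnosis_levels())
    for (r in bad) add(r, "diagnosis",
                       sprintf("unknown label '%s'", as.character(table$diagnosis)[r]))
  }
  if (all(c("tmt_b_sec", "tmt_b_completed") %in% names(table))) {
    bad <- which(is.na(table$tmt_b_sec) == table$tmt_b_completed)
    for (r in bad) add(r, "tmt_b_sec",
                       "tmt_b_sec must be present exactly when tmt_b_completed")
  }
  out <- if (length(probs) > 0) do.call(rbind, probs) else
    data.frame(row = integer(), column = character(), problem = character())
  rownames(out) <- NULL
  class(out) <- c("cohort_validation", "data.frame")
  out
}

observable_columns <- function(cohort)
  cohort[, !grepl("^latent_", names(cohort)), drop = FALSE]

write_result_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> validate -> score -> burden -> moderation
#' inference -> descriptives -> sensitivity variants, writes every result
#' table to `config$out_dir` and finishes with a reproducibility manifest
#' (config hash, seed, package version, row counts and per-file MD5 sums).
#' The whole bundle is a deterministic function of the configuration.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results (`cohort`, `scored`,
#'   `burden_models`, `results`, `descriptives`, `sensitivity`, `manifest`)
#'   and the output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  if (!is.null(config$cohort_csv)) {
    cohort <- utils::read.csv(config$cohort_csv, stringsAsFactors = FALSE)
    cohort$diagnosis <- factor(cohort$diagnosis, levels = diagnosis_levels())
    cohort$tmt_b_completed <- as.logical(cohort$tmt_b_completed)
  } else {
    spec <- config$spec
    spec$seed <- config$seed
    cohort <- generate_cohort(spec)
  }
  issues <- validate_cohort(cohort)
  if (nrow(issues) > 0) {
    bad <- issues[1, ]
    stop(sprintf("cohort schema violation at column '%s'%s: %s (%d issue(s) total)",
                 bad$column,
                 if (is.na(bad$row)) "" else sprintf(", row %d", bad$row),
                 bad$problem, nrow(issues)), call. = FALSE)
  }
  paths$cohort <- write_result_csv(observable_columns(cohort),
                                   file.path(config$out_dir, "cohort.csv"))

  scored <- score_cohort(cohort)
  wb <- add_burden_scores(scored, n_replications = config$burden_reps,
                          per_group_draw = config$burden_draw,
                          seed = config$seed + 100L,
                          method = config$burden_method)
  scored <- wb$scored
  score_cols <- c("id", "diagnosis", "edu_category", "edu_num",
                  cognitive_domains(),
                  paste0("n_tests_", cognitive_domains()),
                  paste0("burden_", cognitive_domains()))
  paths$scores <- write_result_csv(scored[, score_cols],
                                   file.path(config$out_dir, "scores.csv"))
  burden_json <- lapply(wb$models, function(m)
    list(domain = m$domain, intercept = m$intercept, weights = as.list(m$weights),
         n_replications = m$n_replications, per_group_draw = m$per_group_draw,
         method = m$method, seed = m$seed,
         replication_sd = as.list(apply(m$replication_coefs, 2, stats::sd))))
  paths$burden_models <- file.path(config$out_dir, "burden_models.json")
  jsonlite::write_json(burden_json, paths$burden_models, auto_unbox = TRUE,
                       digits = NA)

  results <- run_moderation_analysis(scored)
  for (tab in c("ancova", "stratified", "slope_comparisons", "interactions",
                "simple_slopes"))
    paths[[tab]] <- write_result_csv(results[[tab]],
                                     file.path(config$out_dir, paste0(tab, ".csv")))
  desc <- summary_table(scored)
  paths$descriptives <- write_result_csv(desc,
                                         file.path(config$out_dir, "descriptives.csv"))

  sens <- list()
  if ("norm_scores" %in% config$variants) {
    nt <- synthetic_norm_table(if (is.null(config$spec)) default_sim_spec()
                               else config$spec)
    sens$norm_scores <- run_norm_score_variant(cohort, nt,
                                               main_results = results,
                                               burden_reps = config$burden_reps,
                                               burden_draw = config$burden_draw,
                                               seed = config$seed + 100L)
  }
  if ("reduced_compounds" %in% config$variants)
    sens$reduced_compounds <- run_reduced_compound_variant(
      cohort, main_results = results, burden_reps = config$burden_reps,
      burden_draw = config$burden_draw, seed = config$seed + 100L)
  if ("single_rating" %in% config$variants)
    sens$single_rating <- find_interaction_drivers(
      cohort, main_results = results, burden_reps = config$burden_reps,
      burden_draw = config$burden_draw, seed = config$seed + 100L)
  for (v in names(sens)) {
    obj <- sens[[v]]
    if (inherits(obj, "sensitivity_report")) {
      paths[[paste0(v, "_interactions")]] <- write_result_csv(
        obj$results$interactions,
        file.path(config$out_dir, paste0("sensitivity_", v, "_interactions.csv")))
      paths[[paste0(v, "_stratified")]] <- write_result_csv(
        obj$results$stratified,
        file.path(config$out_dir, paste0("sensitivity_", v, "_stratified.csv")))
      paths[[paste0(v, "_concordance")]] <- write_result_csv(
        obj$concordance,
        file.path(config$out_dir, paste0("sensitivity_", v, "_concordance.csv")))
    } else {
      paths[[v]] <- write_result_csv(
        obj, file.path(config$out_dir, paste0("sensitivity_", v, "_drivers.csv")))
    }
  }

  cfg_path <- file.path(config$out_dir, "config.json")
  save_run_config(config, cfg_path)
  # hash the configuration without its output location, so the same analysis
  # run into two directories yields identical manifests
  canon <- config
  canon$out_dir <- "."
  canon_path <- tempfile(fileext = ".json")
  save_run_config(canon, canon_path)
  config_md5 <- unname(tools::md5sum(canon_path))
  unlink(canon_path)
  manifest <- list(
    schema_version = "1",
    package_version = as.character(utils::packageVersion("cogreserve")),
    seed = config$seed,
    config_md5 = config_md5,
    n_participants = nrow(cohort),
    n_by_group = as.list(table(cohort$diagnosis)),
    files = lapply(paths, function(p) unname(tools::md5sum(p))))
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, scored = scored, burden_models = wb$models,
                 results = results, descriptives = desc, sensitivity = sens,
                 manifest = manifest, paths = paths))
}
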