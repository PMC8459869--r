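#' Leave-one-out averaged ordinary least squares fit
#'
#' Fits an intercept + slopes OLS model leaving out each observation in turn
#' and returns the element-wise mean of the n leave-one-out parameter
#' vectors. Computed through the closed-form downdate
#' `beta_(i) = beta - (X'X)^-1 x_i e_i / (1 - h_i)`, which is exactly
#' equivalent to refitting without row i.
#'
#' @param X numeric matrix (or data.frame) of predictors, here the three
#'   visual MRI ratings; must have full column rank.
#' @param y numeric response vector (a cognitive domain z-score).
#' @return list with `intercept` and named `weights`.
#' @export
loocv_average_fit <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 5L) stop("loocv_average_fit() needs at least 5 rows", call. = FALSE)
  if (length(y) != n) stop("X and y have different lengths", call. = FALSE)
  if (any(is.na(X)) || any(is.na(y)))
    stop("loocv_average_fit() does not accept missing values", call. = FALSE)
  Xm <- cbind(`(Intercept)` = 1, X)
  p <- ncol(Xm)
  if (qr(Xm)$rank < p)
    stop("singular design: predictors are rank deficient", call. = FALSE)
  XtXinv <- chol2inv(chol(crossprod(Xm)))
  beta <- drop(XtXinv %*% crossprod(Xm, y))
  h <- rowSums((Xm %*% XtXinv) * Xm)
  if (any(1 - h < 1e-10))
    stop("singular design: a leave-one-out fit is not identifiable", call. = FALSE)
  e <- y - drop(Xm %*% beta)
  beta_avg <- beta - drop(XtXinv %*% crossprod(Xm, e / (1 - h))) / n
  names(beta_avg) <- colnames(Xm)
  list(intercept = unname(beta_avg[1]), weights = beta_avg[-1])
}

#' Fit a cognitive-domain-specific neuropathology burden model
#'
#' Regresses a cognitive domain score on the three visual MRI ratings under a
#' diagnosis-stratified bootstrap: across `n_replications` replications,
#' `per_group_draw` cases are sampled from each diagnosis group (without
#' replacement by default) so the model is not dominated by the larger
#' groups, leave-one-out cross-validated OLS parameters are retrieved within
#' each replication ([loocv_average_fit()]), and the resulting intercepts and
#' rating weights are averaged into the final parameters.
#'
#' @param data data.frame holding the domain score column, the rating columns
#'   and a diagnosis column; rows with missing values in any of these are
#'   dropped before sampling.
#' @param domain name of the domain score column.
#' @param n_replications number of stratified bootstrap replications.
#' @param per_group_draw cases drawn from each diagnosis group per
#'   replication; every group must have at least this many complete rows.
#' @param seed integer seed; the replication-by-replication subsamples are a
#'   reproducible function of it (replication r uses the r-th consecutive
#'   block of draws from the seeded stream).
#' @param method `"loocv"` (default) averages leave-one-out parameter
#'   vectors within each replication; `"full_ols"` uses the plain OLS fit of
#'   each replication subsample instead (comparison variant).
#' @param replace sample within groups with replacement.
#' @param group_col,rating_cols column names of the diagnosis label and the
#'   ratings.
#' @return object of class `burden_model`: final `intercept` and `weights`,
#'   the per-replication coefficient matrix `replication_coefs`, and the
#'   sampling settings.
#' @export
fit_burden_model <- function(data, domain, n_replications = 100L,
                             per_group_draw = 75L, seed = 1L,
                             method = c("loocv", "full_ols"),
                             replace = FALSE, group_col = "diagnosis",
                             rating_cols = c("mta", "ga", "wmh")) {
  method <- match.arg(method)
  if (n_replications < 1L) stop("n_replications must be >= 1", call. = FALSE)
  keep <- stats::complete.cases(data[, c(domain, rating_cols, group_col)])
  d <- data[keep, , drop = FALSE]
  groups <- split(seq_len(nrow(d)), d[[group_col]], drop = TRUE)
  too_small <- names(groups)[vapply(groups, length, 0L) < per_group_draw]
  if (!replace && length(too_small) > 0)
    stop(sprintf("diagnosis group(s) %s have fewer than per_group_draw = %d complete cases",
                 paste(too_small, collapse = ", "), per_group_draw), call. = FALSE)
  coefs <- matrix(NA_real_, n_replications, length(rating_cols) + 1L,
                  dimnames = list(NULL, c("(Intercept)", rating_cols)))
  with_seed(seed, {
    for (r in seq_len(n_replications)) {
      idx <- unlist(lapply(groups, function(g)
        g[sample.int(length(g), per_group_draw, replace = replace)]),
        use.names = FALSE)
      sub <- d[idx, , drop = FALSE]
      # stratification invariant: exactly per_group_draw rows per group
      stopifnot(all(table(sub[[group_col]])[names(groups)] == per_group_draw))
      X <- as.matrix(sub[, rating_cols, drop = FALSE])
      y <- sub[[domain]]
      fit <- if (method == "loocv") {
        loocv_average_fit(X, y)
      } else {
        cf <- stats::lm.fit(cbind(1, X), y)$coefficients
        list(intercept = cf[1], weights = stats::setNames(cf[-1], rating_cols))
      }
      coefs[r, ] <- c(fit$intercept, fit$weights[rating_cols])
    }
  })
  final <- colMeans(coefs)
  structure(list(domain = domain, intercept = unname(final[1]),
                 weights = final[-1], n_replications = n_replications,
                 per_group_draw = per_group_draw,
                 replication_coefs = coefs, seed = as.integer(seed),
                 method = method, replace = replace,
                 rating_cols = rating_cols),
            class = "burden_model")
}

#' @export
print.burden_model <- function(x, ...) {
  cat(sprintf("Neuropathology burden model for %s\n", x$domain))
  cat(sprintf("  %d replications x %d cases/group (%s, %s replacement)\n",
              x$n_replications, x$per_group_draw, x$method,
              if (x$replace) "with" else "without"))
  cat(sprintf("  intercept %.4f; weights %s\n", x$intercept,
              paste(sprintf("%s=%.4f", names(x$weights), x$weights), collapse = ", ")))
  invisible(x)
}

#' Compute neuropathological burden scores
#'
#' Applies a fitted [fit_burden_model()] to rating rows and inverts the
#' linear predictor, so that higher burden means more neurodegeneration
#' relevant to the model's cognitive domain. By default the raw burden is
#' z-standardized across the supplied rows (the analysis sample), which makes
#' the intercept inconsequential for every downstream model.
#'
#' @param model a `burden_model`.
#' @param data data.frame containing the model's rating columns.
#' @param standardize z-score the inverted predictor across the non-missing
#'   rows (default `TRUE`).
#' @return numeric vector of burden scores aligned with `data` rows; the
#'   un-standardized inverted predictor is attached as attribute `raw`.
#' @export
compute_burden <- function(model, data, standardize = TRUE) {
  stopifnot(inherits(model, "burden_model"))
  X <- as.matrix(data[, model$rating_cols, drop = FALSE])
  raw <- -(model$intercept + drop(X %*% model$weights[model$rating_cols]))
  out <- if (standardize) zscore_sample(raw) else raw
  attr(out, "raw") <- raw
  out
}

#' Fit burden models and attach standardized burden scores for every domain
#'
#' Convenience wrapper running [fit_burden_model()] and [compute_burden()]
#' per cognitive domain and appending `burden_<domain>` columns.
#'
#' @param scored scored cohort ([score_cohort()]).
#' @param n_replications,per_group_draw,seed,method,replace passed to
#'   [fit_burden_model()]; the per-domain fits use consecutive seeds
#'   `seed`, `seed + 1`, `seed + 2`.
#' @param domains domain score columns to model.
#' @return list with `scored` (input plus burden columns) and `models`
#'   (named list of `burden_model` objects).
#' @export
add_burden_scores <- function(scored, n_replications = 100L,
                              per_group_draw = 75L, seed = 1L,
                              method = "loocv", replace = FALSE,
                              domains = cognitive_domains()) {
  models <- list()
  for (i in seq_along(domains)) {
    d <- domains[[i]]
    models[[d]] <- fit_burden_model(scored, d, n_replications = n_replications,
                                    per_group_draw = per_group_draw,
                                    seed = seed + i - 1L, method = method,
                                    replace = replace)
    scored[[paste0("burden_", d)]] <- compute_burden(models[[d]], scored)
  }
  list(scored = scored, models = models)
}
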